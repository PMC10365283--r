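#' Read a 3D volume from TIFF stack or NIfTI
#'
#' TIFF stacks are read page-by-page (pages ordered along ascending z)
#' with integer intensities preserved exactly; voxel size and origin are
#' taken from the JSON sidecar `<path>.json` written by [write_volume()]
#' when present. NIfTI-1 files carry their geometry in the header
#' (spatial units normalised to mm internally); the full-precision voxel
#' size is recovered from the `descrip` field when the file was written
#' by this package.
#'
#' @param path file path ending in `.tif`/`.tiff` or `.nii`/`.nii.gz`.
#' @param voxel_size_um fallback voxel size when the file carries none.
#' @return a [voxel_volume].
#' @export
read_volume <- function(path, voxel_size_um = 1) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d1 <- dim(pages[[1]])
    if (!all(vapply(pages, function(p) identical(dim(p), d1), TRUE)))
      .stopf("format error: TIFF pages have inconsistent dimensions")
    arr <- array(0, c(d1[2], d1[1], length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
    origin <- c(0, 0, 0)
    side <- paste0(path, ".json")
    if (file.exists(side)) {
      meta <- jsonlite::fromJSON(side)
      voxel_size_um <- meta$voxel_size_um
      if (!is.null(meta$origin_mm)) origin <- meta$origin_mm
    }
    voxel_volume(arr, voxel_size_um, origin)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    hdr <- RNifti::niftiHeader(img)
    vs <- RNifti::pixdim(img)[1] * 1000      # mm -> um
    m <- regmatches(hdr$descrip,
                    regexec("voxel_size_um=([0-9.eE+-]+)", hdr$descrip))[[1]]
    if (length(m) == 2) vs <- as.numeric(m[2])
    origin <- c(0, 0, 0)
    mo <- regmatches(hdr$descrip,
                     regexec("origin_mm=([0-9.eE+-]+),([0-9.eE+-]+),([0-9.eE+-]+)",
                             hdr$descrip))[[1]]
    if (length(mo) == 4) origin <- as.numeric(mo[2:4])
    voxel_volume(array(as.numeric(img), dim(img)), vs, origin)
  } else .stopf("format error: unknown volume extension in %s", path)
}

#' Write a 3D volume as TIFF stack or NIfTI
#'
#' TIFF output stores integer intensities (8-bit when the range allows,
#' else 16-bit) bitwise-losslessly, with geometry in a JSON sidecar;
#' non-integer or out-of-range data must be written as NIfTI, which
#' stores the array as-is.
#'
#' @param v a [voxel_volume] (or [label_mask], written as 8-bit TIFF).
#' @param path output path (`.tif`/`.tiff` or `.nii`/`.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (inherits(v, "label_mask"))
    v <- voxel_volume(v$data + 0, v$voxel_size_um, v$origin_mm)
  if (!inherits(v, "voxel_volume")) .stopf("`v` must be a voxel_volume")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    x <- v$data
    if (any(x != round(x)) || min(x) < 0 || max(x) > 65535)
      .stopf("TIFF stores integers in [0, 65535]; write float data as NIfTI")
    bits <- if (max(x) <= 255) 8L else 16L
    scale <- 2^bits - 1
    pages <- lapply(seq_len(dim(x)[3]), function(k) t(x[, , k]) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "deflate",
                    reduce = FALSE)
    jsonlite::write_json(
      list(voxel_size_um = v$voxel_size_um, origin_mm = v$origin_mm),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(v$data)
    RNifti::pixdim(img) <- rep(v$voxel_size_um / 1000, 3)
    RNifti::pixunits(img) <- c("mm", "s")
    img <- RNifti::asNifti(v$data, reference = RNifti::niftiHeader(list(
      pixdim = c(-1, rep(v$voxel_size_um / 1000, 3), rep(0, 4)),
      descrip = sprintf("voxel_size_um=%.17g origin_mm=%.17g,%.17g,%.17g",
                        v$voxel_size_um, v$origin_mm[1], v$origin_mm[2],
                        v$origin_mm[3]))))
    RNifti::pixdim(img) <- rep(v$voxel_size_um / 1000, 3)
    RNifti::writeNifti(img, path)
  } else .stopf("format error: unknown volume extension in %s", path)
  invisible(path)
}

#' Read a triangle mesh from STL
#'
#' Binary and ASCII STL are supported; coincident vertices are merged.
#'
#' @param path STL file path.
#' @return a [surface_mesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80)
  txt <- rawToChar(head[head != as.raw(0)])
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  sz <- file.info(path)$size
  is_binary <- length(nf) == 1 && !is.na(nf) && nf > 0 && sz == 84 + 50 * nf
  if (is_binary) {
    payload <- readBin(con, "raw", 50 * nf)
    pm <- matrix(payload, nrow = 50)
    fl <- readBin(as.vector(pm[1:48, , drop = FALSE]), "numeric",
                  n = 12L * nf, size = 4, endian = "little")
    tri <- matrix(fl, nrow = 12)   # per face: normal, v1, v2, v3
    verts <- rbind(t(tri[4:6, , drop = FALSE]), t(tri[7:9, , drop = FALSE]),
                   t(tri[10:12, , drop = FALSE]))
    ord <- as.vector(t(matrix(seq_len(3 * nf), ncol = 3)))
    verts <- verts[ord, , drop = FALSE]     # v1,v2,v3 per face consecutive
  } else {
    if (!grepl("^\\s*solid", txt) && !grepl("solid", readLines(path, n = 1)))
      .stopf("format error: %s is neither binary nor ASCII STL", path)
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      .stopf("format error: ASCII STL with %d vertex lines", length(vl))
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    nf <- nrow(verts) / 3
  }
  if (nf == 0) .stopf("format error: empty mesh in %s", path)
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  surface_mesh(verts[uk, , drop = FALSE], matrix(map, ncol = 3, byrow = TRUE))
}

#' Write a triangle mesh as STL
#'
#' @param m a [surface_mesh].
#' @param path output path.
#' @param format `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(m, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  if (!inherits(m, "surface_mesh")) .stopf("`m` must be a surface_mesh")
  v <- m$vertices; f <- m$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn <- sqrt(rowSums(nrm^2)); nn[nn < 1e-30] <- 1
  nrm <- nrm / nn
  nf <- nrow(f)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "cochleamorph STL"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    tri <- rbind(t(nrm), t(a), t(b), t(cc))      # 12 floats per face (columns)
    rawf <- writeBin(as.numeric(tri), raw(), size = 4, endian = "little")
    pm <- matrix(rawf, nrow = 48)
    payload <- rbind(pm, matrix(as.raw(0), 2, nf))
    writeBin(as.vector(payload), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid cochleamorph", con)
    for (i in seq_len(nf)) {
      writeLines(sprintf("  facet normal %g %g %g", nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("    outer loop", con)
      writeLines(sprintf("      vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]), con)
      writeLines(sprintf("      vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]), con)
      writeLines(sprintf("      vertex %.9g %.9g %.9g", cc[i, 1], cc[i, 2], cc[i, 3]), con)
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid cochleamorph", con)
  }
  invisible(path)
}

#' Write a tabular report as CSV
#'
#' UTF-8, '.' decimal separator, header always present (a header-only
#' file for empty input).
#'
#' @param records data.frame, or list of single-row data.frames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (!is.data.frame(records)) .stopf("`records` must be a data.frame or list of rows")
  write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read/write landmark points (JSON)
#'
#' Landmarks are the three reference points of the cochlear frame:
#' `center`, `helicotrema` and `basal`, each a 3-vector in mm.
#'
#' @param landmarks named list of 3-vectors.
#' @param path JSON file path.
#' @return for `read_landmarks`, the named list.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(landmarks, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  lm <- jsonlite::fromJSON(path)
  for (nm in c("center", "helicotrema", "basal"))
    if (is.null(lm[[nm]]) || length(lm[[nm]]) != 3)
      .stopf("landmark file must contain 3-vector '%s'", nm)
  lapply(lm, as.numeric)
}
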