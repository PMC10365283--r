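#' Voxel volume container
#'
#' A `voxel_volume` wraps a 3D numeric array of grayscale intensities with
#' its physical geometry: an isotropic voxel size in micrometres and the
#' world-space position (mm) of the grid corner. The array is a native R
#' array with dimensions `(nx, ny, nz)`; the centre of voxel `(i, j, k)`
#' lies at `origin_mm + (c(i, j, k) - 0.5) * voxel_size_um / 1000`.
#'
#' @param data 3D numeric array of intensities.
#' @param voxel_size_um isotropic voxel edge length in micrometres (> 0).
#' @param origin_mm length-3 numeric, world coordinates (mm) of the grid
#'   corner (the face of voxel `(1,1,1)` closest to `-Inf` on every axis).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size_um, origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    .stopf("`data` must be a 3D array (got rank %d)", length(dim(data)))
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    .stopf("`voxel_size_um` must be a single positive number")
  if (length(origin_mm) != 3L || !all(is.finite(origin_mm)))
    .stopf("`origin_mm` must be a finite length-3 vector")
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         origin_mm = as.numeric(origin_mm)),
    class = "voxel_volume")
}

#' Label mask container
#'
#' A `label_mask` is a 3D integer (or logical) grid sharing the geometry of
#' the `voxel_volume` it was derived from. Value 0 is background; positive
#' integers are labels.
#'
#' @inheritParams voxel_volume
#' @param data 3D integer/logical array.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(data, voxel_size_um, origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    .stopf("`data` must be a 3D array (got rank %d)", length(dim(data)))
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
  }
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0)
    .stopf("`voxel_size_um` must be a single positive number")
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         origin_mm = as.numeric(origin_mm)),
    class = "label_mask")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels @ %.4g um, origin (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3], x$voxel_size_um,
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_mask> %d x %d x %d voxels @ %.4g um; %d foreground voxels\n",
              d[1], d[2], d[3], x$voxel_size_um, sum(x$data != 0)))
  invisible(x)
}

# voxel edge in mm
.vox_mm <- function(x) x$voxel_size_um / 1000

.check_same_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    .stopf("geometry mismatch: dims %s vs %s",
           paste(dim(a$data), collapse = "x"), paste(dim(b$data), collapse = "x"))
  if (abs(a$voxel_size_um - b$voxel_size_um) > 1e-9)
    .stopf("geometry mismatch: voxel sizes %g vs %g um",
           a$voxel_size_um, b$voxel_size_um)
  invisible(TRUE)
}

# world coordinates (mm) of the centres of the voxels at linear indices idx
.voxel_world <- function(mask, idx) {
  d <- dim(mask$data)
  idx0 <- idx - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  dv <- .vox_mm(mask)
  cbind(mask$origin_mm[1] + (i + 0.5) * dv,
        mask$origin_mm[2] + (j + 0.5) * dv,
        mask$origin_mm[3] + (k + 0.5) * dv)
}
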