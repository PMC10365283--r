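#' Volumetric porosity
#'
#' Porosity of a structure as the void fraction of its pore-filled
#' counterpart: `p = (Vf - Vo) / Vf * 100` percent, where `Vo` is the
#' original (porous) volume and `Vf` the filled (non-porous) volume.
#'
#' @param Vo_mm3 original volume (>= 0).
#' @param Vf_mm3 filled volume (>= Vo, > 0).
#' @return porosity in percent, in `[0, 100]`.
#' @export
porosity <- function(Vo_mm3, Vf_mm3) {
  if (any(Vf_mm3 <= 0)) .stopf("filled volume must be positive")
  if (any(Vo_mm3 < 0) || any(Vo_mm3 > Vf_mm3 * (1 + 1e-12)))
    .stopf("need 0 <= Vo <= Vf (got Vo=%g, Vf=%g)", Vo_mm3[1], Vf_mm3[1])
  # multiply before dividing so integer volumes give exact percentages
  (Vf_mm3 - pmin(Vo_mm3, Vf_mm3)) * 100 / Vf_mm3
}

#' Split the OSL into tympanic and vestibular plates
#'
#' Fits the inter-plate mid-surface along the reference axis within each
#' angular section of the spiral (detecting the axial gap between the
#' two bony sheets) and assigns every OSL voxel to the plate on its side:
#' the vestibular plate is the side with the greater coordinate along
#' `axis_dir`.
#'
#' @param osl_mask binary [label_mask] of the full OSL.
#' @param frame a `reference_frame`.
#' @param n_steps_per_turn angular sampling of the mid-surface fit.
#' @param gap_min_vox minimum axial gap (voxels) accepted as the
#'   plate separation.
#' @return list with binary [label_mask]s `tympanic` and `vestibular`.
#' @export
split_plates <- function(osl_mask, frame, n_steps_per_turn = 90L,
                         gap_min_vox = 2) {
  tr <- .trace_spiral(osl_mask, frame, n_steps_per_turn)
  dv <- tr$voxel_mm
  n <- length(tr$chain)
  mids <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    s <- sort(tr$cyl$s[tr$cluster_members[[k]]])
    if (length(s) < 2) next
    gaps <- diff(s)
    j <- which.max(gaps)
    if (gaps[j] >= gap_min_vox * dv) mids[k] <- (s[j] + s[j + 1]) / 2
  }
  ok <- !is.na(mids)
  if (mean(ok) < 0.5)
    .stopf("topology error: no inter-plate gap found in %d%% of sections (single sheet?)",
           round(100 * mean(!ok)))
  th <- tr$cluster_theta_deg
  mid_fun <- approxfun(th[ok], mids[ok], rule = 2)
  vest_vec <- logical(length(tr$index))
  for (k in seq_len(n)) {
    mem <- tr$cluster_members[[k]]
    vest_vec[mem] <- tr$cyl$s[mem] > mid_fun(th[k])
  }
  d <- dim(osl_mask$data)
  tymp <- array(FALSE, d); vest <- array(FALSE, d)
  vest[tr$index[vest_vec]] <- TRUE
  tymp[tr$index[!vest_vec]] <- TRUE
  # voxels not reached by the trace (stray clusters) stay unassigned
  list(tympanic = label_mask(tymp, osl_mask$voxel_size_um, osl_mask$origin_mm),
       vestibular = label_mask(vest, osl_mask$voxel_size_um, osl_mask$origin_mm))
}

#' Fill plate pores by morphological closing
#'
#' Voxel-space pore filling: morphological closing with a discrete
#' Euclidean ball. Interior pores up to the ball radius are filled while
#' the outer surface is preserved (up to concave rims smaller than the
#' ball). The operation is extensive (output contains input), increasing
#' in the radius, and idempotent.
#'
#' @param plate binary [label_mask] of one plate.
#' @param ball_radius_vox closing ball radius in voxels (>= 1).
#' @return binary [label_mask] of the filled plate.
#' @export
fill_pores_voxel <- function(plate, ball_radius_vox) {
  if (ball_radius_vox < 1) .stopf("`ball_radius_vox` must be >= 1")
  filled <- close_ball(plate$data, ball_radius_vox)
  label_mask(filled, plate$voxel_size_um, plate$origin_mm)
}

#' Fill plate pores by mesh shrink-wrap
#'
#' Mesh-space pore filling emulating a shrink-wrap modifier: a decimated
#' enclosure (the hole-filled, dilated voxelization of the input mesh) is
#' projected onto the outer surface of the part by iterative steps along
#' the gradient of its Euclidean distance field, with Laplacian relaxation
#' between steps. Interior cavities are absent from the enclosure by
#' construction, so the wrap hugs the outer surface only, yielding an
#' approximately non-porous adaptation of the original part.
#'
#' @param plate_mesh a [surface_mesh] (typically from [mask_to_mesh()]).
#' @param decimation_target_faces face budget of the wrap (>= 8).
#' @param iterations projection/relaxation iterations.
#' @param voxel_size_um grid pitch for the internal distance field;
#'   defaults to the mesh's own voxel size when it derives from a mask.
#' @return a watertight [surface_mesh] enclosing the input.
#' @export
fill_pores_wrap <- function(plate_mesh, decimation_target_faces = 3000L,
                            iterations = 5L, voxel_size_um = NULL) {
  if (!inherits(plate_mesh, "surface_mesh")) .stopf("`plate_mesh` must be a surface_mesh")
  if (decimation_target_faces < 8) .stopf("`decimation_target_faces` must be >= 8")
  src <- attr(plate_mesh, "source_mask")
  if (is.null(voxel_size_um))
    voxel_size_um <- attr(plate_mesh, "voxel_size_um")
  if (is.null(src)) {
    if (is.null(voxel_size_um)) {
      bb <- apply(plate_mesh$vertices, 2, range)
      voxel_size_um <- max(bb[2, ] - bb[1, ]) / 96 * 1000
    }
    src <- voxelize_mesh(plate_mesh, voxel_size_um, pad_vox = 6L)
  } else {
    src <- .pad_mask(src, 6L)
  }
  dv <- .vox_mm(src)
  solid <- fill_holes(dilate_ball(src$data, 2))
  enclosure <- mask_to_mesh(label_mask(solid, src$voxel_size_um, src$origin_mm))
  wrap <- decimate_mesh(enclosure, decimation_target_faces)

  # Euclidean distance field (voxels) to the part, and its trilinear sampler
  Df <- sqrt(.edt_sq(.as_logical_arr(src$data)))
  sampleD <- function(P) .trilinear(Df, src$origin_mm, dv, P)
  gradD <- function(P) {
    h <- 0.5 * dv
    # sweep() subtracts, so sweep(P, 2, c(-h,0,0)) evaluates at x + h
    cbind(sampleD(sweep(P, 2, c(-h, 0, 0))) - sampleD(sweep(P, 2, c(h, 0, 0))),
          sampleD(sweep(P, 2, c(0, -h, 0))) - sampleD(sweep(P, 2, c(0, h, 0))),
          sampleD(sweep(P, 2, c(0, 0, -h))) - sampleD(sweep(P, 2, c(0, 0, h)))) / (2 * h)
  }
  V <- wrap$vertices
  adj <- .vertex_adjacency(wrap)
  target_d <- 0.5                     # rest at half a voxel outside the surface
  for (it in seq_len(iterations)) {
    d <- sampleD(V)                   # in voxel units
    g <- gradD(V)
    gn <- sqrt(rowSums(g^2)); gn[gn < 1e-9] <- 1
    stepv <- (d - target_d) * dv      # mm along -grad
    V <- V - g / gn * stepv
    if (it < iterations) V <- .laplacian_relax(V, adj, lambda = 0.4)
  }
  out <- surface_mesh(V, wrap$faces)
  attr(out, "voxel_size_um") <- src$voxel_size_um
  out
}

.pad_mask <- function(mask, pad) {
  d <- dim(mask$data)
  arr <- array(FALSE, d + 2L * pad)
  arr[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    mask$data != 0
  label_mask(arr, mask$voxel_size_um, mask$origin_mm - pad * .vox_mm(mask))
}

# trilinear interpolation of a 3D field at world points (clamped to the grid)
.trilinear <- function(field, origin, dv, P) {
  d <- dim(field)
  gx <- pmin(pmax((P[, 1] - origin[1]) / dv - 0.5, 0), d[1] - 1 - 1e-9)
  gy <- pmin(pmax((P[, 2] - origin[2]) / dv - 0.5, 0), d[2] - 1 - 1e-9)
  gz <- pmin(pmax((P[, 3] - origin[3]) / dv - 0.5, 0), d[3] - 1 - 1e-9)
  i0 <- floor(gx); j0 <- floor(gy); k0 <- floor(gz)
  fx <- gx - i0; fy <- gy - j0; fz <- gz - k0
  at <- function(di, dj, dk)
    field[cbind(i0 + 1 + di, j0 + 1 + dj, k0 + 1 + dk)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(0, 0, 0) + fx * at(1, 0, 0)) +
              fy * ((1 - fx) * at(0, 1, 0) + fx * at(1, 1, 0))) +
    fz * ((1 - fy) * ((1 - fx) * at(0, 0, 1) + fx * at(1, 0, 1)) +
          fy * ((1 - fx) * at(0, 1, 1) + fx * at(1, 1, 1)))
}

.vertex_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)], f[, 2:1], f[, c(3, 2)], f[, c(1, 3)])
  split(e[, 2], e[, 1])
}

.laplacian_relax <- function(V, adj, lambda = 0.4) {
  M <- V
  ids <- as.integer(names(adj))
  for (ii in seq_along(adj)) {
    nb <- adj[[ii]]
    M[ids[ii], ] <- colMeans(V[nb, , drop = FALSE])
  }
  V + lambda * (M - V)
}

#' Per-segment, per-plate porosity of the OSL
#'
#' Splits the OSL into its tympanic and vestibular plates, partitions the
#' spiral into angular segments (by default thirds of the unwrapped
#' sweep: basal turn, midturn, apex), and computes the volumetric
#' porosity of every plate segment with the chosen pore-filling backend.
#'
#' @param osl_mask binary [label_mask] of the full OSL.
#' @param frame a `reference_frame`.
#' @param segment_bounds_deg numeric vector of unwrapped-angle boundaries
#'   (degrees); default: thirds of the observed angular span.
#' @param backend `"voxel"` (morphological closing; primary) or
#'   `"mesh_wrap"` (shrink-wrap on STL-style meshes).
#' @param closing_radius_vox closing ball radius for the voxel backend;
#'   choose at least 1.5x the largest expected pore radius.
#' @param wrap_target_faces,wrap_iterations mesh backend controls.
#' @param n_steps_per_turn angular sampling for plate splitting and
#'   segment assignment.
#' @return data.frame with columns `segment`, `plate`, `backend`,
#'   `Vo_mm3`, `Vf_mm3`, `p_pct`.
#' @export
segment_porosity <- function(osl_mask, frame, segment_bounds_deg = NULL,
                             backend = c("voxel", "mesh_wrap"),
                             closing_radius_vox = 3,
                             wrap_target_faces = 3000L, wrap_iterations = 5L,
                             n_steps_per_turn = 90L) {
  backend <- match.arg(backend)
  plates <- split_plates(osl_mask, frame, n_steps_per_turn)
  voxvol <- .vox_mm(osl_mask)^3
  rows <- list()
  for (pl in c("tympanic", "vestibular")) {
    pm <- plates[[pl]]
    filled <- fill_pores_voxel(pm, closing_radius_vox)
    # angles of all voxels of the filled plate (pore voxels included)
    trf <- .trace_spiral(filled, frame, n_steps_per_turn)
    th_f <- trf$vox_theta_deg
    if (is.null(segment_bounds_deg)) {
      rng <- range(th_f, na.rm = TRUE)
      bounds <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = 4)
    } else bounds <- segment_bounds_deg
    seg_names <- if (length(bounds) == 4) c("basal", "midturn", "apex")
                 else paste0("segment", seq_len(length(bounds) - 1))
    seg_f <- findInterval(th_f, bounds, rightmost.closed = TRUE)
    orig_f <- pm$data[trf$index] != 0
    for (s in seq_len(length(bounds) - 1)) {
      in_seg <- which(seg_f == s)
      if (backend == "voxel") {
        Vo <- sum(orig_f[in_seg]) * voxvol
        Vf <- length(in_seg) * voxvol
      } else {
        seg_orig <- array(FALSE, dim(pm$data))
        seg_orig[trf$index[in_seg]] <- orig_f[in_seg]
        if (sum(seg_orig) == 0) { Vo <- 0; Vf <- 0 }
        else {
          mo <- mask_to_mesh(label_mask(seg_orig, pm$voxel_size_um, pm$origin_mm))
          Vo <- mesh_volume(mo)
          wrap <- fill_pores_wrap(mo, wrap_target_faces, wrap_iterations)
          Vf <- mesh_volume(wrap)
          Vf <- max(Vf, Vo)           # wrap encloses the part up to tolerance
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        segment = seg_names[s], plate = pl, backend = backend,
        Vo_mm3 = Vo, Vf_mm3 = Vf,
        p_pct = if (Vf > 0) porosity(Vo, Vf) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
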