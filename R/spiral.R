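#' Build the cochlear reference frame
#'
#' The reference axis runs from the cochlear centre point towards the
#' helicotrema; the angular origin points at the basal (round-window) end
#' of the spiral, projected perpendicular to the axis.
#'
#' @param center_mm 3D cochlear centre point (mm).
#' @param helicotrema_mm 3D helicotrema point (mm); must differ from the
#'   centre.
#' @param basal_mm 3D point at the basal end of the spiral; must not lie
#'   on the axis.
#' @return object of class `reference_frame` with unit vectors
#'   `axis_dir`, `zero_dir` and `y_dir = axis_dir x zero_dir`.
#' @export
build_reference_frame <- function(center_mm, helicotrema_mm, basal_mm) {
  center_mm <- as.numeric(center_mm)
  ax <- as.numeric(helicotrema_mm) - center_mm
  na <- sqrt(sum(ax^2))
  if (na < 1e-12) .stopf("helicotrema coincides with the centre point")
  ax <- ax / na
  b <- as.numeric(basal_mm) - center_mm
  zero <- b - sum(b * ax) * ax
  nz <- sqrt(sum(zero^2))
  if (nz < 1e-9) .stopf("basal point lies on the reference axis (collinear landmarks)")
  zero <- zero / nz
  ydir <- c(ax[2] * zero[3] - ax[3] * zero[2],
            ax[3] * zero[1] - ax[1] * zero[3],
            ax[1] * zero[2] - ax[2] * zero[1])
  structure(list(center_mm = center_mm, axis_dir = ax, zero_dir = zero,
                 y_dir = ydir), class = "reference_frame")
}

# cylindrical coordinates of points (rows) in a frame:
# s (axial, mm), rho (radial, mm), phi (radians in [0, 2pi))
.frame_cyl <- function(points_mm, frame) {
  v <- sweep(as.matrix(points_mm), 2, frame$center_mm)
  s <- drop(v %*% frame$axis_dir)
  u <- drop(v %*% frame$zero_dir)
  w <- drop(v %*% frame$y_dir)
  list(s = s, rho = sqrt(u^2 + w^2), phi = atan2(w, u) %% (2 * pi))
}

#' Unwrap the spiral angle of an ordered point sequence
#'
#' Computes the cylindrical angle of each point in the reference frame
#' and unwraps it so that successive differences lie in (-180, 180)
#' degrees, giving a continuous angular coordinate along a spiral sweep.
#'
#' @param points_mm matrix (n x 3) of ordered points (mm).
#' @param frame a [build_reference_frame()] result.
#' @return numeric vector of unwrapped angles in degrees.
#' @export
unwrap_angle <- function(points_mm, frame) {
  cyl <- .frame_cyl(points_mm, frame)
  if (any(cyl$rho < 1e-9)) .stopf("point lies on the reference axis")
  raw <- cyl$phi
  d <- diff(raw)
  d <- d - 2 * pi * round(d / (2 * pi))
  (raw[1] + c(0, cumsum(d))) * 180 / pi
}

# ---- mask-based spiral tracing --------------------------------------------
# Partition the mask voxels into angular wedges, cluster each wedge by radius
# (separating the turns of the spiral), and stitch clusters across adjacent
# wedges by radial continuity into a single chain running base -> apex. The
# chain assigns every cluster (and voxel) a continuous unwrapped angle with
# origin at the innermost (basal) end of the sweep.
.trace_spiral <- function(mask, frame, n_steps_per_turn = 90L,
                          gap_vox = 4, link_vox = 6) {
  idx <- which(mask$data != 0)
  if (length(idx) == 0) .stopf("mask is empty")
  dv <- .vox_mm(mask)
  pts <- .voxel_world(mask, idx)
  cyl <- .frame_cyl(pts, frame)
  W <- as.integer(n_steps_per_turn)
  step <- 2 * pi / W
  wedge <- pmin(floor(cyl$phi / step) + 1L, W)

  # per-wedge clustering by radial gaps
  cl_wedge <- integer(0); cl_rho <- numeric(0); cl_members <- list()
  ord <- order(wedge, cyl$rho)
  ww <- wedge[ord]
  for (w in unique(ww)) {
    sel <- ord[ww == w]                 # sorted by rho within wedge
    rho <- cyl$rho[sel]
    brk <- which(diff(rho) > gap_vox * dv)
    starts <- c(1L, brk + 1L); ends <- c(brk, length(sel))
    for (ci in seq_along(starts)) {
      mem <- sel[starts[ci]:ends[ci]]
      cl_wedge <- c(cl_wedge, w)
      cl_rho <- c(cl_rho, mean(cyl$rho[mem]))
      cl_members[[length(cl_members) + 1L]] <- mem
    }
  }
  nc <- length(cl_wedge)

  # link clusters across adjacent wedges by radial continuity
  link_tol <- link_vox * dv
  nxt <- rep(NA_integer_, nc)
  prv <- rep(NA_integer_, nc)
  by_wedge <- split(seq_len(nc), cl_wedge)
  wkeys <- as.integer(names(by_wedge))
  for (w in wkeys) {
    w2 <- if (w == W) 1L else w + 1L
    if (!w2 %in% wkeys) next
    a <- by_wedge[[as.character(w)]]
    b <- by_wedge[[as.character(w2)]]
    for (ca in a) {
      dd <- abs(cl_rho[b] - cl_rho[ca])
      j <- which.min(dd)
      if (dd[j] <= link_tol && is.na(prv[b[j]])) { nxt[ca] <- b[j]; prv[b[j]] <- ca }
    }
  }

  # chain start: no incoming link, smallest radius; closed rings have no such
  # cluster, so fall back to the global minimum-radius cluster
  starts <- which(is.na(prv))
  start <- if (length(starts)) starts[which.min(cl_rho[starts])] else which.min(cl_rho)
  chain <- integer(0)
  cur <- start
  closed <- FALSE
  repeat {
    chain <- c(chain, cur)
    cur <- nxt[cur]
    if (is.na(cur) || length(chain) > nc) break
    if (cur == start) { closed <- TRUE; break }
  }
  if (length(chain) < 0.10 * W)
    .stopf("coverage error: mask intersects only %d of %d angular half-planes",
           length(chain), W)

  wedge_center <- (cl_wedge - 0.5) * step            # radians
  theta <- (seq_along(chain) - 1L) * step            # unwrapped angle, 0 at start
  out_members <- cl_members[chain]
  # per-voxel angle: cluster angle + in-wedge azimuthal offset
  vox_theta <- rep(NA_real_, length(idx))
  for (k in seq_along(chain)) {
    mem <- out_members[[k]]
    off <- cyl$phi[mem] - wedge_center[chain[k]]
    off <- off - 2 * pi * round(off / (2 * pi))
    vox_theta[mem] <- theta[k] + off
  }
  list(index = idx, pts = pts, cyl = cyl,
       chain = chain, closed = closed,
       cluster_theta_deg = theta * 180 / pi,
       cluster_phi_rad = wedge_center[chain],
       cluster_members = out_members,
       vox_theta_deg = vox_theta * 180 / pi,
       n_wedges = W, voxel_mm = dv)
}

#' Extract inner and outer wall contours of the OSL
#'
#' For each angular half-plane through the reference axis, the inner
#' (modiolar) wall point is the centroid of the one-voxel-thick innermost
#' edge of the mask voxels in that half-plane, and the outer (lateral)
#' wall point the centroid of the outermost edge; both are pushed half a
#' voxel radially outward/inward so they sit on the physical surface
#' rather than on voxel centres. Contour series are smoothed with robust
#' local-quadratic regression constrained to stay within 1.5 voxels of
#' the raw estimates (see the methods vignette).
#'
#' @param osl_mask binary [label_mask] of the OSL (non-empty).
#' @param frame a `reference_frame`.
#' @param n_steps_per_turn angular sampling density (default 90, i.e.
#'   4 degree steps).
#' @param smooth logical; apply the contour smoothing (default TRUE).
#' @return object of class `wall_contours`: list with `angles_deg`
#'   (strictly increasing unwrapped angles), `inner_pts_mm`,
#'   `outer_pts_mm` (matrices n x 3).
#' @export
extract_wall_contours <- function(osl_mask, frame, n_steps_per_turn = 90L,
                                  smooth = TRUE) {
  tr <- .trace_spiral(osl_mask, frame, n_steps_per_turn)
  dv <- tr$voxel_mm
  n <- length(tr$chain)
  rho_in <- rho_out <- s_in <- s_out <- numeric(n)
  for (k in seq_len(n)) {
    mem <- tr$cluster_members[[k]]
    rho <- tr$cyl$rho[mem]
    s <- tr$cyl$s[mem]
    # azimuth offset (radians) of each voxel from the wedge centre
    dphi <- (tr$vox_theta_deg[mem] - tr$cluster_theta_deg[k]) * pi / 180
    # detrend the spiral's radial drift across the wedge so the edge bands
    # are not smeared by the sweep (drift ~ r * g * wedge_width at the apex)
    b <- 0
    if (length(mem) > 3 && stats::var(dphi) > 0)
      b <- stats::cov(rho, dphi) / stats::var(dphi)
    rho_adj <- rho - b * dphi
    rmin <- min(rho_adj); rmax <- max(rho_adj)
    in_set <- rho_adj <= rmin + dv
    out_set <- rho_adj >= rmax - dv
    # half-voxel edge correction: voxel centres sit half a voxel inside the
    # physical wall on either edge
    rho_in[k] <- mean(rho_adj[in_set]) - dv / 2
    rho_out[k] <- mean(rho_adj[out_set]) + dv / 2
    s_in[k] <- mean(s[in_set]); s_out[k] <- mean(s[out_set])
  }
  ang <- tr$cluster_theta_deg
  phic <- tr$cluster_phi_rad
  o <- order(ang)
  keep <- o[!duplicated(ang[o])]
  ang <- ang[keep]
  rho_in <- rho_in[keep]; rho_out <- rho_out[keep]
  s_in <- s_in[keep]; s_out <- s_out[keep]; phic <- phic[keep]
  if (smooth && length(ang) >= 10) {
    rho_in <- .smooth_series(ang, rho_in, dv, tr$closed)
    rho_out <- .smooth_series(ang, rho_out, dv, tr$closed)
    s_in <- .smooth_series(ang, s_in, dv, tr$closed)
    s_out <- .smooth_series(ang, s_out, dv, tr$closed)
  }
  # reconstruct 3D points in the half-plane at each wedge-centre azimuth
  U <- outer(cos(phic), frame$zero_dir) + outer(sin(phic), frame$y_dir)
  inner <- matrix(frame$center_mm, length(ang), 3, byrow = TRUE) +
    U * rho_in + outer(s_in, frame$axis_dir)
  outer_pts <- matrix(frame$center_mm, length(ang), 3, byrow = TRUE) +
    U * rho_out + outer(s_out, frame$axis_dir)
  structure(list(angles_deg = ang, inner_pts_mm = inner, outer_pts_mm = outer_pts,
                 voxel_size_um = osl_mask$voxel_size_um),
            class = "wall_contours")
}

# Robust local-quadratic smoothing of a scalar contour series against the
# unwrapped angle. Closed rings are wrap-padded so the fit has no free
# endpoints; open spirals rely on loess's boundary-corrected local fits
# (degree 2), which do not sag at the ends the way spline boundaries do.
# The widest smoothing window whose fit stays within 1.5 voxels of the raw
# series is used; if none qualifies the raw series is returned.
.smooth_series <- function(ang, y, dv, closed = FALSE) {
  n <- length(y)
  if (closed) {
    k <- min(10L, n - 1L)
    span360 <- 360 * round((max(ang) - min(ang) + (ang[2] - ang[1])) / 360)
    xa <- c(ang[(n - k + 1):n] - span360, ang, ang[1:k] + span360)
    ya <- c(y[(n - k + 1):n], y, y[1:k])
  } else { xa <- ang; ya <- y }
  for (span in c(0.35, 0.2, 0.12, 0.08)) {
    if (span * length(xa) < 7) next
    fit <- try(stats::loess(ya ~ xa, span = span, degree = 2,
                            family = "symmetric"), silent = TRUE)
    if (inherits(fit, "try-error")) next
    sm <- predict(fit, ang)
    if (!anyNA(sm) && max(abs(sm - y)) <= 1.5 * dv) return(sm)
  }
  y
}

#' Width profile of the OSL
#'
#' The OSL width at each sampled angle is the Euclidean distance between
#' the paired inner (modiolar) and outer (lateral) wall points of the
#' radial section. Zero-width samples are kept but flagged via the
#' `degenerate` attribute.
#'
#' @param contours a [extract_wall_contours()] result.
#' @return data.frame of class `width_profile` with columns `angle_deg`,
#'   `x_norm` (NA until filled by [attach_position()]) and `width_mm`;
#'   carries the section midpoints as attribute `midpoints_mm`.
#' @export
width_profile <- function(contours) {
  if (!inherits(contours, "wall_contours")) .stopf("`contours` must be wall_contours")
  d <- sqrt(rowSums((contours$outer_pts_mm - contours$inner_pts_mm)^2))
  out <- data.frame(angle_deg = contours$angles_deg,
                    x_norm = NA_real_, width_mm = d)
  attr(out, "midpoints_mm") <- (contours$inner_pts_mm + contours$outer_pts_mm) / 2
  attr(out, "voxel_size_um") <- contours$voxel_size_um
  attr(out, "degenerate") <- which(d <= .Machine$double.eps^0.5)
  class(out) <- c("width_profile", "data.frame")
  out
}
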