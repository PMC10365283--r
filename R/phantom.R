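#' Synthetic cochlea phantom specification
#'
#' Parameters of the synthetic cochlea used to validate every stage of
#' the morphometry pipeline. The osseous spiral lamina (OSL) is modelled
#' as a ribbon following a logarithmic spiral centerline
#' `r(theta) = r0 * exp(g * theta)` with a constant axial rise per turn,
#' split into two parallel bony plates (tympanic below the mid-surface,
#' vestibular above) separated by a soft-tissue gap. The ribbon width
#' (modiolar to lateral wall) falls linearly with normalised arc length
#' from `width_base_mm` to `width_apex_mm`. Spherical pores with exactly
#' known voxel counts are carved strictly inside each plate, and an
#' optional dense inclusion ("cochleolith") is planted at the tonotopic
#' position of a chosen frequency.
#'
#' Default width endpoints span 1.34 mm at the base to 0.28 mm at the
#' apex, the range reported for the human OSL.
#'
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @param turns number of spiral turns (> 0).
#' @param spiral_r0_mm centerline radius at the basal end (theta = 0).
#' @param spiral_growth logarithmic growth rate per radian (>= 0).
#' @param pitch_mm_per_turn axial rise per full turn (>= 0).
#' @param width_base_mm,width_apex_mm ribbon width endpoints
#'   (`width_apex_mm <= width_base_mm`).
#' @param plate_thickness_mm thickness of each bony plate.
#' @param plate_gap_mm soft-tissue gap between the plates (>= 0).
#' @param pore_target_fraction target pore volume fraction per plate, in
#'   `[0, 1)`.
#' @param pore_radius_vox_range integer pore radius, or a length-2 range
#'   of radii, in voxels (supported radii 1..5).
#' @param inclusion_freq_hz frequency (Hz) at whose tonotopic position
#'   the inclusion is planted, or `NULL` for no inclusion.
#' @param inclusion_radius_mm inclusion radius in mm.
#' @param noise_sigma standard deviation of additive Gaussian intensity
#'   noise (intensity units; the noiseless tissue classes are background
#'   20, soft tissue 90, bone 180, inclusion 255).
#' @param seed integer seed controlling pore placement and noise.
#' @param margin_mm empty margin around the spiral in the generated grid.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_size_um = 60, turns = 2.5,
                         spiral_r0_mm = 2.0, spiral_growth = 0.105,
                         pitch_mm_per_turn = 0.3,
                         width_base_mm = 1.34, width_apex_mm = 0.28,
                         plate_thickness_mm = 1.2, plate_gap_mm = 0.24,
                         pore_target_fraction = 0.30,
                         pore_radius_vox_range = c(1L, 2L),
                         inclusion_freq_hz = 2000, inclusion_radius_mm = 0.25,
                         noise_sigma = 10, seed = 1L,
                         margin_mm = 0.36) {
  if (turns <= 0) .stopf("`turns` must be positive")
  if (spiral_r0_mm <= 0) .stopf("`spiral_r0_mm` must be positive")
  if (spiral_growth < 0) .stopf("`spiral_growth` must be >= 0")
  if (pitch_mm_per_turn < 0) .stopf("`pitch_mm_per_turn` must be >= 0")
  if (voxel_size_um <= 0) .stopf("`voxel_size_um` must be positive")
  if (width_base_mm <= 0 || width_apex_mm <= 0)
    .stopf("width endpoints must be positive")
  if (width_apex_mm > width_base_mm)
    .stopf("`width_apex_mm` must be <= `width_base_mm` (width descends base -> apex)")
  if (plate_thickness_mm <= 0) .stopf("`plate_thickness_mm` must be positive")
  if (plate_gap_mm < 0) .stopf("`plate_gap_mm` must be >= 0")
  if (pore_target_fraction < 0 || pore_target_fraction >= 1)
    .stopf("`pore_target_fraction` must lie in [0, 1)")
  rr <- round(range(pore_radius_vox_range))
  if (any(rr < 1) || any(rr > 5))
    .stopf("pore radii must be integers in 1..5 (got %s)",
           paste(pore_radius_vox_range, collapse = ", "))
  if (!is.null(inclusion_freq_hz) && inclusion_freq_hz <= 0)
    .stopf("`inclusion_freq_hz` must be positive")
  if (noise_sigma < 0) .stopf("`noise_sigma` must be >= 0")
  structure(list(
    voxel_size_um = voxel_size_um, turns = turns,
    spiral_r0_mm = spiral_r0_mm, spiral_growth = spiral_growth,
    pitch_mm_per_turn = pitch_mm_per_turn,
    width_base_mm = width_base_mm, width_apex_mm = width_apex_mm,
    plate_thickness_mm = plate_thickness_mm, plate_gap_mm = plate_gap_mm,
    pore_target_fraction = pore_target_fraction,
    pore_radius_vox_range = as.integer(rr),
    inclusion_freq_hz = inclusion_freq_hz,
    inclusion_radius_mm = inclusion_radius_mm,
    noise_sigma = noise_sigma, seed = as.integer(seed),
    margin_mm = margin_mm), class = "phantom_spec")
}

# arc-length table of the spiral on a dense theta grid (theta in radians)
.spiral_arclength <- function(spec, n = 4096) {
  theta_max <- 2 * pi * spec$turns
  th <- seq(0, theta_max, length.out = n)
  r <- spec$spiral_r0_mm * exp(spec$spiral_growth * th)
  c_ax <- spec$pitch_mm_per_turn / (2 * pi)
  integrand <- sqrt(r^2 * (1 + spec$spiral_growth^2) + c_ax^2)
  dth <- diff(th)
  s <- c(0, cumsum((integrand[-1] + integrand[-n]) / 2 * dth))
  list(theta = th, s = s, total = s[n])
}

# ribbon width (mm) as a function of theta (radians): linear in arc fraction
.width_at_theta <- function(spec, theta, arc = NULL) {
  if (is.null(arc)) arc <- .spiral_arclength(spec)
  sfun <- approxfun(arc$theta, arc$s, rule = 2)
  frac <- sfun(theta) / arc$total
  spec$width_base_mm + (spec$width_apex_mm - spec$width_base_mm) * frac
}

#' Generate the spiral centerline polyline
#'
#' Samples the phantom centerline `r(theta) = r0 * exp(g*theta)`,
#' `z = pitch * theta / (2*pi)`, ordered base to apex.
#'
#' @param spec a [phantom_spec].
#' @param samples_per_turn samples per full turn (>= 32).
#' @return numeric matrix (n x 3) of points in mm, with attributes
#'   `theta_rad` (angle per point) and `arclength_mm` (cumulative).
#' @export
generate_centerline <- function(spec, samples_per_turn = 128L) {
  if (!inherits(spec, "phantom_spec")) .stopf("`spec` must be a phantom_spec")
  if (samples_per_turn < 32) .stopf("need >= 32 samples per turn")
  n <- max(2L, ceiling(samples_per_turn * spec$turns) + 1L)
  th <- seq(0, 2 * pi * spec$turns, length.out = n)
  r <- spec$spiral_r0_mm * exp(spec$spiral_growth * th)
  pts <- cbind(x = r * cos(th), y = r * sin(th),
               z = spec$pitch_mm_per_turn * th / (2 * pi))
  attr(pts, "theta_rad") <- th
  attr(pts, "arclength_mm") <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  pts
}

#' Cumulative arc length of a polyline
#'
#' @param points_mm matrix (n x 3) of ordered points, n >= 2.
#' @return nondecreasing numeric vector of length n starting at 0.
#' @export
arc_length <- function(points_mm) {
  points_mm <- as.matrix(points_mm)
  if (nrow(points_mm) < 2) .stopf("need at least 2 points")
  c(0, cumsum(sqrt(rowSums(diff(points_mm)^2))))
}

# ---- exact-truth pore placement -------------------------------------------

# Integer packing lattices: rows are basis vectors; every nonzero lattice
# vector has squared norm > (2r)^2, so discrete balls of radius r centred on
# distinct sites are voxel-disjoint. Verified exhaustively (all integer
# points in the open ball of radius 2r are non-lattice points).
.pore_lattice_basis <- function(r) {
  switch(as.character(r),
    "1" = rbind(c(2, 1, 0), c(0, 2, 1), c(1, 0, 2)),
    "2" = rbind(c(3, 3, 0), c(0, 3, 3), c(3, 0, 3)),
    "3" = rbind(c(-2, -3, 5), c(2, -6, -9), c(-2, -3, -5)),
    "4" = rbind(c(-4, 6, 4), c(2, -4, 7), c(0, -10, -10)),
    "5" = rbind(c(-10, 10, -10), c(1, 10, 4), c(9, -2, 4)),
    .stopf("unsupported pore radius %s (supported: 1..5)", r))
}

# integer offsets of the discrete ball {v : |v| <= r}
.ball_offsets <- function(r) {
  g <- seq(-r, r)
  gr <- expand.grid(ox = g, oy = g, oz = g)
  gr <- gr[gr$ox^2 + gr$oy^2 + gr$oz^2 <= r^2, , drop = FALSE]
  as.matrix(gr)
}

# all lattice sites (integer voxel coords, 1-based) whose ball of radius r
# fits in the array bounds
.lattice_sites <- function(B, dims, r, offset = c(0L, 0L, 0L)) {
  lo <- r + 1; hi <- dims - r
  if (any(hi < lo)) return(matrix(0L, 0, 3))
  corners <- as.matrix(expand.grid(x = c(lo, hi[1]), y = c(lo, hi[2]),
                                   z = c(lo, hi[3])))
  corners <- sweep(corners, 2, offset)
  U <- corners %*% solve(B)
  ur <- apply(U, 2, range)
  grid <- expand.grid(u1 = floor(ur[1, 1] - 1):ceiling(ur[2, 1] + 1),
                      u2 = floor(ur[1, 2] - 1):ceiling(ur[2, 2] + 1),
                      u3 = floor(ur[1, 3] - 1):ceiling(ur[2, 3] + 1))
  sites <- as.matrix(grid) %*% B
  sites <- sweep(sites, 2, -as.numeric(offset))
  keep <- sites[, 1] >= lo & sites[, 1] <= hi[1] &
          sites[, 2] >= lo & sites[, 2] <= hi[2] &
          sites[, 3] >= lo & sites[, 3] <= hi[3]
  s <- sites[keep, , drop = FALSE]
  storage.mode(s) <- "integer"
  s
}

# Place non-overlapping spherical pores strictly inside `region` (3D logical)
# aiming at `target` volume fraction of sum(region). Returns the carved pore
# mask and exact counts. Caller provides RNG state.
.place_pores <- function(region, rmin, rmax, target, n_pores = NULL) {
  dims <- dim(region)
  total <- sum(region)
  out <- list(pore = array(FALSE, dims), n_pore_vox = 0L, total_vox = total)
  if ((target <= 0 && is.null(n_pores)) || total == 0) return(out)
  # pores must keep a closed 1-voxel wall: whole ball inside the eroded
  # region, with the outside of the array counting as background (pad, erode,
  # crop) so pores can never open onto the hull of a full-array slab
  rp <- array(FALSE, dims + 2L)
  rp[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- region
  core <- erode_ball(rp, 1)[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)]
  core_vec <- as.vector(core)
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  ball_n <- vapply(1:5, function(r) nrow(.ball_offsets(r)), 0L)
  offset <- as.integer(floor(runif(3, 0, 16)))

  # admissible sites (whole ball inside `core`) for a radius assignment on
  # the packing lattice of `r_lat`
  place_with <- function(r_lat, radii_of) {
    sites <- .lattice_sites(.pore_lattice_basis(r_lat), dims, r_lat, offset)
    if (nrow(sites) == 0) return(list(lin = integer(0), r = integer(0)))
    lin <- sites[, 1] + nx * (sites[, 2] - 1L) + nxy * (sites[, 3] - 1L)
    radii <- radii_of(nrow(sites))
    keep_lin <- integer(0); keep_r <- integer(0)
    for (r in unique(radii)) {
      sel <- which(radii == r)
      offs <- .ball_offsets(r)
      off_lin <- offs[, 1] + nx * offs[, 2] + nxy * offs[, 3]
      adm <- rep(TRUE, length(sel))
      cand <- lin[sel]
      for (o in off_lin) adm <- adm & core_vec[cand + o]
      keep_lin <- c(keep_lin, cand[adm])
      keep_r <- c(keep_r, rep.int(r, sum(adm)))
    }
    list(lin = keep_lin, r = keep_r)
  }
  # candidate configurations, preferring a mixed-radius look but falling back
  # to denser packings (smaller radii pack relatively denser on the integer
  # lattices) until the target fraction is reachable
  radii_pool <- seq.int(rmin, rmax)
  configs <- list(function(n) if (length(radii_pool) == 1L)
    rep.int(radii_pool, n) else sample(radii_pool, n, replace = TRUE))
  cfg_lat <- rmax
  if (rmin < rmax) {
    configs <- c(configs, list(function(n) rep.int(rmax, n)))
    cfg_lat <- c(cfg_lat, rmax)
  }
  for (r in rev(seq.int(rmin, rmax - 1))) {
    local({rr <- r; configs[[length(configs) + 1L]] <<- function(n) rep.int(rr, n)})
    cfg_lat <- c(cfg_lat, r)
  }
  mix <- NULL; max_frac <- 0; best_frac <- 0
  for (ci in seq_along(configs)) {
    cand <- place_with(cfg_lat[ci], configs[[ci]])
    frac <- sum(ball_n[cand$r]) / total
    if (is.null(mix) || frac > best_frac) { best_frac <- frac }
    mix <- cand; max_frac <- frac
    if (!is.null(n_pores) || frac >= target) break
  }
  if (is.null(n_pores) && max_frac < target)
    .stopf("pore target fraction %.3f unreachable without overlap (achieved %.3f)",
           target, best_frac)
  ord <- sample.int(length(mix$lin))
  cum <- cumsum(ball_n[mix$r[ord]])
  if (!is.null(n_pores)) {
    if (length(ord) < n_pores)
      .stopf("only %d admissible pore sites (requested %d)", length(ord), n_pores)
    k <- n_pores
  } else {
    k <- which(cum >= target * total)[1]
    if (is.na(k)) k <- length(ord)
    if (k > 1 && abs(cum[k - 1] - target * total) < abs(cum[k] - target * total))
      k <- k - 1
  }
  kept <- ord[seq_len(k)]
  pore_vec <- rep(FALSE, length(core_vec))
  for (r in unique(mix$r[kept])) {
    cl <- mix$lin[kept][mix$r[kept] == r]
    offs <- .ball_offsets(r)
    off_lin <- offs[, 1] + nx * offs[, 2] + nxy * offs[, 3]
    for (o in off_lin) pore_vec[cl + o] <- TRUE
  }
  out$pore <- array(pore_vec, dims)
  out$n_pore_vox <- sum(pore_vec)
  out
}

#' Generate a porous rectangular slab with exact porosity ground truth
#'
#' Unit-test fixture for the porosity pipeline: a solid slab with
#' non-overlapping spherical pores carved strictly in its interior (every
#' pore keeps a closed wall of at least one voxel), so that the true void
#' fraction is an exact voxel count. Pore centres sit on a dense integer
#' packing lattice (randomly shifted and thinned to the target fraction),
#' which is how fractions well above the random sequential adsorption
#' limit (~38%) remain reachable.
#'
#' @param dims_vox integer length-3 slab dimensions in voxels.
#' @param pore_fraction target pore volume fraction in `[0, 1)`.
#' @param pore_radius_vox pore radius in voxels, or a length-2 range
#'   (radii 1..5).
#' @param seed RNG seed.
#' @param n_pores optionally, place exactly this many pores instead of
#'   targeting a fraction.
#' @param voxel_size_um voxel size metadata for the returned mask.
#' @return list with `mask` (binary [label_mask] of the porous slab),
#'   `true_porosity_pct` (exact, by voxel count), `n_pore_vox`,
#'   `n_slab_vox`.
#' @export
generate_porous_slab <- function(dims_vox, pore_fraction, pore_radius_vox,
                                 seed = 1L, n_pores = NULL, voxel_size_um = 60) {
  dims_vox <- as.integer(dims_vox)
  if (length(dims_vox) != 3 || any(dims_vox < 4 * max(pore_radius_vox)))
    .stopf("each slab dimension must be >= 4 * pore radius")
  if (pore_fraction < 0 || pore_fraction >= 1)
    .stopf("`pore_fraction` must lie in [0, 1)")
  rr <- round(range(pore_radius_vox))
  if (any(rr < 1)) .stopf("pore radius must be >= 1")
  region <- array(TRUE, dims_vox)
  res <- .with_seed(seed,
    .place_pores(region, rr[1], rr[2], pore_fraction, n_pores = n_pores))
  slab <- region & !res$pore
  list(mask = label_mask(slab, voxel_size_um),
       true_porosity_pct = 100 * res$n_pore_vox / res$total_vox,
       n_pore_vox = res$n_pore_vox, n_slab_vox = res$total_vox)
}

#' Generate the synthetic cochlea phantom
#'
#' Builds the full voxel phantom: grayscale volume, per-structure label
#' masks, landmark points for the reference frame, and a ground-truth
#' record against which every pipeline measurement can be validated.
#'
#' Intensity classes before noise: background 20, soft tissue (inter-plate
#' gap) 90, bone 180, inclusion 255. Gaussian noise of `spec$noise_sigma`
#' is added last, then intensities are rounded and clamped to `[0, 255]`
#' (so volumes are losslessly representable as 8-bit TIFF).
#'
#' @param spec a [phantom_spec].
#' @param freq_params [freq_map_params] used to convert
#'   `spec$inclusion_freq_hz` to a spiral position.
#' @return object of class `cochlea_phantom`: a list with elements
#'   `volume` ([voxel_volume]), `masks` (list of [label_mask]: `osl`,
#'   `tympanic`, `vestibular`, `soft_tissue`, `inclusion`), `landmarks`
#'   (list of 3D points in mm: `center`, `helicotrema`, `basal`), `truth`
#'   (see Details) and `spec`.
#'
#' @details `truth` contains: `porosity` (exact per plate and per
#' angular-third segment, by voxel count before/after carving),
#' `width_fn(theta_deg)` (analytic ribbon width at any unwrapped angle),
#' `total_arclength_mm`, `centerline` (polyline with attributes),
#' `segment_bounds_deg`, `inclusion_center_xyz`, `inclusion_x_norm`, and
#' `theta_deg_vox` (unwrapped angle of every OSL voxel, as a sparse
#' index/value pair).
#' @export
generate_phantom <- function(spec, freq_params = freq_map_params()) {
  if (!inherits(spec, "phantom_spec")) .stopf("`spec` must be a phantom_spec")
  dv <- spec$voxel_size_um / 1000
  theta_max <- 2 * pi * spec$turns
  arc <- .spiral_arclength(spec)
  sfun <- approxfun(arc$theta, arc$s, rule = 2)

  # grid extents: spiral radius + half-width + margin
  th_dense <- arc$theta
  r_dense <- spec$spiral_r0_mm * exp(spec$spiral_growth * th_dense)
  w_dense <- spec$width_base_mm +
    (spec$width_apex_mm - spec$width_base_mm) * arc$s / arc$total
  r_ext <- max(r_dense + w_dense / 2) + spec$margin_mm
  half_z <- spec$plate_gap_mm / 2 + spec$plate_thickness_mm + spec$margin_mm
  z_lo <- -half_z
  z_hi <- spec$pitch_mm_per_turn * spec$turns + half_z
  nx <- ny <- ceiling(2 * r_ext / dv)
  nz <- ceiling((z_hi - z_lo) / dv)
  origin <- c(-nx * dv / 2, -ny * dv / 2, z_lo)

  xs <- origin[1] + (seq_len(nx) - 0.5) * dv
  ys <- origin[2] + (seq_len(ny) - 0.5) * dv
  zs <- origin[3] + (seq_len(nz) - 0.5) * dv
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  RHO <- sqrt(X^2 + Y^2)
  PHI <- atan2(Y, X) %% (2 * pi)

  tymp <- array(FALSE, c(nx, ny, nz))
  vest <- array(FALSE, c(nx, ny, nz))
  soft <- array(FALSE, c(nx, ny, nz))
  theta_slices <- vector("list", nz)  # per-slice unwrapped angle of OSL voxels
  for (k in seq_len(nz)) theta_slices[[k]] <- NULL

  half_gap <- spec$plate_gap_mm / 2
  tpl <- spec$plate_thickness_mm
  n_cand <- ceiling(spec$turns)
  theta_xy <- vector("list", n_cand)
  radial_ok <- vector("list", n_cand)
  zc_xy <- vector("list", n_cand)
  for (kk in seq_len(n_cand)) {
    tht <- PHI + 2 * pi * (kk - 1)
    valid <- tht <= theta_max + 1e-12
    rc <- spec$spiral_r0_mm * exp(spec$spiral_growth * tht)
    wd <- spec$width_base_mm +
      (spec$width_apex_mm - spec$width_base_mm) * sfun(tht) / arc$total
    radial_ok[[kk]] <- valid & abs(RHO - rc) <= wd / 2
    theta_xy[[kk]] <- tht
    zc_xy[[kk]] <- spec$pitch_mm_per_turn * tht / (2 * pi)
  }
  theta_vox <- array(NA_real_, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    z <- zs[k]
    for (kk in seq_len(n_cand)) {
      rok <- radial_ok[[kk]]
      if (!any(rok)) next
      zc <- zc_xy[[kk]]
      in_t <- rok & (z >= zc - half_gap - tpl) & (z < zc - half_gap)
      in_v <- rok & (z > zc + half_gap) & (z <= zc + half_gap + tpl)
      in_s <- rok & (z >= zc - half_gap) & (z <= zc + half_gap)
      if (any(in_t)) tymp[, , k] <- tymp[, , k] | in_t
      if (any(in_v)) vest[, , k] <- vest[, , k] | in_v
      if (any(in_s)) soft[, , k] <- soft[, , k] | in_s
      hit <- in_t | in_v | in_s
      if (any(hit)) {
        sl <- theta_vox[, , k]
        sl[hit] <- theta_xy[[kk]][hit]
        theta_vox[, , k] <- sl
      }
    }
  }

  # ---- pores (exact ground truth), inclusion, noise: all under the seed ----
  seeds <- .with_seed(spec$seed, as.integer(runif(3, 1, 2^30)))
  rr <- spec$pore_radius_vox_range
  pt <- .with_seed(seeds[1],
    .place_pores(tymp, rr[1], rr[2], spec$pore_target_fraction))
  pv <- .with_seed(seeds[2],
    .place_pores(vest, rr[1], rr[2], spec$pore_target_fraction))
  tymp_carved <- tymp & !pt$pore
  vest_carved <- vest & !pv$pore

  # inclusion: dense blob centred on the vestibular plate mid-plane at the
  # tonotopic position of inclusion_freq_hz
  incl <- array(FALSE, c(nx, ny, nz))
  incl_center <- NULL
  incl_x <- NA_real_
  if (!is.null(spec$inclusion_freq_hz)) {
    incl_x <- frequency_to_position(spec$inclusion_freq_hz, freq_params)
    xa <- if (freq_params$x_convention == "from_base") 1 - incl_x else incl_x
    s_target <- (1 - xa) * arc$total        # arc length from base
    th_star <- approxfun(arc$s, arc$theta, rule = 2)(s_target)
    rc <- spec$spiral_r0_mm * exp(spec$spiral_growth * th_star)
    zc <- spec$pitch_mm_per_turn * th_star / (2 * pi) + half_gap + tpl / 2
    incl_center <- c(rc * cos(th_star), rc * sin(th_star), zc)
    rad2 <- spec$inclusion_radius_mm^2
    d2xy <- (X - incl_center[1])^2 + (Y - incl_center[2])^2
    for (k in seq_len(nz)) {
      dz2 <- (zs[k] - incl_center[3])^2
      if (dz2 > rad2) next
      incl[, , k] <- d2xy + dz2 <= rad2
    }
  }

  vol <- array(20, c(nx, ny, nz))
  vol[soft] <- 90
  vol[tymp_carved | vest_carved] <- 180
  vol[incl] <- 255
  if (spec$noise_sigma > 0)
    vol <- vol + .with_seed(seeds[3],
      array(rnorm(length(vol), 0, spec$noise_sigma), dim(vol)))
  vol <- pmin(pmax(round(vol), 0), 255)

  # ---- exact porosity truth per plate and per angular-third segment -------
  bounds_deg <- seq(0, spec$turns * 360, length.out = 4)
  th_deg <- theta_vox * 180 / pi
  seg_of <- function(mask_arr) {
    td <- th_deg[mask_arr]
    findInterval(td, bounds_deg, rightmost.closed = TRUE)
  }
  seg_names <- c("basal", "midturn", "apex")
  porosity_truth <- do.call(rbind, lapply(
    list(list("tympanic", tymp, pt$pore), list("vestibular", vest, pv$pore)),
    function(pl) {
      seg_all <- seg_of(pl[[2]])
      seg_pore <- seg_of(pl[[2]] & pl[[3]])
      rows <- lapply(1:3, function(s) {
        nv <- sum(seg_all == s); np <- sum(seg_pore == s)
        data.frame(plate = pl[[1]], segment = seg_names[s],
                   plate_vox = nv, pore_vox = np,
                   true_porosity_pct = if (nv > 0) 100 * np / nv else NA_real_)
      })
      rows <- c(rows, list(data.frame(
        plate = pl[[1]], segment = "all", plate_vox = sum(pl[[2]]),
        pore_vox = sum(pl[[2]] & pl[[3]]),
        true_porosity_pct = 100 * sum(pl[[2]] & pl[[3]]) / max(1, sum(pl[[2]])))))
      do.call(rbind, rows)
    }))
  rownames(porosity_truth) <- NULL

  centerline <- generate_centerline(spec)
  wb <- spec$width_base_mm; wa <- spec$width_apex_mm; tot <- arc$total
  width_fn <- function(theta_deg) {
    wb + (wa - wb) * sfun(theta_deg * pi / 180) / tot
  }

  osl_idx <- which(tymp_carved | vest_carved)
  truth <- list(
    porosity = porosity_truth,
    width_fn = width_fn,
    total_arclength_mm = arc$total,
    centerline = centerline,
    segment_bounds_deg = bounds_deg,
    inclusion_center_xyz = incl_center,
    inclusion_x_norm = incl_x,
    theta_deg_vox = list(index = osl_idx, theta_deg = th_deg[osl_idx]))

  mk <- function(a) label_mask(a, spec$voxel_size_um, origin)
  landmarks <- list(center = c(0, 0, 0),
                    helicotrema = c(0, 0, z_hi),
                    basal = c(spec$spiral_r0_mm, 0, 0))
  structure(list(
    volume = voxel_volume(vol, spec$voxel_size_um, origin),
    masks = list(osl = mk(tymp_carved | vest_carved),
                 tympanic = mk(tymp_carved), vestibular = mk(vest_carved),
                 tympanic_pristine = mk(tymp), vestibular_pristine = mk(vest),
                 soft_tissue = mk(soft), inclusion = mk(incl)),
    landmarks = landmarks, truth = truth, spec = spec),
    class = "cochlea_phantom")
}

#' @export
print.cochlea_phantom <- function(x, ...) {
  d <- dim(x$volume$data)
  cat(sprintf("<cochlea_phantom> %d x %d x %d @ %g um; %.2f turns, OSL %d voxels\n",
              d[1], d[2], d[3], x$spec$voxel_size_um, x$spec$turns,
              sum(x$masks$osl$data != 0)))
  invisible(x)
}
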