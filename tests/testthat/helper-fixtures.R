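# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# small, fast phantom for module tests
phantom_small <- function() {
  .cached("phantom_small", generate_phantom(
    phantom_spec(voxel_size_um = 100, turns = 2, pore_target_fraction = 0.2,
                 seed = 11L)))
}

# full study-conditions phantom (default spec) for the acceptance checks
phantom_default <- function() {
  .cached("phantom_default", generate_phantom(phantom_spec(seed = 4L)))
}

phantom_frame <- function(ph) {
  build_reference_frame(ph$landmarks$center, ph$landmarks$helicotrema,
                        ph$landmarks$basal)
}

# Independent connected-components oracle: iterative minimum-label
# propagation over the chosen neighbourhood until a fixed point.
flood_fill_oracle <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  lab[mask] <- seq_len(sum(mask))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(offs))
  offs <- offs[ord > 0 & ord <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ]
  repeat {
    new <- lab
    for (i in seq_len(nrow(offs))) {
      sx <- offs[i, 1]; sy <- offs[i, 2]; sz <- offs[i, 3]
      xs <- max(1, 1 + sx):min(d[1], d[1] + sx)
      ys <- max(1, 1 + sy):min(d[2], d[2] + sy)
      zs <- max(1, 1 + sz):min(d[3], d[3] + sz)
      sub <- lab[xs - sx, ys - sy, zs - sz]
      cur <- new[xs, ys, zs]
      upd <- cur > 0L & sub > 0L & sub < cur
      cur[upd] <- sub[upd]
      new[xs, ys, zs] <- cur
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

oracle_component_sizes <- function(mask, connectivity = 26L) {
  lab <- flood_fill_oracle(mask, connectivity)
  as.integer(table(lab[lab > 0]))
}

# brute-force discrete ball voxel count / offsets
ball_count_oracle <- function(r) {
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  sum(g$x^2 + g$y^2 + g$z^2 <= r^2)
}

.ball_offsets_test <- function(r) {
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  as.matrix(g[g$x^2 + g$y^2 + g$z^2 <= r^2, ])
}

# analytic band-averaged width of a phantom with a linear width profile:
# width is linear in normalised position, so the band average is the width
# at the band midpoint
band_width_truth <- function(spec, partitions) {
  wa <- spec$width_apex_mm; wb <- spec$width_base_mm
  wa + (wb - wa) * (partitions$x_lo + partitions$x_hi) / 2
}
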