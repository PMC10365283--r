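frame_z <- function() build_reference_frame(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))

test_that("reference frame construction and degeneracies", {
  fr <- frame_z()
  expect_equal(fr$axis_dir, c(0, 0, 1))
  expect_equal(fr$zero_dir, c(1, 0, 0))
  expect_equal(sum(fr$axis_dir * fr$zero_dir), 0)
  expect_error(build_reference_frame(c(0, 0, 0), c(0, 0, 1), c(0, 0, 5)),
               "axis")
  expect_error(build_reference_frame(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "coincides")
  ph <- phantom_small()
  fr2 <- phantom_frame(ph)
  expect_equal(fr2$axis_dir, c(0, 0, 1), tolerance = 1e-9)
})

test_that("angle unwrapping is continuous, signed, and fails on the axis", {
  fr <- frame_z()
  sq <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  expect_equal(unwrap_angle(sq, fr), c(0, 90, 180, 270))
  rev_ang <- unwrap_angle(sq[4:1, ], fr)
  expect_equal(diff(rev_ang), rep(-90, 3))
  # phantom centerline spans turns * 360 degrees
  pts <- generate_centerline(phantom_spec(voxel_size_um = 100, turns = 2.5))
  ang <- unwrap_angle(pts, fr)
  expect_equal(ang[length(ang)] - ang[1], 900, tolerance = 1)
  expect_error(unwrap_angle(rbind(c(0, 0, 2)), fr), "axis")
})

test_that("wall contours on an analytic annulus recover both radii and width", {
  # planar annulus, inner 2 mm, outer 3 mm, 0.1 mm voxels, 5 slices thick
  dv <- 0.1
  n <- 70
  ax <- (seq_len(n) - 0.5) * dv - n * dv / 2
  X <- matrix(ax, n, n); Y <- t(X)
  R <- sqrt(X^2 + Y^2)
  ring <- R >= 2 & R <= 3
  arr <- array(FALSE, c(n, n, 5))
  for (k in 1:5) arr[, , k] <- ring
  mask <- label_mask(arr, 100, c(-n * dv / 2, -n * dv / 2, 0))
  fr <- build_reference_frame(c(0, 0, 0.25), c(0, 0, 1.25), c(5, 0, 0.25))
  ct <- extract_wall_contours(mask, fr, n_steps_per_turn = 72)
  rin <- sqrt(rowSums(ct$inner_pts_mm[, 1:2]^2))
  rout <- sqrt(rowSums(ct$outer_pts_mm[, 1:2]^2))
  expect_lt(max(abs(rin - 2)), dv / 2)
  expect_lt(max(abs(rout - 3)), dv / 2)
  pr <- width_profile(ct)
  expect_lt(max(abs(pr$width_mm - 1)), dv / 2)
  expect_error(extract_wall_contours(label_mask(array(FALSE, c(4, 4, 4)), 100), fr),
               "empty")
})

test_that("phantom wall contours land within a voxel of the ribbon edges", {
  ph <- phantom_small()
  fr <- phantom_frame(ph)
  ct <- extract_wall_contours(ph$masks$osl, fr)
  spec <- ph$spec
  dv <- spec$voxel_size_um / 1000
  th <- ct$angles_deg * pi / 180
  rc <- spec$spiral_r0_mm * exp(spec$spiral_growth * th)
  w <- ph$truth$width_fn(ct$angles_deg)
  rin_true <- rc - w / 2
  rout_true <- rc + w / 2
  rin <- sqrt(rowSums(ct$inner_pts_mm[, 1:2]^2))
  rout <- sqrt(rowSums(ct$outer_pts_mm[, 1:2]^2))
  # interior samples (ends are partial wedges)
  mid <- ct$angles_deg > 20 & ct$angles_deg < max(ct$angles_deg) - 20
  expect_lt(stats::quantile(abs(rin - rin_true)[mid], 0.95), dv)
  expect_lt(stats::quantile(abs(rout - rout_true)[mid], 0.95), dv)
})

test_that("width measurement is equivariant under joint rotation of mask and frame", {
  ph <- phantom_small()
  fr <- phantom_frame(ph)
  pr <- width_profile(extract_wall_contours(ph$masks$osl, fr))
  # rotate mask and frame together by 90 degrees about the axis:
  # (x, y) -> (-y, x) maps array index (i, j) -> (N+1-j, i) on the square,
  # origin-centred grid
  arr <- ph$masks$osl$data
  d <- dim(arr)
  expect_equal(d[1], d[2])
  rot <- array(FALSE, d)
  for (k in seq_len(d[3])) rot[, , k] <- t(arr[, d[2]:1, k])
  mrot <- label_mask(rot, ph$masks$osl$voxel_size_um, ph$masks$osl$origin_mm)
  fr2 <- build_reference_frame(ph$landmarks$center, ph$landmarks$helicotrema,
                               c(-ph$landmarks$basal[2], ph$landmarks$basal[1],
                                 ph$landmarks$basal[3]))
  pr2 <- width_profile(extract_wall_contours(mrot, fr2))
  expect_equal(nrow(pr2), nrow(pr))
  expect_equal(pr2$width_mm, pr$width_mm, tolerance = 1e-9)
})

test_that("arc length of a dense circle matches the circumference", {
  t <- seq(0, 2 * pi, length.out = 3601)
  circ <- cbind(2 * cos(t), 2 * sin(t), 0)
  expect_equal(tail(arc_length(circ), 1), 4 * pi, tolerance = 4 * pi * 1e-4)
  expect_error(arc_length(rbind(c(0, 0, 0))), "2 points")
  expect_equal(tail(arc_length(rbind(c(0, 0, 0), c(1, 0, 0))), 1), 1)
})
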