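test_that("centerline geometry matches closed forms", {
  # planar circle: circumference 4*pi
  circ <- phantom_spec(turns = 1, pitch_mm_per_turn = 0, spiral_growth = 0,
                       spiral_r0_mm = 2)
  pts <- generate_centerline(circ, samples_per_turn = 2048)
  s <- arc_length(pts)
  expect_equal(tail(s, 1), 4 * pi, tolerance = 1e-5)
  # 2.5 turns span 900 degrees
  pts2 <- generate_centerline(phantom_spec())
  th <- attr(pts2, "theta_rad")
  expect_equal(tail(th, 1) * 180 / pi, 900)
  # logarithmic spiral closed-form arc length: L = sqrt(1+g^2)/g * (r1 - r0)
  lsp <- phantom_spec(turns = 1, pitch_mm_per_turn = 0, spiral_growth = 0.1,
                      spiral_r0_mm = 1)
  p3 <- generate_centerline(lsp, samples_per_turn = 4096)
  L <- tail(arc_length(p3), 1)
  L_closed <- sqrt(1 + 0.1^2) / 0.1 * (exp(0.1 * 2 * pi) - 1)
  expect_equal(L, L_closed, tolerance = 1e-3)
  expect_error(generate_centerline(phantom_spec(), samples_per_turn = 8), "32")
  expect_error(phantom_spec(spiral_r0_mm = -1), "positive")
  expect_error(phantom_spec(turns = 0), "positive")
})

test_that("porous slab ground truth is exact by voxel count", {
  # no pores
  s0 <- generate_porous_slab(c(20, 20, 12), 0, 2, seed = 1)
  expect_equal(s0$true_porosity_pct, 0)
  expect_true(all(s0$mask$data != 0))
  # one pore of radius 3 in a 50^3 slab: enumerated ball count
  s1 <- generate_porous_slab(c(50, 50, 50), 0.01, 3, seed = 2, n_pores = 1)
  expect_equal(s1$true_porosity_pct, 100 * ball_count_oracle(3) / 50^3)
  # truth equals the carved-voxel ratio exactly
  s2 <- generate_porous_slab(c(64, 64, 24), 0.30, c(1, 2), seed = 3)
  carved <- s2$n_slab_vox - sum(s2$mask$data != 0)
  expect_equal(s2$true_porosity_pct, 100 * carved / s2$n_slab_vox)
  expect_gt(s2$true_porosity_pct, 28)
  expect_lt(s2$true_porosity_pct, 32)
  # mid porosity with a radius range
  s3 <- generate_porous_slab(c(128, 128, 64), 0.5, c(2, 4), seed = 0)
  expect_gt(s3$true_porosity_pct, 45)
  expect_lt(s3$true_porosity_pct, 55)
  # thin plate at 30%
  s4 <- generate_porous_slab(c(200, 200, 10), 0.30, c(1, 2), seed = 5)
  expect_gt(s4$true_porosity_pct, 28)
  expect_lt(s4$true_porosity_pct, 32)
})

test_that("pores stay strictly interior with closed walls", {
  s <- generate_porous_slab(c(40, 40, 16), 0.3, 2, seed = 9)
  pore <- !(s$mask$data != 0)
  # no pore voxel on the slab hull
  d <- dim(pore)
  expect_false(any(pore[c(1, d[1]), , ]) || any(pore[, c(1, d[2]), ]) ||
                 any(pore[, , c(1, d[3])]))
  # every cavity is enclosed: hole filling restores the full slab
  expect_true(all(fill_holes(s$mask$data)))
})

test_that("unreachable pore targets raise a generation error naming the achieved fraction", {
  expect_error(generate_porous_slab(c(20, 20, 8), 0.8, 2, seed = 1),
               "unreachable.*achieved")
})

test_that("phantom generation is deterministic and internally consistent", {
  spec <- phantom_spec(voxel_size_um = 140, turns = 1.5, noise_sigma = 8,
                       pore_target_fraction = 0.15,
                       pore_radius_vox_range = c(1, 1), seed = 21L)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$masks$osl$data, p2$masks$osl$data)
  expect_identical(p1$truth$porosity, p2$truth$porosity)

  # truth consistency: porosity recomputed from the emitted masks
  for (pl in c("tympanic", "vestibular")) {
    pristine <- p1$masks[[paste0(pl, "_pristine")]]$data != 0
    carved <- p1$masks[[pl]]$data != 0
    tru <- p1$truth$porosity
    row <- tru[tru$plate == pl & tru$segment == "all", ]
    expect_equal(row$true_porosity_pct,
                 100 * sum(pristine & !carved) / sum(pristine))
  }

  # analytic width profile is monotone non-increasing base -> apex
  w <- p1$truth$width_fn(seq(0, 1.5 * 360, by = 5))
  expect_true(all(diff(w) <= 1e-12))
  expect_equal(p1$truth$width_fn(0), spec$width_base_mm)
  expect_equal(p1$truth$width_fn(1.5 * 360), spec$width_apex_mm, tolerance = 1e-6)

  # zero pore fraction gives zero porosity truth everywhere
  p0 <- generate_phantom(phantom_spec(voxel_size_um = 140, turns = 1.5,
                                      pore_target_fraction = 0, seed = 3L))
  expect_true(all(p0$truth$porosity$true_porosity_pct == 0))
})
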