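test_that("the porosity formula is exact on integer volumes", {
  expect_identical(porosity(47, 100), 53)
  expect_identical(porosity(43, 100), 57)
  expect_equal(porosity(100, 100), 0)
  expect_equal(porosity(0, 100), 100)
  expect_error(porosity(10, 0), "positive")
  expect_error(porosity(101, 100), "Vo")
})

test_that("voxel pore filling fills enclosed pores and preserves solids", {
  solid <- label_mask(array(TRUE, c(20, 20, 12)), 100)
  expect_identical(fill_pores_voxel(solid, 3)$data != 0, solid$data != 0)
  # interior pore of radius 3, closing radius 5: restored exactly
  a <- array(TRUE, c(30, 30, 20))
  off <- .ball_offsets_test(3)
  a[cbind(15 + off[, 1], 15 + off[, 2], 10 + off[, 3])] <- FALSE
  m <- label_mask(a, 100)
  filled <- fill_pores_voxel(m, 5)
  expect_equal(sum(filled$data != 0), 30 * 30 * 20)
  # pore larger than the closing ball stays partly open
  b <- array(TRUE, c(40, 40, 30))
  off5 <- .ball_offsets_test(5)
  b[cbind(20 + off5[, 1], 20 + off5[, 2], 15 + off5[, 3])] <- FALSE
  part <- fill_pores_voxel(label_mask(b, 100), 3)
  expect_lt(sum(part$data != 0), 40 * 40 * 30)
  expect_true(all(part$data[b]))            # extensive
  expect_error(fill_pores_voxel(m, 0), ">= 1")
})

test_that("plate splitting matches phantom labels and detects single sheets", {
  ph <- phantom_small()
  fr <- phantom_frame(ph)
  pl <- split_plates(ph$masks$osl, fr)
  for (nm in c("tympanic", "vestibular")) {
    truth <- ph$masks[[nm]]$data != 0
    expect_gt(sum(pl[[nm]]$data & truth) / sum(truth), 0.99)
  }
  # flipping the axis swaps the plate labels
  fr_flip <- build_reference_frame(c(0, 0, 10), c(0, 0, -10),
                                   ph$landmarks$basal + c(0, 0, 10))
  pl2 <- split_plates(ph$masks$osl, fr_flip)
  truth_t <- ph$masks$tympanic$data != 0
  expect_gt(sum(pl2$vestibular$data & truth_t) / sum(truth_t), 0.99)
  # a single solid sheet has no inter-plate gap
  ring <- ph$masks$osl
  single <- label_mask(fill_holes(close_ball(ring$data, 4)),
                       ring$voxel_size_um, ring$origin_mm)
  expect_error(split_plates(single, fr), "topology")
})

test_that("segment porosity recovers phantom truth within 3 percentage points", {
  ph <- phantom_small()
  fr <- phantom_frame(ph)
  sp <- segment_porosity(ph$masks$osl, fr, ph$truth$segment_bounds_deg,
                         backend = "voxel", closing_radius_vox = 3)
  expect_equal(nrow(sp), 6)
  tru <- ph$truth$porosity
  m <- merge(sp, tru[tru$segment != "all", ], by = c("plate", "segment"))
  expect_equal(nrow(m), 6)
  expect_lt(max(abs(m$p_pct - m$true_porosity_pct)), 3)
  # zero-pore phantom: discretisation floor only
  p0 <- generate_phantom(phantom_spec(voxel_size_um = 140, turns = 1.5,
                                      pore_target_fraction = 0, seed = 3L))
  # closing ball scaled to the coarser voxels so adjacent turns cannot bridge
  sp0 <- segment_porosity(p0$masks$osl, phantom_frame(p0),
                          p0$truth$segment_bounds_deg, closing_radius_vox = 2)
  expect_lt(max(sp0$p_pct), 1)
})

test_that("voxel and mesh-wrap backends agree on the phantom plates", {
  ph <- phantom_small()
  fr <- phantom_frame(ph)
  sv <- segment_porosity(ph$masks$osl, fr, ph$truth$segment_bounds_deg,
                         backend = "voxel")
  sm <- segment_porosity(ph$masks$osl, fr, ph$truth$segment_bounds_deg,
                         backend = "mesh_wrap")
  m <- merge(sv, sm, by = c("plate", "segment"))
  expect_lt(max(abs(m$p_pct.x - m$p_pct.y)), 5)
})

test_that("mesh volumes match closed forms and voxel counts", {
  cube <- mask_to_mesh(label_mask(array(TRUE, c(1, 1, 1)), 1000))
  expect_equal(mesh_volume(cube), 1)
  ico <- icosphere(2, subdivisions = 4)
  expect_equal(mesh_volume(ico), 4 / 3 * pi * 8, tolerance = 0.01)
  # inverted orientation: same magnitude
  flipped <- surface_mesh(ico$vertices, ico$faces[, c(1, 3, 2)])
  expect_equal(mesh_volume(flipped), mesh_volume(ico))
  # non-watertight input is rejected
  holed <- surface_mesh(ico$vertices, ico$faces[-1, ])
  expect_error(mesh_volume(holed), "watertight")
  # voxel-derived mesh volume equals the voxel count exactly
  s <- generate_porous_slab(c(24, 24, 12), 0.2, 2, seed = 2, voxel_size_um = 100)
  ms <- mask_to_mesh(s$mask)
  expect_equal(mesh_volume(ms), sum(s$mask$data != 0) * 0.1^3, tolerance = 1e-9)
  # and brute-force re-voxelization agrees within 2%
  vx <- voxelize_mesh(ms, 100)
  expect_equal(sum(vx$data), sum(s$mask$data != 0), tolerance = 0.02)
})

test_that("shrink-wrap encloses the part and approximates convex solids", {
  ico <- icosphere(2, subdivisions = 3)
  w <- fill_pores_wrap(ico, 3000, 5, voxel_size_um = 100)
  expect_equal(mesh_volume(w), mesh_volume(ico), tolerance = 0.02)
  # porous slab: wrap volume at least the porous volume, close to pristine
  s <- generate_porous_slab(c(40, 40, 16), 0.3, 2, seed = 3, voxel_size_um = 100)
  sm <- mask_to_mesh(s$mask)
  Vo <- mesh_volume(sm)
  wrap <- fill_pores_wrap(sm, 3000, 5)
  Vf <- mesh_volume(wrap)
  expect_gt(Vf, Vo)
  pristine <- 40 * 40 * 16 * 0.1^3
  expect_equal(Vf, pristine, tolerance = 0.03)
  expect_lt(nrow(wrap$faces), 3001)
  expect_error(fill_pores_wrap(sm, 4), ">= 8")
})

test_that("mesh decimation respects the face budget and keeps closedness", {
  ico <- icosphere(2, subdivisions = 4)
  dm <- decimate_mesh(ico, 500)
  expect_lte(nrow(dm$faces), 500)
  expect_equal(mesh_volume(dm), mesh_volume(ico), tolerance = 0.15)
})
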