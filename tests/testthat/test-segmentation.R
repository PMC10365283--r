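test_that("threshold selection follows the intensity window", {
  v <- voxel_volume(array(c(0, 50, 200, 0, 50, 200, 0, 50), c(2, 2, 2)), 10)
  m <- threshold_segment(v, threshold_rule(100))
  expect_identical(which(m$data != 0), which(v$data == 200))
  expect_true(all(threshold_segment(v, threshold_rule(-Inf))$data == 1))
  expect_error(threshold_rule(10, 5), "lo")
})

test_that("small-component removal keeps only large components and is idempotent", {
  a <- array(FALSE, c(20, 20, 10))
  a[2:6, 2, 2] <- TRUE                      # 5 voxels
  a[10:14, 3:7, 3:6] <- TRUE                # 100 voxels
  m <- label_mask(a, 10)
  r <- remove_small_components(m, 10)
  expect_equal(sum(r$data), 100)
  expect_identical(remove_small_components(m, 1)$data != 0, a)   # identity
  r2 <- remove_small_components(r, 10)
  expect_identical(r2$data, r$data)                              # idempotent
  expect_true(all(a | !(r$data != 0)))                           # never adds
})

test_that("size filtering agrees with the flood-fill oracle on random speckle", {
  set.seed(13)
  a <- array(runif(20^3) < 0.3, c(20, 20, 20))
  m <- label_mask(a, 10)
  r <- remove_small_components(m, 27, connectivity = 26)
  lab <- label_components(r$data, 26)
  oracle_sizes <- oracle_component_sizes(a, 26)
  expect_equal(max(lab), sum(oracle_sizes >= 27))
})

test_that("label subtraction and masking follow voxelwise set algebra", {
  a <- label_mask(array(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
                        c(2, 2, 2)), 10)
  b <- label_mask(array(c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
                        c(2, 2, 2)), 10)
  expect_equal(sum(subtract_labels(a, a)$data), 0)
  expect_identical(subtract_labels(a, label_mask(array(FALSE, c(2, 2, 2)), 10))$data,
                   a$data)
  expect_identical(subtract_labels(a, b)$data != 0, a$data != 0 & b$data == 0)
  wrong <- label_mask(array(FALSE, c(2, 2, 3)), 10)
  expect_error(subtract_labels(a, wrong), "geometry")

  v <- voxel_volume(array(as.double(1:8), c(2, 2, 2)), 10)
  expect_identical(apply_mask(v, a)$data, v$data * (a$data != 0))
  full <- label_mask(array(TRUE, c(2, 2, 2)), 10)
  expect_identical(apply_mask(v, full)$data, v$data)
  # masked-then-thresholded stays inside the mask
  m2 <- threshold_segment(apply_mask(v, a), threshold_rule(1))
  expect_true(all(a$data[m2$data != 0] != 0))
})

test_that("bone thresholding of the noisy phantom matches the truth mask", {
  ph <- phantom_small()
  bone <- threshold_segment(ph$volume, threshold_rule(120, 220))
  bone <- remove_small_components(bone, 27)
  truth <- ph$masks$osl$data != 0
  agree <- sum((bone$data != 0) == truth) / length(truth)
  expect_gt(agree, 0.99)
  # and the soft-tissue recipe: everything-above-background minus bone
  allfg <- threshold_segment(ph$volume, threshold_rule(55, 220))
  soft <- subtract_labels(remove_small_components(allfg, 27), bone)
  truth_soft <- ph$masks$soft_tissue$data != 0
  expect_gt(sum((soft$data != 0) & truth_soft) / sum(truth_soft), 0.95)
})
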