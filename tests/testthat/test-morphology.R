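test_that("ball dilation reproduces enumerated discrete ball volumes", {
  for (r in 1:3) {
    m <- array(FALSE, c(2 * r + 5, 2 * r + 5, 2 * r + 5))
    m[r + 3, r + 3, r + 3] <- TRUE
    expect_equal(sum(dilate_ball(m, r)), ball_count_oracle(r))
  }
})

test_that("closing is extensive, increasing in radius, and idempotent", {
  set.seed(42)
  for (i in 1:3) {
    m <- array(runif(18 * 18 * 12) < 0.25, c(18, 18, 12))
    c1 <- close_ball(m, 1.5)
    c2 <- close_ball(m, 3)
    expect_true(all(c1 | !m))            # extensive
    expect_true(all(c2 | !c1))           # increasing in radius
    expect_identical(close_ball(c1, 1.5), c1)   # idempotent
    expect_identical(close_ball(c2, 3), c2)
  }
})

test_that("erosion and dilation are adjoint on a test slab", {
  slab <- array(FALSE, c(20, 20, 20)); slab[5:16, 5:16, 5:16] <- TRUE
  er <- erode_ball(slab, 2)
  # erosion shrinks each face by the ball radius
  expect_equal(sum(er), 8^3)
  expect_true(all(dilate_ball(er, 2) | !er))
})

test_that("component labeling matches the flood-fill oracle", {
  set.seed(7)
  for (conn in c(6L, 26L)) {
    m <- array(runif(20^3) < 0.2, c(20, 20, 20))
    lab <- label_components(m, conn)
    sizes <- sort(as.integer(table(lab[lab > 0])))
    expect_identical(sizes, sort(oracle_component_sizes(m, conn)))
  }
  expect_error(label_components(array(TRUE, c(2, 2, 2)), 10), "connectivity")
})

test_that("fill_holes closes interior cavities only", {
  a <- array(FALSE, c(10, 10, 10))
  a[2:9, 2:9, 2:9] <- TRUE
  a[5, 5, 5] <- FALSE            # interior cavity
  a[2, 2, 2] <- FALSE            # corner notch, connected to outside
  f <- fill_holes(a)
  expect_true(f[5, 5, 5])
  expect_false(f[2, 2, 2])
  expect_equal(sum(f), sum(a) + 1)
})
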