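test_that("frequency-position map matches its closed form at reference points", {
  p <- freq_map_params()
  # direct closed-form evaluations (Greenwood constants)
  expect_equal(position_to_frequency(0, p), 165.4 * (1 - 0.88))
  expect_equal(position_to_frequency(1, p), 165.4 * (10^2.1 - 0.88))
  expect_equal(position_to_frequency(0.5, p), 165.4 * (10^1.05 - 0.88))
  expect_equal(frequency_to_position(2000, p), 0.530, tolerance = 1e-3)
  expect_equal(frequency_to_position(position_to_frequency(0, p), p), 0)
  expect_equal(frequency_to_position(position_to_frequency(1, p), p), 1)
  expect_error(position_to_frequency(1.2, p), "\\[0, 1\\]")
  expect_error(frequency_to_position(1e6, p), "range")
  expect_error(freq_map_params(k_off = 1), "k_off")
})

test_that("map is strictly monotone and the inverse round-trips to 1e-9", {
  p <- freq_map_params()
  x <- seq(0, 1, length.out = 2000)
  f <- position_to_frequency(x, p)
  expect_true(all(diff(f) > 0))
  set.seed(5)
  xr <- runif(10000)
  expect_lt(max(abs(frequency_to_position(position_to_frequency(xr, p), p) - xr)),
            1e-9)
  # from-base convention mirrors the axis
  pb <- freq_map_params(x_convention = "from_base")
  expect_equal(position_to_frequency(0, pb), position_to_frequency(1, p))
  expect_equal(position_to_frequency(1, pb), position_to_frequency(0, p))
})

test_that("octave partitions are contiguous, disjoint, and cover the range", {
  p <- freq_map_params()
  one <- octave_partitions(p, 1000, 2000)
  expect_equal(nrow(one), 1)
  expect_equal(one$x_lo, 0.400, tolerance = 1e-3)
  expect_equal(one$x_hi, 0.530, tolerance = 1e-3)

  parts <- octave_partitions(p)
  f0 <- position_to_frequency(0, p); f1 <- position_to_frequency(1, p)
  expect_equal(nrow(parts), ceiling(log2(f1 / f0)))
  # shared boundaries are exact, coverage telescopes exactly
  expect_identical(parts$x_lo[-1], parts$x_hi[-nrow(parts)])
  expect_equal(sum(parts$x_hi - parts$x_lo),
               frequency_to_position(f1, p) - frequency_to_position(f0, p))
})

test_that("band assignment follows the half-open tie rule and matches a linear scan", {
  p <- freq_map_params()
  parts <- octave_partitions(p)
  # boundary belongs to the higher band
  j <- 4
  expect_equal(assign_band(parts$x_lo[j], parts), parts$band_label[j])
  mid <- (parts$x_lo[j] + parts$x_hi[j]) / 2
  expect_equal(assign_band(mid, parts), parts$band_label[j])
  expect_error(assign_band(-0.05, parts), "coverage")
  set.seed(8)
  x <- runif(500)
  got <- assign_band(x, parts)
  scan <- vapply(x, function(xi) {
    hit <- which(xi >= parts$x_lo & xi < parts$x_hi)
    if (length(hit) == 0) hit <- nrow(parts)   # xi == 1 endpoint
    parts$band_label[hit[length(hit)]]
  }, "")
  expect_identical(got, scan)
})

test_that("band statistics compute mean and sample SD per partition", {
  p <- freq_map_params()
  parts <- octave_partitions(p)
  prof <- structure(data.frame(angle_deg = seq(0, 360, by = 10),
                               x_norm = seq(0, 1, length.out = 37),
                               width_mm = 1.0),
                    class = c("width_profile", "data.frame"))
  bs <- band_stats(prof, parts)
  expect_true(all(bs$mean_width_mm[bs$n_samples > 0] == 1.0))
  expect_true(all(bs$sd_width_mm[bs$n_samples > 1] == 0))
  # two samples in one band: hand arithmetic
  prof2 <- prof[1:2, ]
  prof2$x_norm <- c(0.45, 0.46)
  prof2$width_mm <- c(1, 2)
  class(prof2) <- c("width_profile", "data.frame")
  bs2 <- band_stats(prof2, parts)
  row <- bs2[bs2$n_samples == 2, ]
  expect_equal(row$mean_width_mm, 1.5)
  expect_equal(row$sd_width_mm, sqrt(0.5), tolerance = 1e-12)
  expect_true(any(bs2$n_samples == 0))
  expect_true(all(is.na(bs2$mean_width_mm[bs2$n_samples == 0])))
})

test_that("inclusions are localised to the band of their spiral position", {
  p <- freq_map_params()
  parts <- octave_partitions(p)
  # straight synthetic 'spiral': a line of length 10 mm along x
  centerline <- cbind(seq(0, 10, by = 0.01), 0, 0)
  mk_blob <- function(at_mm) {
    a <- array(FALSE, c(100, 5, 5))
    a[round(at_mm * 10) + (-2:2), 2:4, 2:4] <- TRUE
    label_mask(a, 100, c(0, -0.25, -0.25))
  }
  # blob at arc fraction 0.47 from the base -> x_norm 0.53 -> the 2 kHz band
  x2k <- frequency_to_position(2000, p)
  loc <- localize_inclusion(mk_blob((1 - x2k) * 10), centerline, parts, p)
  expect_equal(loc$band_label[1], assign_band(x2k, parts))
  expect_gt(loc$overlap_fraction[1], 0.9)
  expect_equal(sum(loc$overlap_fraction), 1)
  # a blob at the basal end maps to a high-frequency band (apex convention)
  loc_base <- localize_inclusion(mk_blob(0.3), centerline, parts, p)
  expect_gte(loc_base$overlap_fraction[1], 0.5)
  expect_gte(parts$f_lo_hz[match(loc_base$band_label[1], parts$band_label)],
             5000)
  # two equal blobs centred in two different bands split 0.5 / 0.5
  mid5 <- (parts$x_lo[5] + parts$x_hi[5]) / 2
  mid8 <- (parts$x_lo[8] + parts$x_hi[8]) / 2
  a <- mk_blob((1 - mid5) * 10)$data | mk_blob((1 - mid8) * 10)$data
  loc2 <- localize_inclusion(label_mask(a, 100, c(0, -0.25, -0.25)),
                             centerline, parts, p)
  expect_equal(loc2$overlap_fraction[1], 0.5)
  expect_equal(loc2$overlap_fraction[2], 0.5)
  expect_error(localize_inclusion(label_mask(array(FALSE, c(2, 2, 2)), 100),
                                  centerline, parts, p), "empty")
})

test_that("attach_position fills normalised positions from the midline arc", {
  ph <- phantom_small()
  fr <- phantom_frame(ph)
  pr <- attach_position(width_profile(extract_wall_contours(ph$masks$osl, fr)))
  expect_equal(pr$x_norm[1], 1)                       # basal end
  expect_equal(pr$x_norm[nrow(pr)], 0)                # apical end
  expect_true(all(diff(pr$x_norm) < 0))
  expect_equal(attr(pr, "total_arclength_mm"), ph$truth$total_arclength_mm,
               tolerance = 0.02)
})
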