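#' Greenwood-form frequency-position map parameters
#'
#' The cochlear frequency-position function `f(x) = A * (10^(a*x) - k)`,
#' where `x` is normalised position along the spiral. Defaults are
#' Greenwood's human organ-of-Corti constants (A = 165.4 Hz, a = 2.1,
#' k = 0.88) with `x` measured from the apex; a spiral-ganglion variant
#' is obtained by overriding the constants, and maps published with `x`
#' measured from the base are supported through
#' `x_convention = "from_base"` (which substitutes `1 - x`).
#'
#' @param A_hz scale constant in Hz (> 0).
#' @param a_exp exponent slope (> 0).
#' @param k_off additive offset in `[0, 1)` (so that `f(0) > 0`).
#' @param x_convention `"from_apex"` (default) or `"from_base"`.
#' @param total_length_mm optional physical spiral length, carried as
#'   metadata for converting arc length to normalised position.
#' @return object of class `freq_map_params`.
#' @export
freq_map_params <- function(A_hz = 165.4, a_exp = 2.1, k_off = 0.88,
                            x_convention = c("from_apex", "from_base"),
                            total_length_mm = NULL) {
  x_convention <- match.arg(x_convention)
  if (A_hz <= 0 || a_exp <= 0) .stopf("`A_hz` and `a_exp` must be positive")
  if (k_off < 0 || k_off >= 1) .stopf("`k_off` must lie in [0, 1)")
  structure(list(A_hz = A_hz, a_exp = a_exp, k_off = k_off,
                 x_convention = x_convention,
                 total_length_mm = total_length_mm),
            class = "freq_map_params")
}

.x_oriented <- function(x, params) {
  if (params$x_convention == "from_base") 1 - x else x
}

#' Map normalised position to characteristic frequency
#'
#' @param x normalised position(s) in `[0, 1]` (orientation per
#'   `params$x_convention`; under the default apex convention `x = 0` is
#'   the apex and `x = 1` the base).
#' @param params a [freq_map_params].
#' @return frequency in Hz.
#' @export
position_to_frequency <- function(x, params = freq_map_params()) {
  if (any(!is.finite(x)) || any(x < -1e-12) || any(x > 1 + 1e-12))
    .stopf("`x` must lie in [0, 1]")
  x <- pmin(pmax(x, 0), 1)
  xa <- .x_oriented(x, params)
  params$A_hz * (10^(params$a_exp * xa) - params$k_off)
}

#' Map frequency to normalised position (closed-form inverse)
#'
#' @param f_hz frequency/frequencies in Hz, within `[min(f), max(f)]` of
#'   the map's range over `x` in `[0, 1]`.
#' @param params a [freq_map_params].
#' @return normalised position(s) in `[0, 1]`.
#' @export
frequency_to_position <- function(f_hz, params = freq_map_params()) {
  lims <- range(params$A_hz * (10^(params$a_exp * c(0, 1)) - params$k_off))
  tol <- 1e-9 * max(1, lims[2])
  if (any(!is.finite(f_hz)) || any(f_hz < lims[1] - tol) || any(f_hz > lims[2] + tol))
    .stopf("frequency outside the map range [%.3f, %.1f] Hz", lims[1], lims[2])
  f_hz <- pmin(pmax(f_hz, lims[1]), lims[2])
  xa <- log10(f_hz / params$A_hz + params$k_off) / params$a_exp
  .x_oriented(xa, params)  # involution: same transform restores orientation
}

#' Octave-band partition of the tonotopic axis
#'
#' Builds contiguous frequency bands with boundaries at
#' `f_min * 2^j`, clipped to `f_max`, and converts each boundary to a
#' normalised position through the closed-form inverse map. Partitions
#' are half-open in `x` (`[x_lo, x_hi)`): a position exactly on a
#' boundary belongs to the higher-frequency band.
#'
#' @param params a [freq_map_params].
#' @param f_min_hz,f_max_hz band range in Hz; both must lie within the
#'   map's range. Defaults are the map endpoints `f(0)` and `f(1)`.
#' @return data.frame of class `tonotopic_partitions` with columns
#'   `band_label`, `f_lo_hz`, `f_hi_hz`, `x_lo`, `x_hi`, ordered by
#'   ascending frequency.
#' @export
octave_partitions <- function(params = freq_map_params(),
                              f_min_hz = NULL, f_max_hz = NULL) {
  lims <- sort(params$A_hz * (10^(params$a_exp * c(0, 1)) - params$k_off))
  if (is.null(f_min_hz)) f_min_hz <- lims[1]
  if (is.null(f_max_hz)) f_max_hz <- lims[2]
  if (f_min_hz >= f_max_hz) .stopf("`f_min_hz` must be < `f_max_hz`")
  n <- ceiling(log2(f_max_hz / f_min_hz) - 1e-12)
  f_lo <- f_min_hz * 2^(seq_len(n) - 1)
  f_hi <- pmin(f_min_hz * 2^seq_len(n), f_max_hz)
  x_lo <- frequency_to_position(f_lo, params)
  x_hi <- frequency_to_position(f_hi, params)
  if (params$x_convention == "from_base") { tmp <- x_lo; x_lo <- x_hi; x_hi <- tmp }
  lab <- sprintf("%s-%s", .fmt_hz(f_lo), .fmt_hz(f_hi))
  out <- data.frame(band_label = lab, f_lo_hz = f_lo, f_hi_hz = f_hi,
                    x_lo = x_lo, x_hi = x_hi, stringsAsFactors = FALSE)
  class(out) <- c("tonotopic_partitions", "data.frame")
  out
}

.fmt_hz <- function(f) {
  ifelse(f >= 1000, sprintf("%.3gkHz", f / 1000), sprintf("%.3gHz", f))
}

#' Assign a normalised position to its octave band
#'
#' Intervals are half-open `[x_lo, x_hi)` in the frequency sense: a
#' position exactly at a shared boundary belongs to the
#' higher-frequency band. The last band includes its upper endpoint.
#'
#' @param x normalised position(s).
#' @param partitions a partition table from [octave_partitions()].
#' @return character vector of band labels.
#' @export
assign_band <- function(x, partitions) {
  idx <- .band_index(x, partitions)
  if (anyNA(idx)) .stopf("position outside the partition coverage")
  partitions$band_label[idx]
}

# Vectorised band lookup; NA when not covered. Bands are half-open with the
# shared boundary belonging to the higher-frequency band; the extreme band at
# the high-frequency end keeps its outer endpoint.
.band_index <- function(x, partitions) {
  n <- nrow(partitions)
  from_apex <- n == 1L || partitions$x_lo[n] >= partitions$x_lo[1]
  if (from_apex) {
    # x ascending with frequency: left-closed intervals [x_lo, x_hi)
    bx <- c(partitions$x_lo, partitions$x_hi[n])
    i <- findInterval(x, bx, rightmost.closed = TRUE)
    i[i < 1L | i > n] <- NA_integer_
    i
  } else {
    # from-base maps: x descends with frequency, so intervals are
    # left-open (x_lo, x_hi] and the ascending-x order is row n .. row 1
    bx <- c(partitions$x_lo[n], rev(partitions$x_hi))
    i <- findInterval(x, bx, left.open = TRUE, rightmost.closed = TRUE)
    i[x == bx[1]] <- 1L  # lowest x endpoint belongs to the highest-f band
    i[i < 1L | i > n] <- NA_integer_
    n + 1L - i
  }
}

#' Attach normalised tonotopic positions to a width profile
#'
#' Converts the per-sample midline arc length of a width profile into the
#' normalised position `x` used by the frequency map. Under the default
#' apex convention `x = 0` at the apical end and `x = 1` at the basal
#' end; profile angles are unwrapped base -> apex, so
#' `x = 1 - s / s_total` with `s` the arc length from the basal end.
#'
#' @param profile a `width_profile` (see [width_profile()]).
#' @param params a [freq_map_params] (controls orientation).
#' @return the profile with its `x_norm` column filled.
#' @export
attach_position <- function(profile, params = freq_map_params()) {
  if (!inherits(profile, "width_profile")) .stopf("`profile` must be a width_profile")
  mid <- attr(profile, "midpoints_mm")
  if (is.null(mid)) .stopf("profile carries no midline points")
  s <- c(0, cumsum(sqrt(rowSums(diff(mid)^2))))
  stot <- s[length(s)]
  if (stot <= 0) .stopf("degenerate midline (zero arc length)")
  x_base <- s / stot                      # 0 at basal end, 1 at apical end
  profile$x_norm <- 1 - x_base            # apex convention: 0 at apex
  attr(profile, "total_arclength_mm") <- stot
  profile
}

#' Per-band width statistics
#'
#' Arithmetic mean and sample standard deviation of the OSL width over
#' the samples falling in each tonotopic band. Bands containing no
#' samples are reported with `n_samples = 0` and `NA` statistics.
#'
#' @param profile a `width_profile` with `x_norm` filled
#'   (see [attach_position()]).
#' @param partitions a partition table from [octave_partitions()].
#' @return data.frame with columns `band_label`, `f_lo_hz`, `f_hi_hz`,
#'   `x_lo`, `x_hi`, `mean_width_mm`, `sd_width_mm`, `n_samples`.
#' @export
band_stats <- function(profile, partitions) {
  if (anyNA(profile$x_norm)) .stopf("profile `x_norm` not filled; see attach_position()")
  idx <- .band_index(profile$x_norm, partitions)
  out <- partitions
  out$mean_width_mm <- NA_real_
  out$sd_width_mm <- NA_real_
  out$n_samples <- 0L
  for (j in seq_len(nrow(partitions))) {
    w <- profile$width_mm[which(idx == j)]
    out$n_samples[j] <- length(w)
    if (length(w) >= 1) out$mean_width_mm[j] <- mean(w)
    if (length(w) >= 2) out$sd_width_mm[j] <- sd(w)
    if (length(w) == 1) out$sd_width_mm[j] <- 0
  }
  class(out) <- "data.frame"
  out
}

#' Localise an inclusion (cochleolith) by tonotopic band
#'
#' Maps every voxel of an inclusion mask to the nearest point of the
#' cochlear centerline, converts that point's arc position to normalised
#' tonotopic position, and reports the fraction of inclusion volume
#' falling into each octave band.
#'
#' @param inclusion_mask binary [label_mask] of the inclusion (non-empty).
#' @param centerline matrix of 3D points (mm), ordered base -> apex.
#' @param partitions a partition table from [octave_partitions()].
#' @param params a [freq_map_params] (orientation).
#' @return data.frame with columns `band_label`, `overlap_fraction`,
#'   sorted by decreasing overlap; fractions sum to 1.
#' @export
localize_inclusion <- function(inclusion_mask, centerline, partitions,
                               params = freq_map_params()) {
  idx <- which(inclusion_mask$data != 0)
  if (length(idx) == 0) .stopf("inclusion mask is empty")
  pts <- .voxel_world(inclusion_mask, idx)
  s <- c(0, cumsum(sqrt(rowSums(diff(centerline)^2))))
  stot <- s[length(s)]
  # nearest centerline sample per voxel (blockwise to bound memory)
  nearest <- integer(nrow(pts))
  step <- max(1L, floor(2e6 / nrow(centerline)))
  for (b in seq(1, nrow(pts), by = step)) {
    bb <- b:min(b + step - 1, nrow(pts))
    d2 <- outer(rowSums(pts[bb, , drop = FALSE]^2), rowSums(centerline^2), "+") -
      2 * pts[bb, , drop = FALSE] %*% t(centerline)
    nearest[bb] <- max.col(-d2, ties.method = "first")
  }
  x <- 1 - s[nearest] / stot              # apex convention
  if (params$x_convention == "from_base") x <- 1 - x
  band <- .band_index(x, partitions)
  if (anyNA(band)) {
    # voxels slightly beyond the covered range are clamped to the end bands
    xr <- range(c(partitions$x_lo, partitions$x_hi))
    x <- pmin(pmax(x, xr[1]), xr[2] - 1e-9)
    band <- .band_index(x, partitions)
  }
  tab <- table(factor(partitions$band_label[band], levels = partitions$band_label))
  out <- data.frame(band_label = names(tab),
                    overlap_fraction = as.numeric(tab) / length(idx),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$overlap_fraction), , drop = FALSE]
  rownames(out) <- NULL
  out
}
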