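#' Intensity threshold rule
#'
#' A closed intensity interval `[lo, hi]` used to select voxels. `hi` may
#' be `Inf`; `lo` may be `-Inf` to select everything below `hi`.
#'
#' @param lo,hi interval bounds, `lo <= hi`.
#' @return object of class `threshold_rule`.
#' @export
threshold_rule <- function(lo, hi = Inf) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L || length(hi) != 1L)
    .stopf("`lo` and `hi` must be single numbers")
  if (is.na(lo) || is.na(hi)) .stopf("threshold bounds must not be NA")
  if (lo > hi) .stopf("invalid threshold rule: lo (%g) > hi (%g)", lo, hi)
  structure(list(lo = lo, hi = hi), class = "threshold_rule")
}

#' Threshold segmentation
#'
#' Selects all voxels whose intensity lies in `[rule$lo, rule$hi]` and
#' returns them as a binary label mask, reproducing interactive
#' threshold-adjustment segmentation of bone on micro-CT volumes.
#'
#' @param v a [voxel_volume].
#' @param rule a [threshold_rule], or a numeric of length 1 or 2 giving
#'   `lo` (and optionally `hi`).
#' @return a binary [label_mask].
#' @export
threshold_segment <- function(v, rule) {
  if (is.numeric(rule))
    rule <- threshold_rule(rule[1], if (length(rule) > 1) rule[2] else Inf)
  if (!inherits(rule, "threshold_rule")) .stopf("`rule` must be a threshold_rule")
  m <- v$data >= rule$lo & v$data <= rule$hi
  label_mask(m, v$voxel_size_um, v$origin_mm)
}

#' Remove small connected components
#'
#' Deletes every connected component with fewer than `min_voxels` voxels.
#' This is the reproducible surrogate for interactive brush-tool noise
#' cleanup: speckle produced by thresholding noisy scans is eliminated by
#' size, not by hand.
#'
#' @param m a binary [label_mask].
#' @param min_voxels minimum component size to keep (>= 1).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return a binary [label_mask]; never adds voxels, and is idempotent.
#' @export
remove_small_components <- function(m, min_voxels = 27L, connectivity = 26L) {
  if (min_voxels < 1) .stopf("`min_voxels` must be >= 1")
  lab <- label_components(m$data, connectivity)
  if (min_voxels == 1L) return(label_mask(lab > 0, m$voxel_size_um, m$origin_mm))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  out <- array(lab %in% keep & lab > 0L, dim = dim(lab))
  label_mask(out, m$voxel_size_um, m$origin_mm)
}

#' Subtract one label from another
#'
#' Voxelwise `a AND NOT b`: the recipe used to isolate soft tissue at the
#' cochlear apex, where bone voxels are subtracted from an
#' everything-above-background label.
#'
#' @param a,b binary [label_mask]s with identical geometry.
#' @return a binary [label_mask].
#' @export
subtract_labels <- function(a, b) {
  .check_same_geometry(a, b)
  label_mask(a$data != 0 & b$data == 0, a$voxel_size_um, a$origin_mm)
}

#' Mask a grayscale volume
#'
#' Voxelwise product of a volume with a binary mask, isolating the
#' labelled anatomy in the original intensities.
#'
#' @param v a [voxel_volume].
#' @param m a binary [label_mask] with the same geometry.
#' @return a [voxel_volume] equal to `v` on the mask and 0 elsewhere.
#' @export
apply_mask <- function(v, m) {
  .check_same_geometry(v, m)
  voxel_volume(v$data * (m$data != 0), v$voxel_size_um, v$origin_mm)
}
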