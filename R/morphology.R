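#' 3D binary morphology with Euclidean ball structuring elements
#'
#' Dilation, erosion and closing of 3D logical arrays with a discrete
#' Euclidean ball of (possibly non-integer) radius `radius_vox`, expressed
#' in voxels. The operations are computed through an exact squared
#' Euclidean distance transform, so the structuring element is the true
#' digital ball `{v : |v| <= r}` and the dilation/erosion pair forms a
#' morphological adjunction (hence `close_ball()` is idempotent).
#'
#' @param mask 3D logical/integer array (non-zero = foreground).
#' @param radius_vox ball radius in voxel units, >= 0.
#' @return 3D logical array of the same dimensions.
#' @name ball-morphology
NULL

.as_logical_arr <- function(mask) {
  if (is.list(mask) && !is.null(mask$data)) mask <- mask$data
  if (!is.array(mask) || length(dim(mask)) != 3L)
    .stopf("expected a 3D array")
  if (!is.logical(mask)) mask <- mask != 0
  mask
}

# squared distance (voxels^2) of every voxel to the nearest TRUE voxel
.edt_sq <- function(mask) {
  d <- dim(mask)
  array(.edt3d_sq(as.logical(mask), as.integer(d)), dim = d)
}

#' @rdname ball-morphology
#' @export
dilate_ball <- function(mask, radius_vox) {
  mask <- .as_logical_arr(mask)
  if (radius_vox < 0) .stopf("`radius_vox` must be >= 0")
  if (radius_vox == 0 || !any(mask)) return(mask)
  .edt_sq(mask) <= radius_vox^2 + 1e-9
}

#' @rdname ball-morphology
#' @export
erode_ball <- function(mask, radius_vox) {
  mask <- .as_logical_arr(mask)
  if (radius_vox < 0) .stopf("`radius_vox` must be >= 0")
  if (radius_vox == 0) return(mask)
  if (all(mask)) return(mask)  # no background: erosion only acts at borders of support
  mask & (.edt_sq(!mask) > radius_vox^2 + 1e-9)
}

#' @rdname ball-morphology
#' @export
close_ball <- function(mask, radius_vox) {
  erode_ball(dilate_ball(mask, radius_vox), radius_vox)
}

#' Label connected components of a 3D mask
#'
#' @param mask 3D logical/integer array.
#' @param connectivity one of 6 (faces), 18 (faces+edges) or 26 (full).
#' @return integer array of component labels (0 = background), numbered
#'   in scan order.
#' @export
label_components <- function(mask, connectivity = 26L) {
  mask <- .as_logical_arr(mask)
  if (!connectivity %in% c(6L, 18L, 26L))
    .stopf("`connectivity` must be 6, 18 or 26 (got %s)", connectivity)
  d <- dim(mask)
  array(.cc_label3d(as.logical(mask), as.integer(d), as.integer(connectivity)),
        dim = d)
}

#' Fill enclosed cavities of a 3D mask
#'
#' Background regions not connected (6-connectivity) to the array border
#' are interior cavities and are set to foreground.
#'
#' @param mask 3D logical/integer array.
#' @return 3D logical array with cavities filled.
#' @export
fill_holes <- function(mask) {
  mask <- .as_logical_arr(mask)
  lab <- label_components(!mask, connectivity = 6L)
  d <- dim(lab)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0]
  mask | !(lab %in% c(0L, border))
}
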