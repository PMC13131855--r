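#' Enhanced perivascular contrast (EPC) image
#'
#' Computes the voxel-wise ratio of the T1-weighted to the T2-weighted image
#' inside an analysis mask. CSF-filled perivascular spaces are dark on T1w
#' and bright on T2w, so they appear strongly hypointense on the ratio image,
#' which is what the downstream vesselness filter exploits.
#'
#' The T2w denominator is clamped from below at `floor` so the ratio stays
#' finite; by default the floor is 1e-6 times the in-mask median T2w
#' intensity.
#'
#' @param t1,t2 coregistered [image_volume()]s (or 3D arrays) on one grid.
#' @param mask binary analysis mask on the same grid.
#' @param floor positive clamp for the T2w denominator; NULL for the default.
#' @return An [image_volume()]: EPC inside the mask, 0 outside.
#' @export
compute_epc <- function(t1, t2, mask, floor = NULL) {
  check_same_grid(t1, t2, "t1", "t2")
  if (!identical(dim(mask), dim(t1))) stop("mask grid differs from t1/t2")
  m <- as.logical(mask != 0)
  if (!any(m)) stop("analysis mask is empty")
  t1a <- as_array3d(t1, "t1"); t2a <- as_array3d(t2, "t2")
  if (is.null(floor)) floor <- 1e-6 * stats::median(t2a[m])
  if (!is.finite(floor) || floor <= 0) stop("`floor` must be positive")
  epc <- array(0, dim = dim(t1a))
  epc[m] <- t1a[m] / pmax(t2a[m], floor)
  if (any(!is.finite(epc[m])))
    stop("non-finite EPC values inside the mask (check inputs)")
  image_volume(epc, voxel_size_of(t1), affine_of(t1))
}
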