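#' Tensor-element field container
#'
#' Bundles the Dxx, Dyy and Dzz diffusion-tensor element maps (mm^2/s) on a
#' shared template grid. Off-diagonal elements are not needed for the ALPS
#' index and are ignored if supplied.
#'
#' @param dxx,dyy,dzz [image_volume()]s on one grid/affine.
#' @param ... further element maps (dxy, dxz, dyz), accepted and ignored.
#' @return A `tensor_field` list.
#' @export
tensor_field <- function(dxx, dyy, dzz, ...) {
  if (missing(dxx) || missing(dyy) || missing(dzz))
    stop("dxx, dyy and dzz element maps are all required")
  check_same_grid(dxx, dyy, "dxx", "dyy")
  check_same_grid(dxx, dzz, "dxx", "dzz")
  structure(list(dxx = dxx, dyy = dyy, dzz = dzz,
                 affine = affine_of(dxx), grid_shape = dim(dxx)),
            class = "tensor_field")
}

#' Spherical ROI on a voxel grid
#'
#' Selects the voxels whose center lies within `diameter/2` (Euclidean, mm)
#' of a world-space center, given the grid's voxel-to-mm affine.
#'
#' @param center_mm length-3 world coordinate of the sphere center, mm.
#' @param diameter sphere diameter, mm.
#' @param affine 4x4 voxel-to-mm affine (0-based voxel indices).
#' @param grid_shape grid size in voxels.
#' @return Integer vector of linear voxel indices (1-based).
#' @export
make_sphere_roi <- function(center_mm, diameter, affine, grid_shape) {
  if (diameter <= 0) stop("diameter must be > 0")
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  r <- diameter / 2
  # bounding box in voxel space around the center
  vc <- world_to_voxel(affine, center_mm)[1, ]
  # conservative voxel radius from the affine's column norms
  scale <- apply(affine[1:3, 1:3], 2, function(col) sqrt(sum(col^2)))
  pad <- ceiling(r / min(scale)) + 1L
  lo <- pmax(floor(vc) - pad, 0); hi <- pmin(ceiling(vc) + pad, grid_shape - 1L)
  if (any(lo > hi))
    stop(sprintf("sphere at (%s) mm does not intersect the grid",
                 paste(center_mm, collapse = ", ")))
  g <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  w <- voxel_to_world(affine, g)
  d2 <- (w[, 1] - center_mm[1])^2 + (w[, 2] - center_mm[2])^2 +
    (w[, 3] - center_mm[3])^2
  sel <- g[d2 <= r^2, , drop = FALSE]
  if (nrow(sel) == 0)
    stop(sprintf("empty ROI at (%s) mm: no voxel center within %.3g mm",
                 paste(center_mm, collapse = ", "), r))
  (sel[, 1] + 1L) + sel[, 2] * grid_shape[1] +
    sel[, 3] * grid_shape[1] * grid_shape[2]
}

#' The four ALPS regions of interest
#'
#' 5 mm-diameter spheres at the level of the lateral ventricles: projection
#' fiber ROIs at (+/-25, -20, 28) mm and association fiber ROIs at
#' (+/-39, -20, 28) mm in template (MNI) space, mirror-symmetric in x.
#'
#' @param affine 4x4 voxel-to-mm affine of the template grid.
#' @param grid_shape grid size in voxels.
#' @param diameter ROI diameter, mm (default 5).
#' @return An `alps_roi_set`: list of linear-index vectors `proj_left`,
#'   `proj_right`, `assoc_left`, `assoc_right`, plus `centers` and
#'   `diameter`.
#' @export
alps_roi_set <- function(affine, grid_shape, diameter = 5) {
  centers <- list(proj_left = c(-25, -20, 28), proj_right = c(25, -20, 28),
                  assoc_left = c(-39, -20, 28), assoc_right = c(39, -20, 28))
  rois <- lapply(centers, make_sphere_roi, diameter = diameter,
                 affine = affine, grid_shape = grid_shape)
  structure(c(rois, list(centers = centers, diameter = diameter)),
            class = "alps_roi_set")
}

#' DTI-ALPS index from tensor-element maps
#'
#' Per hemisphere the index is the ratio of mean diffusivity along x in the
#' projection- and association-fiber ROIs to the mean diffusivity
#' perpendicular to the respective fiber bundles:
#'
#'   ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)
#'
#' where each term is the mean of the element map over that ROI's voxels
#' (Dyy is perpendicular in projection fibers, Dzz in association fibers).
#' The bilateral index is the mean of the left and right indices.
#'
#' @param field a [tensor_field()].
#' @param rois an [alps_roi_set()] on the same grid.
#' @return List: `left_index`, `right_index`, `bilateral_index`, and
#'   `roi_means` (per-ROI mean Dxx/Dyy/Dzz, mm^2/s).
#' @export
compute_alps <- function(field, rois) {
  if (!inherits(field, "tensor_field")) stop("`field` must be a tensor_field")
  if (!inherits(rois, "alps_roi_set")) stop("`rois` must be an alps_roi_set")
  roi_mean <- function(map, idx) mean(map[idx])
  means <- list(
    dxx_proj_left = roi_mean(field$dxx, rois$proj_left),
    dxx_assoc_left = roi_mean(field$dxx, rois$assoc_left),
    dyy_proj_left = roi_mean(field$dyy, rois$proj_left),
    dzz_assoc_left = roi_mean(field$dzz, rois$assoc_left),
    dxx_proj_right = roi_mean(field$dxx, rois$proj_right),
    dxx_assoc_right = roi_mean(field$dxx, rois$assoc_right),
    dyy_proj_right = roi_mean(field$dyy, rois$proj_right),
    dzz_assoc_right = roi_mean(field$dzz, rois$assoc_right)
  )
  side_index <- function(side) {
    num <- mean(c(means[[paste0("dxx_proj_", side)]],
                  means[[paste0("dxx_assoc_", side)]]))
    den <- mean(c(means[[paste0("dyy_proj_", side)]],
                  means[[paste0("dzz_assoc_", side)]]))
    if (!is.finite(den) || den <= 0)
      stop("non-positive perpendicular diffusivity in ", side, " hemisphere")
    num / den
  }
  left <- side_index("left"); right <- side_index("right")
  list(left_index = left, right_index = right,
       bilateral_index = (left + right) / 2,
       roi_means = means)
}
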