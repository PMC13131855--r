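#' 3D image volume with voxel geometry
#'
#' A minimal container for a 3D scalar grid: a numeric array plus the voxel
#' size in mm and a 4x4 voxel-to-mm affine (RNifti xform convention, 0-based
#' voxel indices). Used for T1w/T2w volumes, EPC ratio images, vesselness
#' maps, binary masks, and tensor-element maps.
#'
#' @param data 3D numeric or logical array.
#' @param voxel_size numeric length-1 or length-3, voxel edge length(s) in mm.
#' @param affine optional 4x4 voxel-to-mm affine; defaults to a diagonal
#'   scaling by `voxel_size` with the origin at voxel (0,0,0).
#' @return An `image_volume`: the array with `voxel_size` and `affine`
#'   attributes.
#' @export
image_volume <- function(data, voxel_size = 1, affine = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be positive and finite")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  } else {
    affine <- as.matrix(affine)
    if (!identical(dim(affine), c(4L, 4L))) stop("`affine` must be 4x4")
  }
  structure(data, voxel_size = voxel_size, affine = affine,
            class = c("image_volume", class(data)))
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x)
  vs <- attr(x, "voxel_size")
  cat(sprintf("<image_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

voxel_size_of <- function(x, default = 1) {
  vs <- attr(x, "voxel_size")
  if (is.null(vs)) rep_len(default, 3L) else rep_len(vs, 3L)
}

affine_of <- function(x) {
  af <- attr(x, "affine")
  if (is.null(af)) diag(c(voxel_size_of(x), 1)) else af
}

as_array3d <- function(x, what = "volume") {
  if (length(dim(x)) != 3L) stop("`", what, "` must be a 3D array")
  array(as.numeric(x), dim = dim(x))
}

check_same_grid <- function(a, b, what_a = "first", what_b = "second") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s and %s volumes have different grids (%s vs %s)",
                 what_a, what_b,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  af_a <- affine_of(a); af_b <- affine_of(b)
  if (max(abs(af_a - af_b)) > 1e-6)
    stop(sprintf("%s and %s volumes have different affines", what_a, what_b))
  invisible(TRUE)
}

#' Read a NIfTI file as an image volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume()] carrying the file's affine and voxel sizes.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D NIfTI volume: ", path)
  vs <- RNifti::pixdim(img)[seq_len(3)]
  image_volume(array(as.numeric(img), dim = d), voxel_size = vs,
               affine = RNifti::xform(img))
}

#' Write an image volume to NIfTI
#'
#' The affine is preserved in the sform/qform of the output header.
#'
#' @param vol an [image_volume()] or 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vs <- voxel_size_of(vol)
  af <- affine_of(vol)
  arr <- array(as.numeric(vol), dim = dim(vol))
  img <- RNifti::asNifti(arr, reference = NULL)
  RNifti::pixdim(img) <- vs
  RNifti::qform(img) <- structure(af, code = 2L)
  RNifti::sform(img) <- structure(af, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# world (mm) -> 0-based voxel coordinates of an affine
world_to_voxel <- function(affine, xyz_mm) {
  xyz_mm <- rbind(matrix(xyz_mm, ncol = 3))
  inv <- solve(affine)
  t(inv %*% rbind(t(xyz_mm), 1))[, 1:3, drop = FALSE]
}

# 0-based voxel coordinates -> world (mm)
voxel_to_world <- function(affine, ijk) {
  ijk <- rbind(matrix(ijk, ncol = 3))
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}
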