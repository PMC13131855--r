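# neighbor offsets for 6/18/26-connectivity (half set, to build each
# adjacency once)
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nrm <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nrm == 1, "18" = nrm >= 1 & nrm <= 2, "26" = nrm >= 1)
  off <- off[keep, , drop = FALSE]
  # keep one of each +/- pair
  lex <- off[, 1] * 9 + off[, 2] * 3 + off[, 3]
  off[lex > 0, , drop = FALSE]
}

#' Label connected components of a binary 3D mask
#'
#' Maximal connected components under 6-, 18- or 26-connectivity, computed
#' on the voxel adjacency graph. Labels are dense from 1 (ordered by each
#' component's smallest linear voxel index); background is 0.
#'
#' @param mask binary 3D array.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full neighborhood).
#' @return List: `labels` (integer array), `n` (component count),
#'   `voxels` (list of integer matrices of voxel indices, one per component).
#' @export
label_components <- function(mask, connectivity = 26) {
  connectivity <- as.integer(connectivity)
  d <- dim(mask)
  if (length(d) != 3L) stop("`mask` must be a 3D array")
  lin <- which(mask != 0)
  labels <- array(0L, dim = d)
  if (length(lin) == 0)
    return(list(labels = labels, n = 0L, voxels = list()))
  coords <- arrayInd(lin, d)
  off <- connectivity_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(off))) {
    nb <- sweep(coords, 2, off[r, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
      nb[, 3] >= 1L & nb[, 3] <= d[3]
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
      (nb[ok, 3] - 1L) * d[1] * d[2]
    hit <- match(nb_lin, lin)
    sel <- !is.na(hit)
    from <- c(from, which(ok)[sel])
    to <- c(to, hit[sel])
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  # dense labels ordered by smallest voxel index in each component
  first <- tapply(seq_along(lin), memb, function(ix) min(lin[ix]))
  relabel <- integer(length(first))
  relabel[order(first)] <- seq_along(first)
  lab <- relabel[memb]
  labels[lin] <- lab
  voxels <- lapply(seq_len(max(lab)), function(k)
    coords[lab == k, , drop = FALSE])
  list(labels = labels, n = max(lab), voxels = voxels)
}

#' Size and shape metrics of one connected component
#'
#' Volume is voxel count times voxel volume. Shape comes from the second
#' central moment matrix of the voxel centers (in mm): the principal axis
#' lengths are `4 * sqrt(eigenvalue)`, the lengths of an ellipsoid with
#' matching second moments, sorted descending. The diameter of a tubular
#' component is the mean of the two minor principal-axis lengths, i.e. its
#' average cross-sectional width.
#'
#' @param voxels integer matrix (n x 3) of voxel indices.
#' @param voxel_size voxel edge length(s), mm.
#' @return List: `volume` (mm^3), `principal_axis_lengths` (mm, descending),
#'   `diameter` (mm).
#' @export
component_metrics <- function(voxels, voxel_size = 1) {
  voxels <- rbind(matrix(as.numeric(voxels), ncol = 3))
  if (nrow(voxels) == 0) stop("component is empty")
  h <- rep_len(as.numeric(voxel_size), 3L)
  pts <- sweep(sweep(voxels, 2, 0.5), 2, h, "*")
  n <- nrow(pts)
  ctr <- colMeans(pts)
  cpts <- sweep(pts, 2, ctr)
  cov <- crossprod(cpts) / n
  ev <- sort(pmax(eigen(cov, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  lens <- 4 * sqrt(ev)
  list(volume = n * prod(h),
       principal_axis_lengths = lens,
       diameter = mean(lens[2:3]))
}
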