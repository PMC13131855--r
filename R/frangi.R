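#' Frangi filter parameters
#'
#' @param alpha sensitivity to the plate-vs-line ratio R_A (default 0.5).
#' @param beta sensitivity to the blob ratio R_B (default 0.5).
#' @param c structure-sensitivity constant; `"half_max_hessian_norm"`
#'   (default) sets c per scale to half the maximum in-mask Frobenius norm of
#'   the Hessian, or give an explicit positive value.
#' @param sigmas Gaussian scales in mm; default 0.4/0.6/0.8 mm targets
#'   perivascular spaces 1-3 voxels wide on 0.8 mm isotropic input.
#' @param polarity `"dark"` (default; dark tubes on bright background, the
#'   EPC polarity of CSF-filled spaces) or `"bright"`.
#' @return A `frangi_params` list.
#' @export
frangi_params <- function(alpha = 0.5, beta = 0.5,
                          c = "half_max_hessian_norm",
                          sigmas = c(0.4, 0.6, 0.8),
                          polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0")
  if (is.numeric(c) && c <= 0) stop("explicit c must be > 0")
  if (is.character(c) && !identical(c, "half_max_hessian_norm"))
    stop("c must be numeric or \"half_max_hessian_norm\"")
  if (length(sigmas) == 0 || any(sigmas <= 0))
    stop("sigmas must be a non-empty set of positive scales (mm)")
  structure(list(alpha = alpha, beta = beta, c = c,
                 sigmas = as.numeric(sigmas), polarity = polarity),
            class = "frangi_params")
}

# Sampled Gaussian kernel and its gamma-normalized derivatives at scale
# sigma (mm) on spacing h (mm). The 0th-order kernel is normalized to sum 1
# and the same normalization constant is applied to the derivative kernels.
gaussian_kernels <- function(sigma, h) {
  r <- max(1L, as.integer(ceiling(4 * sigma / h)))
  x <- (-r:r) * h
  g <- exp(-x^2 / (2 * sigma^2))
  z <- sum(g)
  g2 <- (x^2 / sigma^4 - 1 / sigma^2) * g / z
  list(g0 = g / z,
       g1 = (-x / sigma^2) * g / z,
       g2 = g2 - mean(g2),  # zero-sum: constant inputs give exactly zero
       radius = r)
}

# Convolution matrix with replicate (clamp-to-edge) boundary handling.
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in -r:r) {
    j <- pmin(pmax(i + o, 1L), n)
    # kernel tap at offset o multiplies source voxel i+o (clamped)
    K[cbind(i, j)] <- K[cbind(i, j)] + kernel[o + r + 1L]
  }
  K
}

# Separable convolution of a 3D array along one axis.
conv_axis <- function(vol, kernel, axis) {
  d <- dim(vol)
  K <- conv_matrix(d[axis], kernel)
  if (axis == 1L) {
    array(K %*% matrix(vol, d[1], d[2] * d[3]), dim = d)
  } else if (axis == 2L) {
    p <- aperm(vol, c(2, 1, 3))
    out <- array(K %*% matrix(p, d[2], d[1] * d[3]), dim = c(d[2], d[1], d[3]))
    aperm(out, c(2, 1, 3))
  } else {
    p <- aperm(vol, c(3, 1, 2))
    out <- array(K %*% matrix(p, d[3], d[1] * d[2]), dim = c(d[3], d[1], d[2]))
    aperm(out, c(2, 3, 1))
  }
}

# Eigenvalues of a field of symmetric 3x3 matrices (vectorized closed form,
# trigonometric method). Returns a list of three vectors sorted by |lambda|
# ascending: |l1| <= |l2| <= |l3|.
sym3_eigenvalues_abs_sorted <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  ok <- p > 0
  psafe <- ifelse(ok, p, 1)
  b11 <- (a11 - q) / psafe; b22 <- (a22 - q) / psafe; b33 <- (a33 - q) / psafe
  b12 <- a12 / psafe; b13 <- a13 / psafe; b23 <- a23 / psafe
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(1, pmax(-1, detB / 2))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)                 # largest
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)    # smallest
  e2 <- 3 * q - e1 - e3
  e1[!ok] <- q[!ok]; e2[!ok] <- q[!ok]; e3[!ok] <- q[!ok]
  # sort the triple by |lambda| with a 3-element compare-swap network
  M <- cbind(e1, e2, e3)
  swap <- function(M, i, j) {
    s <- abs(M[, i]) > abs(M[, j])
    tmp <- M[s, i]; M[s, i] <- M[s, j]; M[s, j] <- tmp
    M
  }
  M <- swap(M, 1, 2); M <- swap(M, 2, 3); M <- swap(M, 1, 2)
  list(l1 = M[, 1], l2 = M[, 2], l3 = M[, 3])
}

#' Hessian eigenvalue maps of a smoothed volume
#'
#' Computes the Hessian of the volume after Gaussian smoothing at scale
#' `sigma` (in mm, using mm-scaled separable derivative-of-Gaussian kernels,
#' replicate edges) and returns its eigenvalues at every voxel, ordered by
#' absolute value. Second derivatives are gamma-normalized with gamma = 1
#' (multiplied by sigma^2) so responses are comparable across scales.
#'
#' @param volume [image_volume()] or 3D array.
#' @param sigma Gaussian scale, mm.
#' @param voxel_size voxel size in mm (taken from `volume` when available).
#' @return List of 3D arrays `l1`, `l2`, `l3` with |l1| <= |l2| <= |l3|.
#' @export
hessian_eigenvalues <- function(volume, sigma, voxel_size = NULL) {
  if (sigma <= 0) stop("sigma must be > 0")
  vs <- if (is.null(voxel_size)) voxel_size_of(volume)
        else rep_len(as.numeric(voxel_size), 3L)
  v <- as_array3d(volume)
  k <- lapply(vs, function(h) gaussian_kernels(sigma, h))
  d2 <- function(ka, kb, kc)
    conv_axis(conv_axis(conv_axis(v, k[[1]][[ka]], 1L), k[[2]][[kb]], 2L),
              k[[3]][[kc]], 3L)
  hxx <- d2("g2", "g0", "g0"); hyy <- d2("g0", "g2", "g0")
  hzz <- d2("g0", "g0", "g2")
  hxy <- d2("g1", "g1", "g0"); hxz <- d2("g1", "g0", "g1")
  hyz <- d2("g0", "g1", "g1")
  s2 <- sigma^2  # gamma = 1 scale normalization
  ev <- sym3_eigenvalues_abs_sorted(s2 * hxx, s2 * hyy, s2 * hzz,
                                    s2 * hxy, s2 * hxz, s2 * hyz)
  shp <- dim(v)
  lapply(ev, array, dim = shp)
}

#' Multiscale Frangi vesselness map
#'
#' At each scale sigma the filter computes the Hessian eigenvalues
#' (|l1| <= |l2| <= |l3|) and the tube ratios R_A = |l2|/|l3| (plate vs
#' line), R_B = |l1|/sqrt(|l2 l3|) (blob deviation) and S = sqrt(sum l_i^2)
#' (second-order structure). For dark tubes the response is zero unless
#' l2 > 0 and l3 > 0 (signs reversed for bright tubes); otherwise
#'
#'   V = (1 - exp(-R_A^2 / 2 alpha^2)) * exp(-R_B^2 / 2 beta^2) *
#'       (1 - exp(-S^2 / 2 c^2))
#'
#' with c set per scale to half the maximum in-mask S (the default rule).
#' The final map is the maximum over scales, zero outside the mask.
#'
#' @param volume image to filter (typically an EPC image).
#' @param mask binary analysis mask (white matter minus lesions).
#' @param params a [frangi_params()].
#' @return An [image_volume()] vesselness map in `[0, 1]`, with attributes
#'   `scale_of_max` (mm scale attaining the maximum per voxel, NA outside the
#'   mask or where the response is 0) and `c_per_scale`.
#' @export
frangi_vesselness <- function(volume, mask, params = frangi_params()) {
  if (!inherits(params, "frangi_params")) stop("`params` must be frangi_params")
  if (!identical(dim(mask), dim(volume))) stop("mask grid differs from volume")
  m <- mask != 0
  if (!any(m)) stop("analysis mask is empty")
  vs <- voxel_size_of(volume)
  best <- array(0, dim = dim(volume))
  scale_of_max <- array(NA_real_, dim = dim(volume))
  c_used <- setNames(numeric(length(params$sigmas)),
                     paste0("sigma_", params$sigmas))
  dark <- params$polarity == "dark"
  for (si in seq_along(params$sigmas)) {
    sg <- params$sigmas[si]
    ev <- hessian_eigenvalues(volume, sg, vs)
    l1 <- ev$l1[m]; l2 <- ev$l2[m]; l3 <- ev$l3[m]
    a2 <- abs(l2); a3 <- abs(l3)
    S <- sqrt(l1^2 + l2^2 + l3^2)
    cval <- if (is.numeric(params$c)) params$c else max(S) / 2
    c_used[si] <- cval
    # degenerate scale: no second-order structure anywhere in the mask
    c_floor <- 1e-12 * max(1, max(abs(l3)))
    if (!is.finite(cval) || cval <= c_floor) {
      warning(sprintf("scale %.3g mm: zero Hessian norm in mask; scale skipped", sg))
      next
    }
    sign_ok <- if (dark) (l2 > 0 & l3 > 0) else (l2 < 0 & l3 < 0)
    ra2 <- ifelse(a3 > 0, (a2 / a3)^2, 0)
    rb2 <- ifelse(a2 * a3 > 0, l1^2 / (a2 * a3), 0)
    v <- (1 - exp(-ra2 / (2 * params$alpha^2))) *
      exp(-rb2 / (2 * params$beta^2)) *
      (1 - exp(-S^2 / (2 * cval^2)))
    v[!sign_ok] <- 0
    cur <- best[m]
    upd <- v > cur
    cur[upd] <- v[upd]
    best[m] <- cur
    sc <- scale_of_max[m]
    sc[upd] <- sg
    scale_of_max[m] <- sc
  }
  out <- image_volume(best, vs, affine_of(volume))
  attr(out, "scale_of_max") <- scale_of_max
  attr(out, "c_per_scale") <- c_used
  out
}

#' Threshold a vesselness map into a binary PVS mask
#'
#' A voxel joins the PVS mask iff it lies in the analysis mask and its
#' vesselness strictly exceeds the given percentile of the positive in-mask
#' vesselness values. The percentile is evaluated through the empirical CDF,
#' so with heavily tied values the whole tied block at the cut is kept
#' together (a voxel is selected iff the fraction of positive values less
#' than or equal to its own exceeds `percentile`/100).
#'
#' @param v vesselness map ([image_volume()] or array).
#' @param analysis_mask binary mask (white matter minus lesions).
#' @param percentile threshold percentile in (0, 100].
#' @return Logical 3D array; `TRUE` voxels form the PVS mask (always a
#'   subset of the analysis mask). The threshold value actually applied is
#'   in `attr(, "threshold")`.
#' @export
threshold_vesselness <- function(v, analysis_mask, percentile) {
  if (!identical(dim(analysis_mask), dim(v)))
    stop("analysis_mask grid differs from vesselness map")
  if (!is.numeric(percentile) || percentile <= 0 || percentile > 100)
    stop("percentile must be in (0, 100]")
  m <- analysis_mask != 0
  if (!any(m)) stop("analysis mask is empty")
  va <- as_array3d(v, "vesselness")
  pos <- va[m & va > 0]
  out <- array(FALSE, dim = dim(va))
  if (length(pos) == 0) {
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  spos <- sort(pos)
  n <- length(spos)
  # largest positive value whose ECDF is still <= percentile/100
  k <- findInterval(percentile / 100 * n + 1e-9, seq_len(n))
  thr <- if (k < 1) 0 else {
    # step down over ties so that ECDF(thr) <= percentile/100
    val <- spos[k]
    if (sum(spos <= val) / n > percentile / 100 + 1e-12) {
      below <- spos[spos < val]
      if (length(below)) max(below) else 0
    } else val
  }
  out[m & va > thr] <- TRUE
  attr(out, "threshold") <- thr
  out
}

#' One-call PVS segmentation from T1w/T2w volumes
#'
#' Convenience wrapper chaining [compute_epc()], [frangi_vesselness()] and
#' [threshold_vesselness()] over the union of the atlas region masks (minus
#' an optional lesion mask).
#'
#' @param t1,t2 coregistered volumes.
#' @param atlas a [region_atlas()] supplying the white-matter masks.
#' @param lesion_mask optional binary mask excluded from analysis.
#' @param params a [frangi_params()].
#' @param percentile thresholding percentile (see [threshold_vesselness()]).
#' @param epc_floor passed to [compute_epc()].
#' @return List: `epc`, `vesselness`, `pvs_mask`, `analysis_mask`,
#'   `metadata` (alpha, beta, c per scale, sigmas, percentile, threshold).
#' @export
segment_pvs <- function(t1, t2, atlas, lesion_mask = NULL,
                        params = frangi_params(), percentile = 98,
                        epc_floor = NULL) {
  analysis_mask <- atlas_union_mask(atlas)
  if (!is.null(lesion_mask)) {
    if (!identical(dim(lesion_mask), dim(analysis_mask)))
      stop("lesion mask grid differs from atlas")
    analysis_mask <- analysis_mask & !(lesion_mask != 0)
  }
  epc <- compute_epc(t1, t2, analysis_mask, floor = epc_floor)
  ves <- frangi_vesselness(epc, analysis_mask, params)
  pvs <- threshold_vesselness(ves, analysis_mask, percentile)
  list(epc = epc, vesselness = ves, pvs_mask = pvs,
       analysis_mask = analysis_mask,
       metadata = list(alpha = params$alpha, beta = params$beta,
                       c_rule = params$c,
                       c_per_scale = attr(ves, "c_per_scale"),
                       sigmas = params$sigmas, polarity = params$polarity,
                       percentile = percentile,
                       threshold = attr(pvs, "threshold")))
}
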