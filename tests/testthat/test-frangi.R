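make_dark_cylinder <- function(n = 32, r = 1.5, axis_len = 20, contrast = 0.75) {
  vol <- array(1, c(n, n, n))
  c0 <- n / 2
  for (k in 1:n) for (j in 1:n) {
    d <- sqrt((j - 0.5 - c0)^2 + (k - 0.5 - c0)^2)
    if (d <= r) vol[(c0 - axis_len / 2):(c0 + axis_len / 2), j, k] <- 1 - contrast
  }
  vol
}

make_dark_sphere <- function(n = 32, r = 1.5, contrast = 0.75) {
  vol <- array(1, c(n, n, n))
  c0 <- n / 2
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    d <- sqrt(sum((c(i, j, k) - 0.5 - c0)^2))
    if (d <= r) vol[i, j, k] <- 1 - contrast
  }
  vol
}

test_that("constant volumes have zero curvature and zero vesselness", {
  vol <- image_volume(array(3, c(16, 16, 16)))
  ev <- hessian_eigenvalues(vol, 1)
  expect_equal(max(abs(ev$l3)), 0)
  mask <- array(TRUE, dim(vol))
  expect_warning(v <- frangi_vesselness(vol, mask, frangi_params(sigmas = 1)),
                 "zero Hessian norm")
  expect_equal(max(v), 0)
})

test_that("smoothed Hessian of a separable quadratic matches the closed form", {
  # f(x) = x^2 in mm: Gaussian smoothing preserves the second derivative
  # (d^2/dx^2 of x^2 + sigma^2 is 2), so the gamma-normalized dominant
  # eigenvalue is 2 sigma^2 with the others near 0.
  n <- 21
  vol <- array(0, c(n, n, n))
  xc <- (1:n) - (n + 1) / 2
  for (k in 1:n) for (j in 1:n) vol[, j, k] <- xc^2
  sig <- 1.5
  ev <- hessian_eigenvalues(image_volume(vol), sig)
  ctr <- 11
  expect_equal(ev$l3[ctr, ctr, ctr], 2 * sig^2, tolerance = 0.01)
  expect_lt(abs(ev$l1[ctr, ctr, ctr]), 0.01)
  expect_lt(abs(ev$l2[ctr, ctr, ctr]), 0.01)
})

test_that("Hessian eigenvalues match a finite-difference oracle on a smooth field", {
  n <- 16; sig <- 1.5
  x <- (1:n) - 0.5
  vol <- array(0, c(n, n, n))
  for (k in 1:n) for (j in 1:n)
    vol[, j, k] <- sin(x / 3) + cos(x[j] / 4) * sin(x[k] / 5) +
      0.5 * sin((x + x[j]) / 6)
  # oracle: dense Gaussian smoothing written here, then central differences,
  # then eigen() per voxel
  r <- ceiling(4 * sig)
  gk <- exp(-((-r:r))^2 / (2 * sig^2)); gk <- gk / sum(gk)
  shift <- function(v, a, o) {
    d <- dim(v); i <- pmin(pmax(seq_len(d[a]) + o, 1), d[a])
    switch(a, v[i, , , drop = FALSE], v[, i, , drop = FALSE],
           v[, , i, drop = FALSE])
  }
  smooth1 <- function(v, a) {
    out <- array(0, dim(v))
    for (o in -r:r) out <- out + gk[o + r + 1] * shift(v, a, o)
    out
  }
  sm <- smooth1(smooth1(smooth1(vol, 1), 2), 3)
  d2 <- function(v, a, b) {
    if (a == b) shift(v, a, 1) - 2 * v + shift(v, a, -1)
    else (shift(shift(v, a, 1), b, 1) - shift(shift(v, a, 1), b, -1) -
            shift(shift(v, a, -1), b, 1) + shift(shift(v, a, -1), b, -1)) / 4
  }
  ev <- hessian_eigenvalues(image_volume(vol), sig)
  worst <- 0
  for (i in 7:10) for (j in 7:10) for (k in 7:10) {
    M <- sig^2 * matrix(c(
      d2(sm, 1, 1)[i, j, k], d2(sm, 1, 2)[i, j, k], d2(sm, 1, 3)[i, j, k],
      d2(sm, 1, 2)[i, j, k], d2(sm, 2, 2)[i, j, k], d2(sm, 2, 3)[i, j, k],
      d2(sm, 1, 3)[i, j, k], d2(sm, 2, 3)[i, j, k], d2(sm, 3, 3)[i, j, k]),
      3, 3)
    lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    lam <- lam[order(abs(lam))]
    got <- c(ev$l1[i, j, k], ev$l2[i, j, k], ev$l3[i, j, k])
    worst <- max(worst, max(abs(got - lam)))
  }
  expect_lt(worst, 0.02 * max(abs(ev$l3)))
})

test_that("eigenvalue and vesselness maps are equivariant to axis permutation", {
  set.seed(42)
  vol <- array(rnorm(14^3), c(14, 14, 14))
  ev <- hessian_eigenvalues(image_volume(vol), 1.2)
  evp <- hessian_eigenvalues(image_volume(aperm(vol, c(2, 3, 1))), 1.2)
  expect_equal(aperm(ev$l3, c(2, 3, 1)), evp$l3, tolerance = 1e-10)
  expect_equal(aperm(ev$l1, c(2, 3, 1)), evp$l1, tolerance = 1e-10)

  mask <- array(FALSE, c(14, 14, 14)); mask[3:12, 3:12, 3:12] <- TRUE
  pr <- frangi_params(sigmas = c(0.8, 1.2))
  v <- frangi_vesselness(image_volume(vol), mask, pr)
  vp <- frangi_vesselness(image_volume(aperm(vol, c(2, 3, 1))),
                          aperm(mask, c(2, 3, 1)), pr)
  expect_equal(aperm(array(as.numeric(v), dim(v)), c(2, 3, 1)),
               array(as.numeric(vp), dim(vp)), tolerance = 1e-10)
})

test_that("vesselness prefers tubes over spheres and respects polarity", {
  mask <- array(TRUE, c(32, 32, 32))
  pr <- frangi_params(sigmas = c(1, 1.5))
  tube <- frangi_vesselness(image_volume(make_dark_cylinder()), mask, pr)
  sphere <- frangi_vesselness(image_volume(make_dark_sphere()), mask, pr)
  expect_gt(tube[16, 16, 16], sphere[16, 16, 16])
  expect_gt(max(tube), max(sphere))

  bright <- 2 - make_dark_cylinder()  # bright tube on dark background
  vb <- frangi_vesselness(image_volume(bright), mask, pr)
  expect_equal(max(vb[12:20, 16, 16]), 0)
  vb2 <- frangi_vesselness(image_volume(bright), mask,
                           frangi_params(sigmas = c(1, 1.5),
                                         polarity = "bright"))
  expect_gt(vb2[16, 16, 16], 0)
})

test_that("vesselness stays in [0,1] and vanishes outside the mask", {
  ph <- generate_pvs_phantom(grid_shape = 40, seed = 5, snr = 10,
                             length_range = c(5, 8), radius_range = c(1, 1.5))
  mask <- csfclearance:::atlas_union_mask(ph$atlas)
  epc <- compute_epc(ph$t1, ph$t2, mask)
  v <- frangi_vesselness(epc, mask, frangi_params(sigmas = c(0.5, 1)))
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(v[!mask] == 0))
})

test_that("percentile thresholding handles ties, bounds and containment", {
  # 90 voxels at 0.1 and 10 at 0.9: the 95th percentile cut must select
  # exactly the 10 high voxels (sort-and-count oracle)
  v <- array(0, c(10, 10, 10))
  mask <- array(FALSE, c(10, 10, 10))
  mask[1:100] <- TRUE
  v[1:90] <- 0.1; v[91:100] <- 0.9
  pv <- threshold_vesselness(v, mask, 95)
  expect_equal(sum(pv), 10)
  expect_true(all(which(pv) == 91:100))

  expect_equal(sum(threshold_vesselness(v, mask, 100)), 0)

  set.seed(7)
  v2 <- array(runif(1000), c(10, 10, 10))
  mask2 <- array(runif(1000) < 0.5, c(10, 10, 10))
  p90 <- threshold_vesselness(v2, mask2, 90)
  p95 <- threshold_vesselness(v2, mask2, 95)
  expect_true(all(which(p95) %in% which(p90)))   # monotone in percentile
  expect_true(all(which(p90) %in% which(mask2))) # contained in mask
  # no-ties case: selects the top ~10% (n - floor(0.9 n) voxels)
  n_pos <- sum(v2[mask2] > 0)
  expect_equal(sum(p90), n_pos - floor(0.9 * n_pos))
  expect_error(threshold_vesselness(v2, array(FALSE, c(10, 10, 10)), 90),
               "empty")
  expect_error(threshold_vesselness(v2, mask2, 0), "percentile")
})

test_that("tubes in noise-free phantoms are detected at the phantom percentile", {
  ph <- generate_pvs_phantom(seed = 9, tubes_per_region = 1, snr = Inf)
  seg <- segment_pvs(ph$t1, ph$t2, ph$atlas,
                     params = frangi_params(sigmas = c(0.5, 0.75, 1)),
                     percentile = 10)
  met <- suppressMessages(regional_pvs_metrics(seg$pvs_mask, ph$atlas))
  expect_equal(met$count, ph$truth$true_count)
})
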