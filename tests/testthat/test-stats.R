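toy_cohort <- function(ages, groups) {
  data.frame(subject_id = sprintf("s%02d", seq_along(ages)),
             group = groups, age = ages,
             sex = rep(c("M", "F"), length.out = length(ages)),
             stringsAsFactors = FALSE)
}

test_that("age centering is exact and idempotent", {
  tab <- toy_cohort(c(40, 50, 60), c(0, 1, 0))
  cen <- center_age(tab)
  expect_equal(cen$age_centered, c(-10, 0, 10))
  expect_lt(abs(mean(cen$age_centered)), 1e-9)
  expect_equal(center_age(cen)$age_centered, cen$age_centered,
               tolerance = 1e-12)
  tab$age[2] <- NA
  expect_error(center_age(tab), "s02")
})

test_that("the normality screen flags heavy tails and not Gaussians", {
  flagged <- vapply(1:100, function(s) {
    set.seed(s)
    tab <- data.frame(y = exp(rnorm(110)))
    shapiro_screen(tab, "y")$non_normal
  }, logical(1))
  expect_gte(mean(flagged), 0.95)

  ps <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    shapiro_screen(data.frame(y = rnorm(50)), "y")$p
  }, numeric(1))
  expect_gt(median(ps), 0.05)

  deg <- shapiro_screen(data.frame(y = rep(2, 10)), "y")
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
})

test_that("Bonferroni thresholds reproduce the per-lobe values", {
  th <- bonferroni_thresholds(list(frontal = 22, parietal = 10,
                                   temporal = 16, occipital = 8,
                                   lateral_ventricle = 2, alps = 1))
  get <- function(f, col) th[[col]][th$family == f]
  expect_equal(get("frontal", "alpha_display"), 0.00227)
  expect_equal(get("parietal", "alpha_display"), 0.00500)
  expect_equal(get("temporal", "alpha_display"), 0.00313)
  expect_equal(get("occipital", "alpha_display"), 0.00625)
  expect_equal(get("lateral_ventricle", "alpha_display"), 0.025)
  expect_equal(get("alps", "alpha_display"), 0.05)
  expect_equal(get("frontal", "alpha_adjusted"), 0.05 / 22)
  # strictly decreasing in the number of masks
  th2 <- bonferroni_thresholds(setNames(as.list(1:30), paste0("f", 1:30)))
  expect_true(all(diff(th2$alpha_adjusted) < 0))
})

test_that("demographics: chi-square on a 2x2 sex table matches a hand oracle", {
  # 28 M / 21 F cases vs 29 M / 32 F controls
  tab <- data.frame(
    group = c(rep(1, 49), rep(0, 61)),
    sex = c(rep("M", 28), rep("F", 21), rep("M", 29), rep("F", 32)),
    age = 50)
  res <- demographic_tests(tab, categorical = "sex")
  # oracle: sum (O-E)^2/E over the four cells
  O <- matrix(c(28, 21, 29, 32), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(round(res$statistic, 2), 1.00)
  expect_equal(res$df, 1)
})

test_that("identical group distributions give null statistics", {
  tab <- data.frame(group = rep(c(0, 1), each = 20),
                    age = rep(c(40, 60), 20),
                    sex = rep(c("M", "F"), 20))
  res <- demographic_tests(tab, continuous = "age", categorical = "sex")
  expect_equal(res$statistic[res$variable == "age"], 0)
  expect_equal(res$statistic[res$variable == "sex"], 0)
})

test_that("an exact fit yields the minimum attainable permutation p", {
  tab <- center_age(toy_cohort(seq(30, 73, length.out = 12),
                               rep(c(0, 1), 6)))
  y <- 1 + 0.5 * tab$group + 0.02 * tab$age_centered +
    0.3 * tab$group * tab$age_centered  # zero residuals
  B <- 99
  res <- permutation_regression(y, tab, B = B, seed = 1)
  expect_equal(res$p_perm, rep(1 / (B + 1), 3))
})

test_that("permutation p equals the exhaustive enumeration oracle at n = 6", {
  set.seed(5)
  tab <- toy_cohort(c(34, 41, 55, 62, 48, 70), c(1, 1, 1, 0, 0, 0))
  tab <- center_age(tab)
  y <- c(1.2, 0.7, 1.9, 0.4, 1.1, 0.8)
  perms <- all_permutations(6)   # 720 permutations incl. identity
  res <- permutation_regression(y, tab, seed = 1, perm_indices = perms)

  # oracle: refit the full model per permuted response with lm()
  X <- cbind(1, tab$group, tab$age_centered, tab$group * tab$age_centered)
  t_of <- function(yy, j) {
    fit <- lm(yy ~ X - 1)
    summary(fit)$coefficients[j, "t value"]
  }
  for (j in 2:4) {
    Z <- X[, -j]
    fz <- lm(y ~ Z - 1)
    t_obs <- t_of(y, j)
    cnt <- 0
    for (b in seq_len(ncol(perms))) {
      ystar <- fitted(fz) + residuals(fz)[perms[, b]]
      # tie-safe comparison: exact ties (identity permutation) must count
      if (abs(t_of(ystar, j)) >= abs(t_obs) * (1 - 1e-12)) cnt <- cnt + 1
    }
    expect_equal(res$p_perm[j - 1], (1 + cnt) / (1 + ncol(perms)),
                 info = paste("term", j))
  }
})

test_that("permutation p-values are deterministic under the seed", {
  co <- generate_cohort(cohort_spec(seed = 7))
  a <- permutation_regression(co$outcome, co, B = 199, seed = 42)
  b <- permutation_regression(co$outcome, co, B = 199, seed = 42)
  expect_identical(a, b)
  c_ <- permutation_regression(co$outcome, co, B = 199, seed = 43)
  expect_false(identical(a$p_perm, c_$p_perm))
})

test_that("flipping the group coding flips the group beta", {
  co <- generate_cohort(cohort_spec(beta_group = 0.4, seed = 10))
  res <- permutation_regression(co$outcome, co, B = 99, seed = 1)
  co2 <- co; co2$group <- 1 - co2$group
  res2 <- permutation_regression(co2$outcome, co2, B = 99, seed = 1)
  # Group and Group:Age flip sign with unchanged |t|; the Age coefficient
  # changes meaning under recoding (it becomes the slope of the other group)
  for (tm in c("Group", "Group:Age")) {
    expect_equal(res2$beta[res2$term == tm], -res$beta[res$term == tm],
                 tolerance = 1e-10)
    expect_equal(abs(res2$t[res2$term == tm]), abs(res$t[res$term == tm]),
                 tolerance = 1e-10)
  }
})

test_that("type-I error is near nominal under the global null (screen run)", {
  # reduced-size screen; the full 1000-cohort calibration backs acceptance
  B <- 199; n_rep <- 200
  rej <- matrix(FALSE, n_rep, 3)
  for (r in seq_len(n_rep)) {
    co <- generate_cohort(cohort_spec(seed = 5000 + r))
    res <- permutation_regression(co$outcome, co, B = B, seed = 9000 + r)
    rej[r, ] <- res$p_perm < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates > 0.015 & rates < 0.095))
})

test_that("rank-deficient designs and constant outcomes are rejected", {
  tab <- toy_cohort(rep(50, 8), rep(c(0, 1), 4))  # no age variation
  expect_error(permutation_regression(rnorm(8), tab, B = 9, seed = 1),
               "rank deficient")
  tab2 <- toy_cohort(seq(30, 70, length.out = 8), rep(c(0, 1), 4))
  expect_error(permutation_regression(rep(1, 8), tab2, B = 9, seed = 1),
               "constant")
  expect_error(permutation_regression(rnorm(8), {
    t3 <- tab2; t3$group <- 1; t3
  }, B = 9, seed = 1), "both groups")
})

test_that("marker analysis maps families, thresholds and flags correctly", {
  co <- generate_cohort(cohort_spec(beta_group = 2, noise_sd = 0.5, seed = 3))
  co$alps <- generate_cohort(cohort_spec(seed = 77))$outcome
  manifest <- data.frame(
    outcome = c("outcome", "alps"),
    family = c("parietal", "alps"),
    mask = c("L-precuneus", "alps"),
    lobe = c("parietal", NA), hemisphere = c("L", NA),
    stringsAsFactors = FALSE)
  manifest$mask <- as.character(manifest$mask)
  fit <- run_marker_analysis(co, manifest, B = 199, seed = 2)
  expect_equal(nrow(fit$results), 6)  # 2 outcomes x 3 terms
  expect_equal(unique(fit$results$threshold[fit$results$family == "alps"]),
               0.05)
  grp <- fit$results[fit$results$outcome == "outcome" &
                       fit$results$term == "Group", ]
  expect_true(grp$p_perm == 1 / 200 && grp$significant)
  # determinism across calls
  fit2 <- run_marker_analysis(co, manifest, B = 199, seed = 2)
  expect_identical(fit$results$p_perm, fit2$results$p_perm)
  expect_error(run_marker_analysis(co, data.frame(outcome = "nope",
                                                  family = "f", mask = "m")),
               "nope")
})

test_that("an injected group-by-age effect is recovered in the right outcome", {
  co <- generate_cohort(cohort_spec(seed = 60))
  set.seed(61)
  for (k in 1:5) co[[paste0("null", k)]] <- rnorm(nrow(co), 0, 0.3)
  age_c <- co$age - mean(co$age)
  co$target <- 0.02 * co$group * age_c + rnorm(nrow(co), 0, 0.3)
  outs <- c(paste0("null", 1:5), "target")
  manifest <- data.frame(outcome = outs, family = "parietal",
                         mask = outs, stringsAsFactors = FALSE)
  fit <- run_marker_analysis(co[, c("subject_id", "group", "age", outs)],
                             manifest, B = 499, seed = 4)
  ia <- fit$results[fit$results$term == "Group:Age", ]
  expect_equal(ia$outcome[which.min(ia$p_perm)], "target")
  expect_lt(min(ia$p_perm), 0.05)
})

test_that("lobar summaries: a single significant row is 100% of its lobe", {
  res <- data.frame(term = "Group", lobe = "temporal", hemisphere = "L",
                    p_perm = 0.01)
  sm <- summarize_effects_by_lobe(res)
  expect_equal(sm$lobar$percent[sm$lobar$lobe == "temporal"], 100)
  expect_equal(sum(sm$lobar$n), 1)
  expect_equal(sm$laterality$n[sm$laterality$hemisphere == "L"], 1)
})
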