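#' Mean-center age in a cohort table
#'
#' Adds (or refreshes) `age_centered = age - mean(age)` over all included
#' subjects, improving interpretability of the group effect (evaluated at
#' the sample mean age) and reducing collinearity with the interaction.
#'
#' @param table cohort data.frame with an `age` column.
#' @return The table with an `age_centered` column; idempotent.
#' @export
center_age <- function(table) {
  if (!"age" %in% names(table)) stop("cohort table has no `age` column")
  bad <- which(!is.finite(table$age))
  if (length(bad)) {
    who <- if ("subject_id" %in% names(table))
      paste(table$subject_id[bad], collapse = ", ") else
        paste(bad, collapse = ", ")
    stop("missing age for subject(s): ", who)
  }
  table$age_centered <- table$age - mean(table$age)
  table
}

#' Shapiro-Wilk normality screen over outcome columns
#'
#' Advisory screen, as used before switching to permutation inference:
#' permutation models are fit regardless of the outcome's distribution.
#' Constant columns are flagged degenerate and get no p-value.
#'
#' @param table cohort data.frame.
#' @param outcomes character vector of outcome column names.
#' @param alpha flag threshold (default 0.05).
#' @return data.frame: `outcome`, `n`, `W`, `p`, `non_normal`, `degenerate`.
#' @export
shapiro_screen <- function(table, outcomes, alpha = 0.05) {
  rows <- lapply(outcomes, function(oc) {
    if (!oc %in% names(table)) stop("no such outcome column: ", oc)
    x <- table[[oc]]
    x <- x[is.finite(x)]
    if (length(x) < 3) stop("outcome ", oc, " has fewer than 3 observations")
    if (sd(x) == 0)
      return(data.frame(outcome = oc, n = length(x), W = NA_real_,
                        p = NA_real_, non_normal = NA, degenerate = TRUE))
    sw <- shapiro.test(x)
    data.frame(outcome = oc, n = length(x), W = unname(sw$statistic),
               p = sw$p.value, non_normal = sw$p.value < alpha,
               degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Design matrix for the three-term model y ~ group + age_c + group:age_c.
cohort_design <- function(table) {
  if (!"age_centered" %in% names(table)) table <- center_age(table)
  if (!all(table$group %in% c(0, 1)))
    stop("group must be coded 0 (control) / 1 (case)")
  X <- cbind(`(Intercept)` = 1, Group = table$group,
             Age = table$age_centered,
             `Group:Age` = table$group * table$age_centered)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  X
}

# t statistics of all coefficients for many response columns at once.
# X: n x p design, Y: n x B responses. Returns p x B matrix of t values.
ols_t_matrix <- function(X, Y, xtx_inv, qr_x) {
  cf <- qr.coef(qr_x, Y)                       # p x B
  res <- Y - X %*% cf
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df                # length B
  se <- sqrt(outer(diag(xtx_inv), sigma2))     # p x B
  tt <- cf / se
  tt[se == 0] <- sign(cf[se == 0]) * Inf
  tt
}

#' Permutation linear regression for group, age and group-by-age
#'
#' Fits `y ~ group + age_centered + group:age_centered` by ordinary least
#' squares and tests each term with a permutation null. The default scheme
#' is Freedman-Lane: for each term, the model without that term is fitted,
#' its residuals are permuted (seeded), added back onto the reduced-model
#' fits, the full model is refitted on each permuted response and the term's
#' |t| collected; the p-value is the add-one estimator
#' `(1 + #\{|t*| >= |t_obs|\}) / (1 + B)`, two-sided. `ter_braak` (permute
#' full-model residuals about the full fit) and `raw_y` (permute the
#' response) are available for comparison.
#'
#' Rows with a missing outcome are dropped listwise before fitting.
#'
#' @param y numeric outcome vector (one value per row of `table`).
#' @param table cohort data.frame with `group` (0/1) and `age` columns.
#' @param B number of permutations (default 5000).
#' @param seed integer seed; required for a reproducible null.
#' @param scheme permutation scheme (see above).
#' @param perm_indices optional n x B integer matrix of permutations to use
#'   (e.g. an exhaustive enumeration); overrides `B` and the seeded draw.
#' @return data.frame with one row per term (`Group`, `Age`, `Group:Age`):
#'   `beta`, `se`, `t`, `p_perm`, `B`; attributes `seed`, `scheme`, `n`.
#' @export
permutation_regression <- function(y, table, B = 5000, seed = 1,
                                   scheme = c("freedman_lane", "ter_braak",
                                              "raw_y"),
                                   perm_indices = NULL) {
  scheme <- match.arg(scheme)
  keep <- is.finite(y)
  y <- y[keep]
  table <- table[keep, , drop = FALSE]
  n <- length(y)
  if (n <= 4) stop("need more than 4 complete observations")
  if (sd(y) == 0) stop("outcome is constant")
  if (length(unique(table$group)) < 2) stop("both groups must be present")
  table <- center_age(table)
  X <- cohort_design(table)
  p <- ncol(X)
  qr_x <- qr(X)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  beta <- qr.coef(qr_x, y)
  res_full <- y - X %*% beta
  sigma2 <- sum(res_full^2) / (n - p)
  se <- sqrt(sigma2 * diag(xtx_inv))
  t_obs <- ifelse(se > 0, beta / se, sign(beta) * Inf)

  if (!is.null(perm_indices)) {
    perm_indices <- as.matrix(perm_indices)
    if (nrow(perm_indices) != n)
      stop("perm_indices must have one row per complete observation")
    B <- ncol(perm_indices)
  }

  terms <- c("Group", "Age", "Group:Age")
  cols <- match(terms, colnames(X))
  out <- with_private_seed(seed, {
    idx <- if (is.null(perm_indices))
      vapply(seq_len(B), function(b) sample.int(n), integer(n))
    else perm_indices
    p_perm <- numeric(length(terms))
    for (ti in seq_along(terms)) {
      j <- cols[ti]
      Ystar <- switch(scheme,
        freedman_lane = {
          Z <- X[, -j, drop = FALSE]
          qz <- qr(Z)
          fit_z <- qr.fitted(qz, y)
          res_z <- y - fit_z
          fit_z + matrix(res_z[idx], n, B)
        },
        ter_braak = {
          fit_full <- X %*% beta
          as.numeric(fit_full) + matrix(as.numeric(res_full)[idx], n, B)
        },
        raw_y = matrix(y[idx], n, B)
      )
      tstar <- ols_t_matrix(X, Ystar, xtx_inv, qr_x)[j, ]
      # count with a hair of slack so exact ties (e.g. the identity
      # permutation under exhaustive enumeration) are never lost to
      # floating-point noise between computation paths
      tie_tol <- 1 - 1e-12
      if (scheme == "ter_braak") {
        # null distribution of t about the observed fit; recenter
        p_perm[ti] <-
          (1 + sum(abs(tstar - t_obs[j]) >= abs(t_obs[j]) * tie_tol)) / (1 + B)
      } else {
        p_perm[ti] <- (1 + sum(abs(tstar) >= abs(t_obs[j]) * tie_tol)) / (1 + B)
      }
    }
    p_perm
  })
  res <- data.frame(term = terms, beta = beta[cols], se = se[cols],
                    t = t_obs[cols], p_perm = out, B = B,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  attr(res, "scheme") <- scheme
  attr(res, "n") <- n
  res
}

#' Bonferroni threshold scheme per family
#'
#' Thresholds are `alpha / n_masks` per family; the value used for
#' significance calls is unrounded, while `alpha_display` carries the
#' 3-significant-figure rounding used in reports (e.g. 0.05/22 -> 0.00227,
#' 0.05/16 -> 0.00313).
#'
#' @param families named integer vector or list: family -> number of masks.
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame: `family`, `n_masks`, `alpha_adjusted` (unrounded),
#'   `alpha_display` (3 significant figures).
#' @export
bonferroni_thresholds <- function(families, alpha = 0.05) {
  n_masks <- unlist(families)
  if (is.null(names(n_masks)) || any(!nzchar(names(n_masks))))
    stop("families must be named")
  if (any(n_masks < 1)) stop("n_masks must be >= 1")
  adj <- alpha / n_masks
  # round half away from zero at 3 significant figures (0.003125 -> 0.00313),
  # matching conventional reporting; signif() rounds half to even
  signif_up <- function(x, digits) {
    f <- 10^(digits - 1 - floor(log10(abs(x))))
    floor(x * f + 0.5) / f
  }
  data.frame(family = names(n_masks), n_masks = as.integer(n_masks),
             alpha_adjusted = adj,
             alpha_display = vapply(adj, signif_up, numeric(1), digits = 3),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Demographic group comparisons
#'
#' Classical equal-variance two-sample t-tests for continuous variables and
#' a Pearson chi-square test without continuity correction for categorical
#' variables (e.g. the 2x2 group-by-sex table).
#'
#' @param table cohort data.frame with a 0/1 `group` column.
#' @param continuous character vector of continuous column names.
#' @param categorical character vector of categorical column names.
#' @return data.frame: `variable`, `test` (`"t"` or `"chisq"`), `statistic`,
#'   `df`, `p`.
#' @export
demographic_tests <- function(table, continuous = character(),
                              categorical = character()) {
  if (length(unique(table$group)) < 2) stop("both groups must be present")
  rows <- list()
  for (v in continuous) {
    tt <- t.test(table[[v]] ~ table$group, var.equal = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, test = "t", statistic = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    tab <- table(table$group, table[[v]])
    cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, test = "chisq", statistic = unname(cs$statistic),
      df = unname(cs$parameter), p = cs$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation regression across all markers with family thresholds
#'
#' Runs one three-term permutation regression per outcome column and applies
#' the family-wise Bonferroni thresholds. The number of masks per family is
#' the number of distinct `mask` values in that family (so a lobe with 22
#' masks keeps threshold 0.05/22 even though three metrics are tested per
#' mask, and a paired-volume family of two masks gets 0.025).
#'
#' @param table cohort data.frame (`group`, `age`, plus outcome columns).
#' @param outcome_manifest data.frame with columns `outcome`, `family`,
#'   `mask`, and optionally `lobe`, `hemisphere`, `metric`. Every outcome
#'   column analyzed must appear exactly once.
#' @param B permutations per model (default 5000).
#' @param seed integer seed; outcome k uses `seed + k - 1`.
#' @param alpha nominal familywise alpha (default 0.05).
#' @param scheme permutation scheme, see [permutation_regression()].
#' @return List: `results` (one row per outcome x term with beta/se/t/
#'   p_perm, family threshold, `significant` and `uncorrected` flags),
#'   `thresholds` (the [bonferroni_thresholds()] table), `seed`, `B`.
#' @export
run_marker_analysis <- function(table, outcome_manifest, B = 5000, seed = 1,
                                alpha = 0.05, scheme = "freedman_lane") {
  need <- c("outcome", "family", "mask")
  if (!all(need %in% names(outcome_manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  missing_cols <- setdiff(outcome_manifest$outcome, names(table))
  if (length(missing_cols))
    stop("manifest outcome(s) not in the cohort table: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(outcome_manifest$outcome))
    stop("duplicated outcomes in manifest")
  table <- center_age(table)
  fam_masks <- tapply(outcome_manifest$mask, outcome_manifest$family,
                      function(m) length(unique(m)))
  thresholds <- bonferroni_thresholds(as.list(fam_masks), alpha)
  res <- vector("list", nrow(outcome_manifest))
  for (k in seq_len(nrow(outcome_manifest))) {
    oc <- outcome_manifest$outcome[k]
    pr <- permutation_regression(table[[oc]], table, B = B,
                                 seed = seed + k - 1L, scheme = scheme)
    thr <- thresholds$alpha_adjusted[
      thresholds$family == outcome_manifest$family[k]]
    pr$outcome <- oc
    pr$mask <- outcome_manifest$mask[k]
    pr$family <- outcome_manifest$family[k]
    pr$lobe <- if ("lobe" %in% names(outcome_manifest))
      outcome_manifest$lobe[k] else NA_character_
    pr$hemisphere <- if ("hemisphere" %in% names(outcome_manifest))
      outcome_manifest$hemisphere[k] else NA_character_
    pr$metric <- if ("metric" %in% names(outcome_manifest))
      outcome_manifest$metric[k] else NA_character_
    pr$threshold <- thr
    pr$significant <- pr$p_perm < thr
    pr$uncorrected <- pr$p_perm < alpha
    res[[k]] <- pr
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  list(results = results, thresholds = thresholds, seed = seed, B = B,
       scheme = scheme)
}

#' Lobar distribution and laterality of uncorrected-significant effects
#'
#' For each model term, tallies the rows significant at the uncorrected
#' level (`p_perm < alpha`) by lobe — reported as percentages of that term's
#' significant rows, rounded to 1 decimal — and by hemisphere.
#'
#' @param results data.frame with columns `term`, `lobe`, `hemisphere`,
#'   `p_perm` (e.g. from [run_marker_analysis()]`$results`).
#' @param alpha uncorrected significance level (default 0.05).
#' @return List: `lobar` (term, lobe, n, percent; percent NA when the term
#'   has no significant rows) and `laterality` (term, hemisphere, n).
#' @export
summarize_effects_by_lobe <- function(results, alpha = 0.05) {
  lobes <- c("frontal", "parietal", "temporal", "occipital")
  terms <- unique(results$term)
  sig <- results[results$p_perm < alpha, , drop = FALSE]
  lob <- do.call(rbind, lapply(terms, function(tm) {
    rows <- sig[sig$term == tm, , drop = FALSE]
    n <- vapply(lobes, function(lb) sum(rows$lobe == lb), integer(1))
    tot <- sum(n)
    data.frame(term = tm, lobe = lobes, n = n,
               percent = if (tot > 0) round(100 * n / tot, 1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  lat <- do.call(rbind, lapply(terms, function(tm) {
    rows <- sig[sig$term == tm, , drop = FALSE]
    data.frame(term = tm, hemisphere = c("L", "R"),
               n = c(sum(rows$hemisphere == "L"),
                     sum(rows$hemisphere == "R")),
               stringsAsFactors = FALSE)
  }))
  rownames(lob) <- rownames(lat) <- NULL
  list(lobar = lob, laterality = lat)
}
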