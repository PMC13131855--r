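#' Published uncorrected-significant WM-PVS regression terms
#'
#' The per-mask regression terms (metric, lobe, mask, term, beta, SE, t,
#' permutation p) reported as uncorrected-significant (p-perm < 0.05) for an
#' aging autism cohort, shipped as a plain-text fixture. Useful as a worked
#' input for [summarize_effects_by_lobe()]: the lobar percentages and the
#' left-lateralization of the interaction effects can be recomputed from it.
#'
#' @return data.frame with columns `metric`, `lobe`, `mask`, `term`,
#'   `beta`, `se`, `t`, `p_perm`, plus a derived `hemisphere` column.
#' @export
reported_pvs_terms <- function() {
  path <- system.file("extdata", "wm_pvs_reported_terms.tsv",
                      package = "csfclearance", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$hemisphere <- substr(tab$mask, 1, 1)
  tab
}
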