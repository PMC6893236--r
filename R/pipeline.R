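#' Run the full mega-analysis on a synthetic cohort
#'
#' Convenience driver chaining the modules: integration of all studies, MGP
#' estimation on the study-corrected matrix, differential expression with the
#' uncorrected and MGP-corrected model variants (optionally with the
#' leave-one-study-out jackknife), and the Spearman comparison of the two
#' rankings.
#'
#' @param cohort A \code{synthetic_cohort} (or a list with \code{studies} and
#'   \code{profiles} of the same shape).
#' @param jackknife Run the leave-one-study-out jackknife; default TRUE.
#' @param ... Passed to \code{\link{integrate_cohort}}.
#' @return List with \code{integrated}, \code{mgp}, \code{mgp_tests},
#'   \code{de_uncorrected}, \code{de_corrected} and
#'   \code{ranking_correlation}.
#' @export
run_mega_analysis <- function(cohort, jackknife = TRUE, ...) {
  integrated <- integrate_cohort(cohort$studies,
                                 sex_genes = cohort$profiles$sex_genes, ...)
  expr <- integrated$expr
  meta <- integrated$meta
  corrected <- correct_study_effects(expr, meta$study_id[
    match(colnames(expr), meta$sample_id)])
  mgp <- estimate_mgp(corrected, cohort$profiles$markers)
  mgp_tests <- test_mgp_difference(mgp, meta)
  fit <- if (jackknife) {
    function(m) jackknife_rank(expr, meta, mgps = m)
  } else {
    function(m) fit_all_genes(expr, meta, mgps = m)
  }
  de_unc <- fit(NULL)
  de_cor <- fit(mgp)
  list(integrated = integrated, mgp = mgp, mgp_tests = mgp_tests,
       de_uncorrected = de_unc, de_corrected = de_cor,
       ranking_correlation = compare_rankings(de_unc, de_cor))
}
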