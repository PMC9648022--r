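#' Published IHC diagnostic-performance reference rows
#'
#' The reported diagnostic performance of the IHC biomarkers for detecting
#' HSIL and HSIL+ in the source study's simultaneously evaluated sections:
#' sensitivity and specificity with exact 95% CIs, PPV, NPV (all percent)
#' and binary-test AUC.  These printed summaries are inputs to the
#' confusion-table reconstruction (see [reconstruct_confusion()]).
#'
#' @return data.frame with columns `panel`, `marker`, `sens`, `sens_lo`,
#'   `sens_hi`, `spec`, `spec_lo`, `spec_hi`, `ppv`, `npv`, `auc`.
#' @export
ihc_reference_metrics <- function() {
  path <- system.file("extdata", "ihc_reference_metrics.csv",
                      package = "cervstage", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}

#' Published Ki-67 / TOP2A concordance summary
#'
#' Reported agreement between the two proliferation markers: percent
#' agreement over all stages and within HSIL sections.
#'
#' @return list with `all_stages` and `hsil`, each `(agreement_pct, kappa)`.
#' @export
ihc_reference_concordance <- function() {
  list(all_stages = c(agreement_pct = 90.2, kappa = 0.80),
       hsil = c(agreement_pct = 97.1, kappa = 0.84))
}
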