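#' Optional replication targets from the published multi-center cohort
#'
#' The cohort-level quantities reported for the real MSK/TIMING/UM patients
#' (the DNA + clinical data of the public cBioPortal study
#' `rectal_msk_2022` plus institutional samples) cannot be recomputed from
#' synthetic data: they depend on the actual mutation calls and clinical
#' covariates. This table documents them as optional replication targets; the
#' analysis drivers switch from synthetic input to a downloaded cBioPortal
#' export when a real-data directory is supplied, and the pipeline then
#' recomputes each quantity with the listed function.
#'
#' @return Data.frame with one row per target: `quantity`, `value`,
#'   `pipeline_stage` (the exported function that recomputes it), and
#'   `requires_external_data` (always TRUE).
#' @export
replication_targets <- function() {
  data.frame(
    quantity = c(
      "weighted TMB contrast p-value (CR vs ICR, matching weights)",
      "tumor size contrast p-value (CR vs ICR)",
      "DNA-repair panel mutated fraction, CR (%)",
      "DNA-repair panel mutated fraction, ICR (%)",
      "co-occurring pairs, CR tumors",
      "co-occurring pairs, ICR tumors",
      "response model OR: tumor size (cm)",
      "response model OR: network-gene mutation",
      "response model OR: 1-2 co-occurring mutations",
      "response model OR: 3 or more co-occurring mutations",
      "response model Tjur R2",
      "response model AIC"),
    value = c(0.0369, 0.0069, 52, 34, 70, 38,
              0.79, 2.57, 1.57, 8.47, 0.14, 349.72),
    pipeline_stage = c(
      "compare_tmb_weighted", "weighted_ttest",
      "repair_panel_fraction", "repair_panel_fraction",
      "count_significant_pairs", "count_significant_pairs",
      "fit_response_model", "fit_response_model",
      "fit_response_model", "fit_response_model",
      "fit_response_model", "fit_response_model"),
    requires_external_data = TRUE,
    stringsAsFactors = FALSE
  )
}
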