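# Bundled reference tables from the PD1-PDL1 dimerizer screening campaign
# this workflow follows: the single-dose HTRF results with Vina scores for
# the 20 shortlisted compounds, and the per-fingerprint training/test R^2
# of the published classification models. Used as inputs by the triage
# helpers and the acceptance checks.

#' Benchmark single-dose HTRF screen results
#'
#' Percent PD1-PDL1 inhibition at 25 uM (mean and dispersion over
#' replicates) together with the best AutoDock Vina docking score for the
#' 20 compounds shortlisted by the reference screening campaign.
#'
#' @return Tibble: `compound`, `cayman_id`, `pct_inhibition`, `pct_sd`,
#'   `vina_score_kcal_mol`.
#' @export
htrf_screen_results <- function() {
  readr::read_csv(
    system.file("extdata", "htrf_screen_results.csv", package = "pdlscreen"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Benchmark fingerprint-model metrics
#'
#' Training and test R^2 of the six published fingerprint Random Forest
#' classifiers.
#'
#' @return Tibble: `fingerprint`, `r2_train`, `r2_test`.
#' @export
fingerprint_model_r2 <- function() {
  readr::read_csv(
    system.file("extdata", "fingerprint_model_r2.csv", package = "pdlscreen"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Triage single-dose screen results
#'
#' Applies the activity threshold used to pick compounds for dose-response
#' follow-up: percent inhibition at the single tested dose at or above
#' `threshold` (default 30%).
#'
#' @param results Tibble with a `pct_inhibition` column (e.g.
#'   [htrf_screen_results()]).
#' @param threshold Percent-inhibition cutoff.
#' @return The qualifying rows, ordered by descending inhibition.
#' @export
triage_single_dose <- function(results, threshold = 30) {
  stopifnot("pct_inhibition" %in% names(results))
  results %>%
    filter(.data$pct_inhibition >= threshold) %>%
    arrange(desc(.data$pct_inhibition))
}
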