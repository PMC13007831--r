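#' Load the packaged clinical cohort table
#'
#' Per-patient demographics, follow-up and Engel class for the published
#' 12-patient thalamic RNS cohort.
#'
#' @return Data frame, one row per patient.
#' @export
load_cohort_clinical <- function() {
  utils::read.csv(system.file("extdata", "cohort_clinical.csv",
                              package = "thalnet"),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Load the packaged imaging cohort table
#'
#' Per-patient SOZ regions, stimulation settings (polarity-string notation),
#' per-side VTA volumes, streamline counts and seizure frequencies.
#'
#' @return Data frame, one row per patient.
#' @export
load_cohort_imaging <- function() {
  utils::read.csv(system.file("extdata", "cohort_imaging.csv",
                              package = "thalnet"),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Recompute the published cohort's derived quantities from its raw columns
#'
#' From the packaged tables this recomputes, per patient, the rounded
#' activated percent from the printed streamline count pair, the seizure
#' reduction from the pre/post frequencies, and the response category; and,
#' over the cohort, the responder/partial/nonresponder counts, the mean age,
#' and the Spearman correlation between the activation ratio (count pairs,
#' not the rounded percent column) and the reported percent reduction.
#'
#' @return List with `table` (per-patient recomputation and match flags),
#'   `percent_matches`, `response_counts`, `mean_age_rounded`, `spearman`.
#' @export
published_cohort_report <- function() {
  img <- load_cohort_imaging()
  clin <- load_cohort_clinical()
  ratio <- img$n_activated / img$n_streamlines
  pct <- round_half_up(100 * ratio)
  red_recomputed <- seizure_reduction(img$preop_per_month,
                                      img$postop_per_month)
  response <- classify_response(img$reduction_pct)
  tab <- data.frame(case = img$case,
                    activation_ratio = ratio,
                    percent_recomputed = pct,
                    percent_reported = img$percent_activated,
                    percent_match = pct == img$percent_activated,
                    reduction_recomputed = red_recomputed,
                    reduction_reported = img$reduction_pct,
                    response = response,
                    stringsAsFactors = FALSE)
  counts <- c(responder = sum(response == "responder"),
              partial = sum(response == "partial"),
              nonresponder = sum(response == "nonresponder"))
  sp <- spearman_test(ratio, img$reduction_pct)
  list(table = tab,
       percent_matches = sum(tab$percent_match),
       response_counts = counts,
       mean_age_rounded = round_half_up(mean(clin$age_years)),
       spearman = sp)
}
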