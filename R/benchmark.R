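#' Bundled reference-cohort benchmark tables
#'
#' Two small plain-text tables ship with the package for worked examples
#' and sanity checks of the summary arithmetic: the per-subject accuracy
#' (percent) and Cohen's kappa reported for a seven-subject noncontact
#' staging evaluation on sleep-disordered-breathing patients, and the
#' pooled Wake/REM/NREM epoch counts of a 17-night healthy-subject corpus
#' scored at 60-s epochs.
#'
#' @return A list with tibbles `performance` (subject, accuracy_pct,
#'   kappa) and `epoch_counts` (stage, count), plus `total_epochs` (the
#'   published corpus total, carried as printed).
#' @export
#' @examples
#' b <- benchmark_cohort()
#' summarize_performance(b$performance$accuracy_pct, b$performance$kappa)
benchmark_cohort <- function() {
  perf <- readr::read_csv(
    system.file("extdata", "sdb_cohort_performance.csv", package = "somnosense"),
    show_col_types = FALSE
  )
  counts <- readr::read_csv(
    system.file("extdata", "reference_cohort_epochs.csv", package = "somnosense"),
    show_col_types = FALSE
  )
  total <- counts$count[counts$stage == "Total"]
  list(
    performance = perf,
    epoch_counts = counts[counts$stage != "Total", ],
    # the published total; note the published per-stage counts sum to two
    # epochs fewer, so the total is carried separately rather than derived
    total_epochs = total
  )
}

#' Stage percentages from epoch counts
#'
#' @param counts Tibble with `stage` and `count` columns.
#' @param total Denominator; defaults to the column sum.
#' @return Tibble with an added `percent` column (of `total`).
#' @export
stage_percentages <- function(counts, total = sum(counts$count)) {
  dplyr::mutate(counts, percent = 100 * .data$count / total)
}
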