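#' Epoch-by-epoch agreement: accuracy and Cohen's Kappa
#'
#' Computes the overall agreement
#' \deqn{p_0 = \sum_{c \in \{Wake, NREM, REM\}} TP_c / T,}
#' the chance agreement
#' \deqn{p_e = \sum_c \frac{TP_c + FP_c}{T} \cdot \frac{TP_c + FN_c}{T},}
#' and \eqn{\kappa = (p_0 - p_e)/(1 - p_e)}. In the degenerate case
#' \eqn{p_e = 1} (both raters constant on the same class when in perfect
#' agreement), \eqn{\kappa} is 1 if \eqn{p_0 = 1} and 0 otherwise.
#'
#' @param predicted,reference Hypnograms (or stage vectors) of equal length.
#' @return An `agreement_summary` list: `per_class` tibble (TP/FP/FN per
#'   class), `total`, `p0`, `pe`, `kappa`.
#' @export
#' @examples
#' agreement_metrics(c("Wake", "NREM"), c("Wake", "REM"))$p0
agreement_metrics <- function(predicted, reference) {
  p <- stage_labels(predicted)
  r <- stage_labels(reference)
  if (length(p) != length(r)) {
    rlang::abort("predicted and reference hypnograms differ in length")
  }
  if (length(p) == 0) rlang::abort("empty hypnograms")
  total <- length(p)
  per_class <- purrr::map_dfr(SLEEP_STAGES, function(cl) {
    tibble::tibble(
      stage = cl,
      tp = sum(p == cl & r == cl),
      fp = sum(p == cl & r != cl),
      fn = sum(p != cl & r == cl)
    )
  })
  p0 <- sum(per_class$tp) / total
  pe <- sum(((per_class$tp + per_class$fp) / total) *
              ((per_class$tp + per_class$fn) / total))
  kappa <- if (pe >= 1) {
    if (p0 >= 1) 1 else 0
  } else {
    (p0 - pe) / (1 - pe)
  }
  structure(
    list(per_class = per_class, total = total, p0 = p0, pe = pe, kappa = kappa),
    class = "agreement_summary"
  )
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(
    "# Agreement over %d epochs: accuracy %.4f, chance %.4f, kappa %.4f\n",
    x$total, x$p0, x$pe, x$kappa
  ))
  print(x$per_class)
  invisible(x)
}

#' Summarize per-recording staging performance
#'
#' Arithmetic means and standard deviations (population divisor n) of
#' per-recording accuracies and kappas.
#'
#' @param accuracy Numeric vector of per-recording accuracies.
#' @param kappa Numeric vector of per-recording kappas (same length), or
#'   `NULL` to summarize accuracy only.
#' @return One-row tibble with `mean_accuracy`, `sd_accuracy`,
#'   `mean_kappa`, `sd_kappa`, `n`.
#' @export
summarize_performance <- function(accuracy, kappa = NULL) {
  if (length(accuracy) == 0) rlang::abort("no per-recording values to summarize")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  tibble::tibble(
    mean_accuracy = mean(accuracy),
    sd_accuracy = pop_sd(accuracy),
    mean_kappa = if (is.null(kappa)) NA_real_ else mean(kappa),
    sd_kappa = if (is.null(kappa)) NA_real_ else pop_sd(kappa),
    n = length(accuracy)
  )
}
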