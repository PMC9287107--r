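#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-fold summary of a LOOCV staging run
#'
#' @param x A `staging_cv` object from [loocv_stage()].
#' @param ... Unused.
#' @return Tibble with one row per recording: epoch count, accuracy and
#'   kappa before (`_pre`) and after (`_post`) stage fusion.
#' @method tidy staging_cv
#' @export
tidy.staging_cv <- function(x, ...) {
  purrr::map_dfr(x$folds, function(f) {
    tibble::tibble(
      recording = f$recording,
      n_epochs = f$agreement_pre$total,
      accuracy_pre = f$agreement_pre$p0,
      kappa_pre = f$agreement_pre$kappa,
      accuracy_post = f$agreement_post$p0,
      kappa_post = f$agreement_post$kappa
    )
  })
}

#' Pooled one-row summary of a LOOCV staging run
#'
#' @inheritParams tidy.staging_cv
#' @return One-row tibble with pooled accuracy/kappa pre and post fusion,
#'   classifier id and fold count.
#' @method glance staging_cv
#' @export
glance.staging_cv <- function(x, ...) {
  tibble::tibble(
    classifier = x$classifier,
    n_recordings = length(x$folds),
    n_epochs = x$pooled_pre$total,
    accuracy_pre = x$pooled_pre$p0,
    kappa_pre = x$pooled_pre$kappa,
    accuracy_post = x$pooled_post$p0,
    kappa_post = x$pooled_post$kappa
  )
}

#' One-row summary of an agreement computation
#'
#' @param x An `agreement_summary` from [agreement_metrics()].
#' @param ... Unused.
#' @return One-row tibble with `n_epochs`, `p0`, `pe`, `kappa`.
#' @method glance agreement_summary
#' @export
glance.agreement_summary <- function(x, ...) {
  tibble::tibble(n_epochs = x$total, p0 = x$p0, pe = x$pe, kappa = x$kappa)
}

#' Per-class counts of an agreement computation
#'
#' @inheritParams glance.agreement_summary
#' @return Tibble with TP/FP/FN per stage.
#' @method tidy agreement_summary
#' @export
tidy.agreement_summary <- function(x, ...) x$per_class
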