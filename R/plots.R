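#' Plot a hypnogram
#'
#' Classic staircase hypnogram: time on the x axis, stages ordered Wake on
#' top, then REM, then NREM.
#'
#' @param object A [hypnogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hypnogram
#' @export
autoplot.hypnogram <- function(object, ...) {
  el <- epoch_len(object)
  df <- tibble::tibble(
    time_h = (object$epoch - 1) * el / 3600,
    stage = factor(object$stage, levels = rev(SLEEP_STAGES))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$stage, group = 1)) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::labs(x = "Time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a stretch of a pressure recording
#'
#' @param object A [raw_recording()].
#' @param from,to Time window to show, seconds (defaults to the first 30 s).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pressure_recording
#' @export
autoplot.pressure_recording <- function(object, from = 0, to = NULL, ...) {
  to <- to %||% min(max(object$time_s), from + 30)
  df <- dplyr::filter(tibble::as_tibble(object),
                      .data$time_s >= from, .data$time_s <= to)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude") +
    ggplot2::theme_minimal()
}

#' Plot per-recording LOOCV performance before and after fusion
#'
#' @param object A `staging_cv` from [loocv_stage()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot staging_cv
#' @export
autoplot.staging_cv <- function(object, ...) {
  df <- tidy.staging_cv(object) |>
    tidyr::pivot_longer(c("accuracy_pre", "accuracy_post"),
                        names_to = "stage", values_to = "accuracy") |>
    dplyr::mutate(stage = ifelse(.data$stage == "accuracy_pre",
                                 "before fusion", "after fusion"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recording, y = .data$accuracy,
                                   fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Epoch accuracy", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot feature-group importance shares
#'
#' @param importance Output of [feature_importance()].
#' @param by `"group"` (default) or `"feature"` (top 15 features).
#' @return A ggplot.
#' @export
plot_feature_importance <- function(importance, by = c("group", "feature")) {
  by <- match.arg(by)
  if (by == "group") {
    df <- importance$groups
    ggplot2::ggplot(df, ggplot2::aes(
      x = stats::reorder(.data$group, -.data$share), y = .data$share
    )) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "Importance share") +
      ggplot2::theme_minimal()
  } else {
    df <- dplyr::slice_max(importance$per_feature, .data$importance, n = 15)
    ggplot2::ggplot(df, ggplot2::aes(
      x = stats::reorder(.data$feature, .data$importance),
      y = .data$importance, fill = .data$group
    )) +
      ggplot2::geom_col() +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "Importance share", fill = NULL) +
      ggplot2::theme_minimal()
  }
}
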