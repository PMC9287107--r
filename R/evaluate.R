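# Ground-truth comparison utilities for simulator-driven validation.

#' Match detected events to ground-truth events
#'
#' Greedy nearest-neighbour matching: each truth event takes the closest
#' unused detected event within `tol_s`.
#'
#' @param detected,truth Numeric vectors of event times, seconds.
#' @param tol_s Matching tolerance, seconds.
#' @return Tibble with `truth_time`, `detected_time` (`NA` = missed).
#' @export
match_events <- function(detected, truth, tol_s) {
  detected <- sort(detected)
  used <- rep(FALSE, length(detected))
  det <- vapply(truth, function(tt) {
    if (length(detected) == 0) return(NA_real_)
    d <- abs(detected - tt)
    d[used] <- Inf
    i <- which.min(d)
    if (length(i) == 0 || d[i] > tol_s) return(NA_real_)
    used[i] <<- TRUE
    detected[i]
  }, numeric(1))
  tibble::tibble(truth_time = truth, detected_time = det)
}

in_intervals <- function(times, intervals, margin = 0) {
  if (nrow(intervals) == 0 || length(times) == 0) return(rep(FALSE, length(times)))
  out <- rep(FALSE, length(times))
  for (i in seq_len(nrow(intervals))) {
    out <- out | (times >= intervals$start_s[i] - margin &
                    times <= intervals$end_s[i] + margin)
  }
  out
}

#' Interval-recovery errors against simulator ground truth
#'
#' Matches detected events to truth events and scores the recovered
#' inter-event intervals over truth intervals lying fully outside movement
#' (with a safety margin of one mask window).
#'
#' @param detected An [event_series()] or numeric times.
#' @param truth_times Ground-truth event times.
#' @param movement Ground-truth movement tibble (`start_s`, `end_s`), or
#'   `NULL`.
#' @param tol_s Event matching tolerance.
#' @param margin_s Exclusion margin around movement intervals.
#' @return List: `time_mae_s` (mean absolute event-time error over
#'   matches), `interval_rmse_s`, `n_intervals`, `recall`.
#' @export
evaluate_event_recovery <- function(detected, truth_times, movement = NULL,
                                    tol_s = 0.5, margin_s = 2) {
  det_times <- if (is.data.frame(detected)) detected$time_s else detected
  m <- match_events(det_times, truth_times, tol_s)
  ok <- !is.na(m$detected_time)
  time_mae <- if (any(ok)) mean(abs(m$detected_time[ok] - m$truth_time[ok])) else NA_real_

  pair_ok <- ok[-length(ok)] & ok[-1]
  if (!is.null(movement) && nrow(movement) > 0) {
    clear <- !in_intervals(m$truth_time[-length(ok)], movement, margin_s) &
      !in_intervals(m$truth_time[-1], movement, margin_s)
    pair_ok <- pair_ok & clear
  }
  truth_iv <- diff(m$truth_time)[pair_ok]
  det_iv <- diff(m$detected_time)[pair_ok]
  rmse <- if (length(truth_iv) > 0) sqrt(mean((det_iv - truth_iv)^2)) else NA_real_
  list(
    time_mae_s = time_mae,
    interval_rmse_s = rmse,
    n_intervals = length(truth_iv),
    recall = mean(ok)
  )
}

#' Window-level movement-detection score against ground truth
#'
#' Labels each mask window as true-movement when it overlaps any
#' ground-truth movement interval and scores the detected states with
#' precision, recall and F1.
#'
#' @param mask A [detect_movement()] mask.
#' @param movement Ground-truth movement tibble (`start_s`, `end_s`).
#' @return List with `precision`, `recall`, `f1`, `n_windows`.
#' @export
evaluate_movement_detection <- function(mask, movement) {
  truth <- rep(FALSE, nrow(mask))
  if (nrow(movement) > 0) {
    for (i in seq_len(nrow(movement))) {
      truth <- truth | (mask$start_s < movement$end_s[i] &
                          mask$end_s > movement$start_s[i])
    }
  }
  pred <- mask$movement == 1
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1, n_windows = nrow(mask))
}
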