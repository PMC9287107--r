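TIMESCALES <- c(1, 3, 5, 7, 9, 11, 13, 15)

#' Multi-timescale interval series
#'
#' Estimates the heartbeat (or respiratory) interval on consecutive
#' non-overlapping t-second windows tiling the recording from time zero.
#' Within a window the estimate is the overlap-weighted mean of the
#' intervals crossing it,
#' \deqn{\widehat{I} = \sum_n \alpha_n \beta_n I_n / \sum_n \alpha_n \beta_n,}
#' where \eqn{I_n} is the duration of the n-th inter-event interval,
#' \eqn{\alpha_n} the fraction of the window it covers, and
#' \eqn{\beta_n = 0} when the interval touches a movement episode (1
#' otherwise). A window is marked invalid (`NA`) when it lies entirely
#' inside movement or no usable interval overlaps it. Intervals outside the
#' event kind's physiological bounds are discarded before weighting.
#'
#' @param events An [event_series()] of beats or breaths.
#' @param mask A movement mask from [detect_movement()], or `NULL`.
#' @param timescale Window width t in seconds; one of 1, 3, 5, 7, 9, 11,
#'   13, 15 (9 s is the default working timescale).
#' @param duration_s Span to tile; defaults to the mask's span, else the
#'   last event time.
#' @return A `scaled_series` tibble with columns `window`, `start_s`,
#'   `value` (`NA` = invalid); timescale and kind kept as attributes.
#' @export
#' @examples
#' ev <- event_series(0:9, "heartbeat")
#' scaled_intervals(ev, mask = NULL, timescale = 3, duration_s = 9)
scaled_intervals <- function(events, mask = NULL, timescale = 9,
                             duration_s = NULL) {
  if (!timescale %in% TIMESCALES) {
    rlang::abort(paste0(
      "`timescale` must be one of ", paste(TIMESCALES, collapse = ", ")
    ))
  }
  if (is.null(duration_s)) {
    duration_s <- if (!is.null(mask)) {
      max(mask$end_s)
    } else if (nrow(events) > 0) {
      max(events$time_s)
    } else {
      rlang::abort("cannot infer the span: give `duration_s` or a mask")
    }
  }
  t <- timescale
  n_w <- floor(duration_s / t)
  if (n_w < 1) rlang::abort("span shorter than one window")

  num <- numeric(n_w)
  den <- numeric(n_w)

  tm <- events$time_s
  if (length(tm) >= 2) {
    s <- tm[-length(tm)]
    e <- tm[-1]
    iv <- e - s
    b <- event_bounds(events)
    keep <- iv >= b[1] & iv <= b[2]
    if (!is.null(mask)) keep <- keep & !overlaps_movement(s, e, mask)
    s <- s[keep]; e <- e[keep]; iv <- iv[keep]
    for (n in seq_along(s)) {
      w0 <- max(0L, floor(s[n] / t))
      w1 <- min(n_w - 1L, floor((e[n] - 1e-12) / t))
      if (w1 < w0) next
      ws <- w0:w1
      ov <- pmin(e[n], (ws + 1) * t) - pmax(s[n], ws * t)
      ov[ov < 0] <- 0
      alpha <- ov / t
      num[ws + 1L] <- num[ws + 1L] + alpha * iv[n]
      den[ws + 1L] <- den[ws + 1L] + alpha
    }
  }

  value <- ifelse(den > 1e-12, num / den, NA_real_)
  if (!is.null(mask)) {
    iv_mv <- mask_intervals(mask)
    if (nrow(iv_mv) > 0) {
      w_start <- (seq_len(n_w) - 1) * t
      w_end <- w_start + t
      fully <- rep(FALSE, n_w)
      for (i in seq_len(nrow(iv_mv))) {
        fully <- fully | (iv_mv$start_s[i] <= w_start & iv_mv$end_s[i] >= w_end)
      }
      value[fully] <- NA_real_
    }
  }

  out <- tibble::tibble(
    window = seq_len(n_w),
    start_s = (seq_len(n_w) - 1) * t,
    value = value
  )
  attr(out, "timescale_s") <- t
  attr(out, "kind") <- attr(events, "kind")
  class(out) <- c("scaled_series", class(out))
  out
}

series_timescale <- function(series) {
  ts <- attr(series, "timescale_s")
  if (is.null(ts)) ts <- stats::median(diff(series$start_s))
  ts
}
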