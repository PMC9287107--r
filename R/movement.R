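#' Detect body movement from multi-timescale peak-to-valley amplitude
#'
#' The recording is cut into consecutive non-overlapping 2-second windows
#' and the peak-to-valley difference (PVD, max minus min amplitude) of each
#' is compared against running medians of PVD taken over context epochs of
#' 30, 60, 120 and 300 s centred on the window (truncated at the recording
#' edges). A window is flagged as movement when its PVD exceeds
#' `threshold_factor` (2.2) times at least one of the four context medians,
#' i.e. the smallest of them. Medians below 1% of the recording's global
#' median PVD are floored at that value so flat segments cannot flag
#' everything.
#'
#' @param rec A [raw_recording()] tibble.
#' @param window_len_s Movement window length, seconds (2).
#' @param context_scales_s Context epoch lengths for the running medians.
#' @param threshold_factor PVD ratio above which a window is movement (2.2).
#' @return A `movement_mask` tibble with columns `window` (1-based),
#'   `start_s`, `end_s`, `movement` (integer 0/1); window length and
#'   parameters are kept as attributes.
#' @export
detect_movement <- function(rec, window_len_s = 2,
                            context_scales_s = c(30, 60, 120, 300),
                            threshold_factor = 2.2) {
  rec <- as_recording(rec)
  if (threshold_factor <= 1) rlang::abort("`threshold_factor` must exceed 1")
  fs <- sample_rate(rec)
  spw <- round(window_len_s * fs)
  n_win <- floor(nrow(rec) / spw)
  if (n_win < 1) rlang::abort("recording shorter than one movement window")

  x <- rec$amplitude[seq_len(n_win * spw)]
  dim(x) <- c(spw, n_win)
  pvd <- apply(x, 2, max) - apply(x, 2, min)

  global_med <- stats::median(pvd)
  floor_val <- 0.01 * global_med

  min_med <- rep(Inf, n_win)
  for (scale_s in context_scales_s) {
    w <- max(1L, round(scale_s / window_len_s))
    med <- zoo::rollapply(pvd, width = w, FUN = stats::median,
                          align = "center", partial = TRUE)
    med <- pmax(med, floor_val)
    min_med <- pmin(min_med, med)
  }

  state <- as.integer(pvd > threshold_factor * min_med)
  out <- tibble::tibble(
    window = seq_len(n_win),
    start_s = (seq_len(n_win) - 1) * window_len_s + rec$time_s[1],
    end_s = seq_len(n_win) * window_len_s + rec$time_s[1],
    movement = state
  )
  attr(out, "window_len_s") <- window_len_s
  attr(out, "context_scales_s") <- context_scales_s
  attr(out, "threshold_factor") <- threshold_factor
  class(out) <- c("movement_mask", class(out))
  out
}

# movement intervals (start, end) implied by a mask, merged across adjacent
# flagged windows
mask_intervals <- function(mask) {
  mv <- mask$movement == 1
  if (!any(mv)) return(tibble::tibble(start_s = numeric(0), end_s = numeric(0)))
  r <- rle(mv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(
    start_s = mask$start_s[starts[keep]],
    end_s = mask$end_s[ends[keep]]
  )
}

# TRUE for each time in `times` that falls inside a flagged window
in_movement <- function(times, mask) {
  iv <- mask_intervals(mask)
  if (nrow(iv) == 0 || length(times) == 0) return(rep(FALSE, length(times)))
  out <- rep(FALSE, length(times))
  for (i in seq_len(nrow(iv))) {
    out <- out | (times >= iv$start_s[i] & times < iv$end_s[i])
  }
  out
}

# TRUE where the span [from, to] overlaps any flagged window
overlaps_movement <- function(from, to, mask) {
  iv <- mask_intervals(mask)
  if (nrow(iv) == 0 || length(from) == 0) return(rep(FALSE, length(from)))
  out <- rep(FALSE, length(from))
  for (i in seq_len(nrow(iv))) {
    out <- out | (from < iv$end_s[i] & to > iv$start_s[i])
  }
  out
}
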