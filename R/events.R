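#' Event series tibbles
#'
#' Detected heartbeat or breath times are kept as a tibble with one column
#' `time_s` (strictly increasing), with the event `kind` and the
#' physiological interval `bounds` (seconds) carried as attributes.
#' Out-of-bounds intervals are not deleted here; interval-level screening
#' happens where intervals are consumed (see [scaled_intervals()]).
#'
#' @param time_s Numeric vector of event times, seconds.
#' @param kind `"heartbeat"` or `"breath"`.
#' @param bounds Physiological interval bounds, seconds.
#' @return An `event_series` tibble.
#' @export
event_series <- function(time_s, kind = c("heartbeat", "breath"),
                         bounds = if (match.arg(kind) == "heartbeat") c(0.3, 2) else c(1.5, 10)) {
  kind <- match.arg(kind)
  time_s <- sort(as.numeric(time_s))
  if (anyDuplicated(time_s)) time_s <- unique(time_s)
  out <- tibble::tibble(time_s = time_s)
  attr(out, "kind") <- kind
  attr(out, "bounds") <- bounds
  class(out) <- c("event_series", class(out))
  out
}

event_bounds <- function(ev) attr(ev, "bounds") %||% c(0, Inf)

# centred moving-RMS envelope via cumulative sums (O(n))
rms_envelope <- function(x, k) {
  n <- length(x)
  k <- max(1L, min(k, n))
  cs <- cumsum(c(0, x^2))
  half <- k %/% 2
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

#' Detect heartbeats from the BCG component
#'
#' Contract-level forward–backward beat detector: a band-limited RMS energy
#' envelope of the BCG is scanned for local maxima at plausible spacing
#' (forward pass, adaptive threshold at 40% of the median candidate height),
#' then gaps longer than 1.5 times the running median interval are
#' re-scanned at a reduced threshold for missed beats (backward pass).
#' Candidates inside movement windows are discarded.
#'
#' @param bcg Output of [extract_bcg()].
#' @param mask Movement mask from [detect_movement()]; `NULL` for none.
#' @param envelope_win_s RMS envelope window, seconds.
#' @param min_spacing_s Minimum accepted beat spacing, seconds.
#' @return An [event_series()] of kind `"heartbeat"`.
#' @export
detect_heartbeats <- function(bcg, mask = NULL, envelope_win_s = 0.12,
                              min_spacing_s = 0.3) {
  bcg <- as_recording(bcg)
  fs <- sample_rate(bcg)
  env <- rms_envelope(bcg$amplitude, round(envelope_win_s * fs))
  # second smoothing pass kills the residual ripple at twice the BCG
  # carrier frequency that survives the first RMS window
  env <- rms_envelope(env, round(envelope_win_s * fs))
  if (all(env == 0)) return(event_series(numeric(0), "heartbeat"))

  pk <- pracma::findpeaks(env, minpeakdistance = max(1L, round(min_spacing_s * fs)),
                          minpeakheight = .Machine$double.eps)
  if (is.null(pk)) return(event_series(numeric(0), "heartbeat"))
  heights <- pk[, 1]
  times <- bcg$time_s[pk[, 2]]
  ord <- order(times)
  heights <- heights[ord]
  times <- times[ord]

  if (!is.null(mask)) {
    keep <- !in_movement(times, mask)
    heights <- heights[keep]
    times <- times[keep]
  }
  if (length(times) == 0) return(event_series(numeric(0), "heartbeat"))

  # beats sit well above the between-beat envelope: anchor the threshold on
  # the upper candidate heights so noise maxima between beats are rejected
  ref <- as.numeric(stats::quantile(heights, 0.85))
  thr <- 0.4 * ref
  accept <- heights >= thr
  acc_t <- times[accept]

  # backward pass: revisit long gaps with a lower threshold
  if (length(acc_t) >= 3) {
    iv <- diff(acc_t)
    med_iv <- stats::median(iv)
    low_thr <- 0.15 * ref
    gap_idx <- which(iv > 1.5 * med_iv)
    for (gi in gap_idx) {
      inside <- which(!accept & times > acc_t[gi] + min_spacing_s &
                        times < acc_t[gi + 1] - min_spacing_s &
                        heights >= low_thr)
      if (length(inside) > 0) {
        accept[inside] <- TRUE
      }
    }
    acc_t <- times[accept]
  }

  # refine each beat to the local energy centroid: the BCG pulse envelope
  # is symmetric about the heartbeat, so the centroid pins the beat time
  # far better than the discrete envelope maximum
  half <- round(0.15 * fs)
  e2 <- env^2
  t0 <- bcg$time_s[1]
  acc_t <- vapply(acc_t, function(b) {
    c_idx <- round((b - t0) * fs) + 1
    idx <- max(1, c_idx - half):min(length(e2), c_idx + half)
    w <- e2[idx]
    if (sum(w) == 0) return(b)
    sum(bcg$time_s[idx] * w) / sum(w)
  }, numeric(1))
  event_series(acc_t, "heartbeat")
}

#' Detect breaths from the respiratory waveform
#'
#' Peak detection on the respiration signal: local maxima spaced at least
#' the refractory interval (1.5 s) apart and rising above an adaptive
#' amplitude threshold. Peaks inside movement windows are discarded.
#'
#' @param resp Output of [extract_respiration()].
#' @param mask Movement mask, or `NULL`.
#' @param refractory_s Minimum peak spacing, seconds.
#' @return An [event_series()] of kind `"breath"`.
#' @export
detect_breaths <- function(resp, mask = NULL, refractory_s = 1.5) {
  resp <- as_recording(resp)
  fs <- sample_rate(resp)
  x <- resp$amplitude
  ref_amp <- as.numeric(stats::quantile(abs(x), 0.95))
  if (ref_amp == 0) return(event_series(numeric(0), "breath"))
  thr <- 0.25 * ref_amp

  pk <- pracma::findpeaks(x, minpeakdistance = max(1L, round(refractory_s * fs)),
                          minpeakheight = thr)
  if (is.null(pk)) return(event_series(numeric(0), "breath"))
  times <- sort(resp$time_s[pk[, 2]])
  if (!is.null(mask)) times <- times[!in_movement(times, mask)]
  event_series(times, "breath")
}

#' One-call preprocessing of a raw recording
#'
#' Runs the standard separation chain: powerline band-stop, multi-timescale
#' movement detection, BCG band-pass with beat detection, and wavelet
#' respiration extraction with breath detection.
#'
#' @param rec A [raw_recording()] tibble.
#' @param powerline Stop-band corners in Hz, or `NULL` to skip the filter.
#' @return A list with `mask`, `bcg`, `resp`, `beats`, `breaths`.
#' @export
#' @examples
#' sim <- sim_recording(hypnogram(rep("NREM", 3)),
#'                      sim_config(sample_rate_hz = 200), seed = 2)
#' pp <- preprocess_recording(sim$recording)
#' nrow(pp$beats)
preprocess_recording <- function(rec, powerline = c(49, 51)) {
  rec <- as_recording(rec)
  # the band-stop only applies when the mains band sits below Nyquist;
  # at lower sampling rates the interference is aliased and the filter
  # stage is skipped
  if (!is.null(powerline) && powerline[2] < sample_rate(rec) / 2) {
    rec <- remove_powerline(rec, powerline[1], powerline[2])
  }
  mask <- detect_movement(rec)
  bcg <- extract_bcg(rec, mask)
  beats <- detect_heartbeats(bcg, mask)
  resp <- extract_respiration(rec, bcg)
  breaths <- detect_breaths(resp, mask)
  list(mask = mask, bcg = bcg, resp = resp, beats = beats, breaths = breaths)
}
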