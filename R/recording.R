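#' Single-channel pressure recording
#'
#' A recording is a tibble with columns `time_s` and `amplitude`, carrying
#' `sample_rate_hz` (and optionally `adc_bits`) as attributes. Amplitudes are
#' processed as floating point throughout, whatever the acquisition ADC
#' emitted.
#'
#' @param amplitude Numeric vector of samples.
#' @param sample_rate_hz Sampling rate in Hz (1 kHz for the target hardware).
#' @param start_time_s Time of the first sample, seconds.
#' @param adc_bits Optional ADC resolution; when set, amplitudes must lie in
#'   the signed range it implies.
#' @return A `pressure_recording` tibble.
#' @export
raw_recording <- function(amplitude, sample_rate_hz = 1000, start_time_s = 0,
                          adc_bits = NULL) {
  if (length(amplitude) == 0) rlang::abort("recording must contain samples")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    rlang::abort("`sample_rate_hz` must be positive")
  }
  amplitude <- as.numeric(amplitude)
  if (!is.null(adc_bits)) {
    lim <- 2^(adc_bits - 1)
    if (any(abs(amplitude) > lim, na.rm = TRUE)) {
      rlang::abort(sprintf("amplitudes exceed the signed %d-bit ADC range", adc_bits))
    }
  }
  out <- tibble::tibble(
    time_s = start_time_s + (seq_along(amplitude) - 1) / sample_rate_hz,
    amplitude = amplitude
  )
  attr(out, "sample_rate_hz") <- as.numeric(sample_rate_hz)
  attr(out, "adc_bits") <- adc_bits
  class(out) <- c("pressure_recording", class(out))
  out
}

#' @export
#' @rdname raw_recording
#' @param x A data frame with `time_s` and `amplitude` columns.
as_recording <- function(x, sample_rate_hz = NULL) {
  if (inherits(x, "pressure_recording") && is.null(sample_rate_hz)) return(x)
  if (!is.data.frame(x) || !all(c("time_s", "amplitude") %in% names(x))) {
    rlang::abort("`x` must have `time_s` and `amplitude` columns")
  }
  fs <- sample_rate_hz %||% attr(x, "sample_rate_hz")
  if (is.null(fs)) {
    dt <- diff(x$time_s[seq_len(min(1000L, nrow(x)))])
    fs <- 1 / stats::median(dt)
  }
  raw_recording(x$amplitude, sample_rate_hz = fs, start_time_s = x$time_s[1])
}

sample_rate <- function(rec) {
  fs <- attr(rec, "sample_rate_hz")
  if (is.null(fs)) rlang::abort("recording is missing its sample rate")
  fs
}

rec_duration <- function(rec) nrow(rec) / sample_rate(rec)

# carry a filtered amplitude vector into a recording with the same clock
with_amplitude <- function(rec, amplitude) {
  out <- rec
  out$amplitude <- amplitude
  out
}

#' @export
print.pressure_recording <- function(x, ...) {
  cat(sprintf(
    "# Pressure recording: %d samples at %g Hz (%.1f min)\n",
    nrow(x), sample_rate(x), rec_duration(x) / 60
  ))
  NextMethod()
}
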