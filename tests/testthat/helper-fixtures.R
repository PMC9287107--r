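# fixture builders shared across the suite; everything is generated in code

make_mask <- function(states, window_len_s = 2) {
  n <- length(states)
  out <- tibble::tibble(
    window = seq_len(n),
    start_s = (seq_len(n) - 1) * window_len_s,
    end_s = seq_len(n) * window_len_s,
    movement = as.integer(states)
  )
  attr(out, "window_len_s") <- window_len_s
  class(out) <- c("movement_mask", class(out))
  out
}

make_series <- function(values, timescale = 1, kind = "heartbeat") {
  out <- tibble::tibble(
    window = seq_along(values),
    start_s = (seq_along(values) - 1) * timescale,
    value = as.numeric(values)
  )
  attr(out, "timescale_s") <- timescale
  attr(out, "kind") <- kind
  class(out) <- c("scaled_series", class(out))
  out
}

sine_recording <- function(freq_hz, duration_s, fs = 1000, amp = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  raw_recording(amp * sin(2 * pi * freq_hz * t), sample_rate_hz = fs)
}

# a noise-free BCG-like pulse train with beats at the given times
pulse_train_recording <- function(beat_times, duration_s, fs = 200,
                                  freq_hz = 6, width_s = 0.05) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (b in beat_times) {
    idx <- which(abs(t - b) <= 4 * width_s)
    u <- t[idx] - b
    x[idx] <- x[idx] + exp(-u^2 / (2 * width_s^2)) * cos(2 * pi * freq_hz * u)
  }
  raw_recording(x, sample_rate_hz = fs)
}

# a separable 3-class feature set: class-specific mean pattern across all
# features, with noise small against the between-class distances
separable_features <- function(n_per_class = 30, seed = 42) {
  withr::with_seed(seed, {
    stages <- rep(SLEEP_STAGES, each = n_per_class)
    centroids <- matrix(stats::rnorm(3 * 41, 0, 1.5), nrow = 3,
                        dimnames = list(SLEEP_STAGES, NULL))
    base <- centroids[stages, ] +
      matrix(stats::rnorm(length(stages) * 41, 0, 0.1), ncol = 41)
    colnames(base) <- feature_names()
    df <- tibble::as_tibble(as.data.frame(base))
    df$stage <- stages
    df
  })
}

random_stages <- function(n, seed = NULL) {
  if (!is.null(seed)) {
    withr::with_seed(seed, sample(SLEEP_STAGES, n, replace = TRUE))
  } else {
    sample(SLEEP_STAGES, n, replace = TRUE)
  }
}

# independent brute-force evaluation of the overlap-weighted interval mean
brute_scaled_value <- function(event_times, mask_iv, t, w, bounds) {
  a <- (w - 1) * t
  b <- w * t
  if (nrow(mask_iv) > 0 &&
      any(mask_iv$start_s <= a & mask_iv$end_s >= b)) {
    return(NA_real_)
  }
  if (length(event_times) < 2) return(NA_real_)
  s <- event_times[-length(event_times)]
  e <- event_times[-1]
  iv <- e - s
  num <- 0
  den <- 0
  for (n in seq_along(s)) {
    if (iv[n] < bounds[1] || iv[n] > bounds[2]) next
    beta <- 1
    if (nrow(mask_iv) > 0 &&
        any(s[n] < mask_iv$end_s & e[n] > mask_iv$start_s)) {
      beta <- 0
    }
    ov <- max(0, min(e[n], b) - max(s[n], a))
    alpha <- ov / t
    num <- num + alpha * beta * iv[n]
    den <- den + alpha * beta
  }
  if (den <= 1e-12) NA_real_ else num / den
}

# independent contingency-table computation of accuracy and kappa
brute_agreement <- function(pred, ref) {
  classes <- SLEEP_STAGES
  cm <- matrix(0, 3, 3, dimnames = list(pred = classes, ref = classes))
  for (i in seq_along(pred)) cm[pred[i], ref[i]] <- cm[pred[i], ref[i]] + 1
  total <- sum(cm)
  p0 <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (pe >= 1) (if (p0 >= 1) 1 else 0) else (p0 - pe) / (1 - pe)
  list(p0 = p0, pe = pe, kappa = kappa)
}

signal_rms <- function(x) sqrt(mean(x^2))
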