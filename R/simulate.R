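#' Simulator configuration
#'
#' Parameters of the synthetic all-night pressure-signal generator. The
#' generator mixes, per the physical signal model of the sensing problem:
#' one ballistocardiogram (BCG) pulse per heartbeat, an additive respiratory
#' oscillation, broadband high-amplitude body-movement bursts, 50 Hz
#' powerline interference and white sensor noise.
#'
#' Per-stage statistics are ordered so that autonomic variability follows
#' Wake ~ REM > NREM, the physiological ordering the staging features rely
#' on: deep sleep shows the slowest, steadiest heartbeat and breathing,
#' while wake (and, for heart-rate variability, REM) is faster and more
#' irregular. Movement concentrates in Wake and is rare in REM/NREM.
#'
#' @param hi_mean,hi_sd Named per-stage heartbeat-interval mean/SD, seconds.
#' @param ri_mean,ri_sd Named per-stage breath-interval mean/SD, seconds.
#' @param movement_rate Named per-stage movement rate, events/hour.
#' @param movement_dur_range Movement burst duration range, seconds.
#' @param bcg_freq_hz Centre frequency of the damped BCG oscillation (inside
#'   the 3–10 Hz BCG band).
#' @param bcg_width_s Gaussian half-width (SD) of the BCG pulse envelope.
#' @param bcg_amp BCG pulse peak amplitude (reference unit).
#' @param resp_amp_ratio Respiration amplitude relative to the BCG pulse.
#' @param movement_amp Movement burst amplitude (uniform, peak); kept well
#'   above 5x the BCG pulse so bursts dominate every other component.
#' @param powerline_amp,powerline_freq_hz Powerline interference amplitude
#'   and frequency.
#' @param noise_sd White noise standard deviation.
#' @param sample_rate_hz Sampling rate, Hz (>= 100; hardware default 1000).
#' @param hi_bounds,ri_bounds Physiological interval bounds, seconds;
#'   simulated intervals are clipped into them.
#' @return A `sim_config` list.
#' @export
sim_config <- function(hi_mean = c(Wake = 0.85, REM = 0.90, NREM = 1.00),
                       hi_sd = c(Wake = 0.06, REM = 0.07, NREM = 0.03),
                       ri_mean = c(Wake = 3.5, REM = 3.6, NREM = 4.0),
                       ri_sd = c(Wake = 0.5, REM = 0.5, NREM = 0.15),
                       movement_rate = c(Wake = 60, REM = 4, NREM = 6),
                       movement_dur_range = c(2, 8),
                       bcg_freq_hz = 6,
                       bcg_width_s = 0.05,
                       bcg_amp = 1,
                       resp_amp_ratio = 3,
                       movement_amp = 10,
                       powerline_amp = 0.1,
                       powerline_freq_hz = 50,
                       noise_sd = 0.05,
                       sample_rate_hz = 1000,
                       hi_bounds = c(0.3, 2.0),
                       ri_bounds = c(1.5, 10)) {
  cfg <- list(
    hi_mean = hi_mean, hi_sd = hi_sd, ri_mean = ri_mean, ri_sd = ri_sd,
    movement_rate = movement_rate, movement_dur_range = movement_dur_range,
    bcg_freq_hz = bcg_freq_hz, bcg_width_s = bcg_width_s, bcg_amp = bcg_amp,
    resp_amp_ratio = resp_amp_ratio, movement_amp = movement_amp,
    powerline_amp = powerline_amp, powerline_freq_hz = powerline_freq_hz,
    noise_sd = noise_sd, sample_rate_hz = sample_rate_hz,
    hi_bounds = hi_bounds, ri_bounds = ri_bounds
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  for (nm in c("hi_mean", "hi_sd", "ri_mean", "ri_sd", "movement_rate")) {
    v <- cfg[[nm]]
    if (!all(SLEEP_STAGES %in% names(v))) {
      rlang::abort(sprintf("`%s` must be named for Wake, REM and NREM", nm))
    }
  }
  if (any(cfg$hi_mean < 0.3) || any(cfg$hi_mean > 2.0)) {
    rlang::abort("heartbeat-interval means must lie in [0.3, 2.0] s")
  }
  if (any(cfg$ri_mean < 1.5) || any(cfg$ri_mean > 10)) {
    rlang::abort("breath-interval means must lie in [1.5, 10] s")
  }
  if (any(cfg$hi_sd < 0) || any(cfg$ri_sd < 0)) {
    rlang::abort("interval SDs must be non-negative")
  }
  if (any(cfg$movement_rate < 0)) rlang::abort("movement rates must be non-negative")
  if (cfg$sample_rate_hz < 100) rlang::abort("`sample_rate_hz` must be at least 100 Hz")
  if (diff(cfg$movement_dur_range) < 0 || cfg$movement_dur_range[1] < 0) {
    rlang::abort("`movement_dur_range` must be a non-decreasing, non-negative pair")
  }
  invisible(cfg)
}

# run `expr` under a private RNG stream; the caller's RNG state is untouched
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    rlang::abort("`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a plausible all-night hypnogram
#'
#' Stage-duration grammar: an initial Wake run of 5–20 min, then alternating
#' NREM (40–70 min) and REM runs (starting at 10–16 min, lengthening by a
#' factor 1.3 per cycle, capped at 30 min), giving the classical ~90-min
#' NREM/REM cycle with NREM dominant early and REM runs growing toward
#' morning. Brief 1–3-epoch Wake intrusions are inserted after some cycles.
#'
#' @param duration_min Night length in minutes (at least two epochs' worth).
#' @param seed RNG seed; the same seed always yields the same hypnogram.
#' @param epoch_len_s Epoch length in seconds.
#' @return A [hypnogram()].
#' @export
#' @examples
#' h <- sim_hypnogram(480, seed = 1)
#' table(h$stage)
sim_hypnogram <- function(duration_min, seed, epoch_len_s = 60) {
  if (!is.numeric(duration_min) || duration_min <= 0) {
    rlang::abort("`duration_min` must be positive")
  }
  n_epochs <- floor(duration_min * 60 / epoch_len_s)
  if (n_epochs < 2) rlang::abort("duration must cover at least two epochs")
  per_min <- 60 / epoch_len_s

  with_local_seed(seed, {
    lab <- rep(NA_character_, n_epochs)
    n_wake <- max(1L, round(stats::runif(1, 5, 20) * per_min))
    seq_lab <- rep("Wake", n_wake)
    rem_base <- stats::runif(1, 10, 16)
    cycle <- 0L
    while (length(seq_lab) < n_epochs) {
      cycle <- cycle + 1L
      n_nrem <- max(1L, round(stats::runif(1, 40, 70) * per_min))
      seq_lab <- c(seq_lab, rep("NREM", n_nrem))
      rem_min <- min(30, rem_base * 1.3^(cycle - 1) * stats::runif(1, 0.9, 1.2))
      n_rem <- max(1L, round(rem_min * per_min))
      seq_lab <- c(seq_lab, rep("REM", n_rem))
      if (stats::runif(1) < 0.4) {
        seq_lab <- c(seq_lab, rep("Wake", sample(1:3, 1)))
      }
    }
    hypnogram(seq_lab[seq_len(n_epochs)], epoch_len_s = epoch_len_s)
  })
}

# truncated-normal interval draw: a normal deviate clipped to bounds,
# so sd = 0 degenerates to exactly the mean
draw_interval <- function(mean, sd, bounds) {
  min(max(stats::rnorm(1, mean, sd), bounds[1]), bounds[2])
}

# event times from per-stage interval statistics; stage looked up at the
# time each interval begins
sim_event_times <- function(duration_s, stage_of, means, sds, bounds) {
  times <- numeric(0)
  t <- 0
  repeat {
    s <- stage_of(t)
    t <- t + draw_interval(means[[s]], sds[[s]], bounds)
    if (t >= duration_s) break
    times <- c(times, t)
  }
  times
}

#' Synthesize a pressure recording from a hypnogram
#'
#' Builds the full signal mix of the noncontact sensing problem at the
#' configured sample rate: a Gaussian-windowed damped-cosine BCG pulse per
#' heartbeat, a sinusoidal respiratory oscillation whose peaks define the
#' ground-truth breath times, uniform broadband bursts over the simulated
#' movement intervals, a powerline sinusoid, and white noise. Ground truth
#' (beat times, breath times, movement intervals, hypnogram) is returned
#' alongside the recording.
#'
#' @param hypnogram A [hypnogram()] defining per-epoch stages.
#' @param config A [sim_config()].
#' @param seed RNG seed; identical inputs and seed give bit-identical output.
#' @return A list of class `sim_recording` with elements `recording` (a
#'   [raw_recording()] tibble) and `truth` (list: `beat_times`,
#'   `breath_times`, `movement` tibble with `start_s`/`end_s`, `hypnogram`).
#' @export
#' @examples
#' h <- hypnogram(rep("NREM", 3))
#' sim <- sim_recording(h, sim_config(sample_rate_hz = 100), seed = 7)
#' length(sim$truth$beat_times)
sim_recording <- function(hypnogram, config = sim_config(), seed = 1) {
  h <- as_hypnogram(hypnogram)
  validate_sim_config(config)
  el <- epoch_len(h)
  duration_s <- nrow(h) * el
  fs <- config$sample_rate_hz
  stage_of <- function(t) h$stage[pmin(nrow(h), floor(t / el) + 1L)]

  with_local_seed(seed, {
    beat_times <- sim_event_times(
      duration_s, stage_of, config$hi_mean, config$hi_sd, config$hi_bounds
    )
    breath_times <- sim_event_times(
      duration_s, stage_of, config$ri_mean, config$ri_sd, config$ri_bounds
    )
    movement <- sim_movement_intervals(h, config)

    n <- round(duration_s * fs)
    tt <- (seq_len(n) - 1) / fs
    x <- numeric(n)

    # BCG pulse train: envelope centred on the beat time, cosine in phase at
    # the centre, so the band-limited energy envelope peaks at the beat time
    half <- ceiling(4 * config$bcg_width_s * fs)
    for (b in beat_times) {
      c_idx <- round(b * fs) + 1
      idx <- max(1, c_idx - half):min(n, c_idx + half)
      u <- tt[idx] - b
      x[idx] <- x[idx] + config$bcg_amp *
        exp(-u^2 / (2 * config$bcg_width_s^2)) * cos(2 * pi * config$bcg_freq_hz * u)
    }

    # respiration: unit-amplitude sinusoid whose phase hits pi/2 (+2*pi*k)
    # exactly at each ground-truth breath time
    if (length(breath_times) >= 2) {
      phase_knots <- pi / 2 + 2 * pi * (seq_along(breath_times) - 1)
      phi <- linear_interp_extrap(breath_times, phase_knots, tt)
      x <- x + config$resp_amp_ratio * config$bcg_amp * sin(phi)
    }

    if (nrow(movement) > 0) {
      for (i in seq_len(nrow(movement))) {
        idx <- which(tt >= movement$start_s[i] & tt < movement$end_s[i])
        x[idx] <- x[idx] + config$movement_amp * stats::runif(length(idx), -1, 1)
      }
    }

    if (config$powerline_amp > 0) {
      x <- x + config$powerline_amp * sin(2 * pi * config$powerline_freq_hz * tt)
    }
    if (config$noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, config$noise_sd)
    }

    out <- list(
      recording = raw_recording(x, sample_rate_hz = fs),
      truth = list(
        beat_times = beat_times,
        breath_times = breath_times,
        movement = movement,
        hypnogram = h
      )
    )
    class(out) <- "sim_recording"
    out
  })
}

# linear interpolation with linear (not constant) extrapolation at the ends
linear_interp_extrap <- function(x, y, xout) {
  yout <- stats::approx(x, y, xout = xout, rule = 2)$y
  k <- length(x)
  lo <- xout < x[1]
  if (any(lo)) {
    slope <- (y[2] - y[1]) / (x[2] - x[1])
    yout[lo] <- y[1] + slope * (xout[lo] - x[1])
  }
  hi <- xout > x[k]
  if (any(hi)) {
    slope <- (y[k] - y[k - 1]) / (x[k] - x[k - 1])
    yout[hi] <- y[k] + slope * (xout[hi] - x[k])
  }
  yout
}

# Poisson bursts per epoch at the stage's hourly rate; overlaps merged
sim_movement_intervals <- function(h, config) {
  el <- epoch_len(h)
  duration_s <- nrow(h) * el
  starts <- numeric(0)
  ends <- numeric(0)
  for (e in seq_len(nrow(h))) {
    rate <- config$movement_rate[[h$stage[e]]]
    n_ev <- stats::rpois(1, rate * el / 3600)
    if (n_ev == 0) next
    s <- (e - 1) * el + stats::runif(n_ev, 0, el)
    d <- stats::runif(n_ev, config$movement_dur_range[1], config$movement_dur_range[2])
    starts <- c(starts, s)
    ends <- c(ends, pmin(s + d, duration_s))
  }
  if (length(starts) == 0) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0)))
  }
  ord <- order(starts)
  starts <- starts[ord]
  ends <- ends[ord]
  m_start <- starts[1]
  m_end <- ends[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= m_end) {
      m_end <- max(m_end, ends[i])
    } else {
      out_s <- c(out_s, m_start)
      out_e <- c(out_e, m_end)
      m_start <- starts[i]
      m_end <- ends[i]
    }
  }
  tibble::tibble(start_s = c(out_s, m_start), end_s = c(out_e, m_end))
}

#' @export
print.sim_recording <- function(x, ...) {
  cat(sprintf(
    "# Synthetic recording: %.1f min at %g Hz | %d beats, %d breaths, %d movement bursts\n",
    rec_duration(x$recording) / 60, sample_rate(x$recording),
    length(x$truth$beat_times), length(x$truth$breath_times), nrow(x$truth$movement)
  ))
  invisible(x)
}
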