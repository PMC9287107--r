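test_that("hypnogram generation is deterministic and well-formed", {
  h1 <- sim_hypnogram(480, seed = 1)
  h2 <- sim_hypnogram(480, seed = 1)
  expect_identical(h1$stage, h2$stage)

  h <- sim_hypnogram(2, seed = 99)
  expect_equal(nrow(h), 2)
  expect_true(all(h$stage %in% SLEEP_STAGES))

  expect_error(sim_hypnogram(-5, seed = 1), "positive")
  expect_error(sim_hypnogram(1, seed = 1), "two epochs")
})

test_that("night structure: starts awake, NREM-dominant, ~90-min cycling", {
  for (seed in 1:20) {
    h <- sim_hypnogram(480, seed = seed)
    expect_equal(h$stage[1], "Wake")
    frac_nrem <- mean(h$stage == "NREM")
    expect_gte(frac_nrem, 0.4)
    expect_lte(frac_nrem, 0.8)
  }
  # REM runs lengthen toward morning
  h <- sim_hypnogram(480, seed = 3)
  r <- rle(h$stage)
  rem_runs <- r$lengths[r$values == "REM"]
  expect_gt(mean(tail(rem_runs, 2)), mean(head(rem_runs, 2)))
})

test_that("recording synthesis is bit-deterministic", {
  h <- hypnogram(rep("NREM", 3))
  cfg <- sim_config(sample_rate_hz = 100)
  s1 <- sim_recording(h, cfg, seed = 5)
  s2 <- sim_recording(h, cfg, seed = 5)
  expect_identical(s1$recording$amplitude, s2$recording$amplitude)
  expect_identical(s1$truth$beat_times, s2$truth$beat_times)
  expect_identical(s1$truth$movement, s2$truth$movement)
})

test_that("degenerate config yields an exactly periodic beat train", {
  h <- hypnogram(rep("NREM", 3))
  cfg <- sim_config(
    hi_mean = c(Wake = 1, REM = 1, NREM = 1),
    hi_sd = c(Wake = 0, REM = 0, NREM = 0),
    movement_rate = c(Wake = 0, REM = 0, NREM = 0),
    powerline_amp = 0, noise_sd = 0, sample_rate_hz = 100
  )
  sim <- sim_recording(h, cfg, seed = 2)
  expect_equal(diff(sim$truth$beat_times), rep(1, length(sim$truth$beat_times) - 1))
  expect_equal(nrow(sim$truth$movement), 0)
  expect_equal(length(sim$recording$amplitude), 3 * 60 * 100)
})

test_that("fixed 4-s breathing dominates the low-frequency spectrum at 0.25 Hz", {
  h <- hypnogram(rep("NREM", 5))
  cfg <- sim_config(
    ri_mean = c(Wake = 4, REM = 4, NREM = 4),
    ri_sd = c(Wake = 0, REM = 0, NREM = 0),
    movement_rate = c(Wake = 0, REM = 0, NREM = 0),
    sample_rate_hz = 100
  )
  sim <- sim_recording(h, cfg, seed = 4)
  x <- sim$recording$amplitude - mean(sim$recording$amplitude)
  n <- length(x)
  spec <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * 100 / n
  low <- freq > 0.05 & freq < 1
  peak_freq <- freq[low][which.max(spec[low])]
  expect_lt(abs(peak_freq - 0.25), 0.02)
})

test_that("simulated beat intervals track the per-stage statistics", {
  h <- hypnogram(rep(c("Wake", "REM", "NREM"), each = 10))
  cfg <- sim_config(sample_rate_hz = 100)
  sim <- sim_recording(h, cfg, seed = 11)
  bt <- sim$truth$beat_times
  iv <- diff(bt)
  iv_stage <- h$stage[pmin(nrow(h), floor(bt[-length(bt)] / 60) + 1)]
  for (s in SLEEP_STAGES) {
    x <- iv[iv_stage == s]
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - cfg$hi_mean[[s]]), 3 * se)
  }
})

test_that("movement concentrates in Wake and bursts dominate the amplitude", {
  h <- hypnogram(rep(c("Wake", "NREM"), each = 20))
  cfg <- sim_config(sample_rate_hz = 100)
  sim <- sim_recording(h, cfg, seed = 8)
  mv <- sim$truth$movement
  expect_gt(nrow(mv), 0)
  wake_time <- sum(pmax(0, pmin(mv$end_s, 20 * 60) - pmin(mv$start_s, 20 * 60)))
  nrem_time <- sum(pmax(0, mv$end_s - pmax(mv$start_s, 20 * 60)))
  expect_gt(wake_time, nrem_time)

  # peak-to-valley inside movement exceeds every movement-free 2-s window
  x <- sim$recording$amplitude
  t <- sim$recording$time_s
  n_win <- floor(length(x) / 200)
  pvd <- vapply(seq_len(n_win), function(w) {
    seg <- x[((w - 1) * 200 + 1):(w * 200)]
    max(seg) - min(seg)
  }, numeric(1))
  win_start <- (seq_len(n_win) - 1) * 2
  in_mv <- vapply(win_start, function(ws) {
    any(ws < mv$end_s & ws + 2 > mv$start_s)
  }, logical(1))
  expect_gt(min(pvd[in_mv]), max(pvd[!in_mv]))
})

test_that("configs outside physiological bounds are rejected", {
  expect_error(sim_config(hi_mean = c(Wake = 0.1, REM = 0.9, NREM = 1)), "0.3")
  expect_error(sim_config(ri_mean = c(Wake = 12, REM = 4, NREM = 4)), "1.5")
  expect_error(sim_config(sample_rate_hz = 50), "100")
  expect_error(sim_config(hi_sd = c(Wake = -1, REM = 0, NREM = 0)), "non-negative")
})
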