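test_that("powerline band-stop removes 50 Hz and spares the passband", {
  mains <- sine_recording(50, 20, fs = 1000)
  out <- remove_powerline(mains)
  expect_equal(nrow(out), nrow(mains))
  expect_lt(signal_rms(out$amplitude), 0.1 * signal_rms(mains$amplitude))

  dc <- raw_recording(rep(1, 5000), sample_rate_hz = 1000)
  out_dc <- remove_powerline(dc)
  core <- out_dc$amplitude[1000:4000]
  expect_true(all(abs(core - 1) < 0.01))

  slow <- sine_recording(5, 20, fs = 1000)
  out_slow <- remove_powerline(slow)
  expect_lt(abs(signal_rms(out_slow$amplitude) / signal_rms(slow$amplitude) - 1), 0.05)

  expect_error(remove_powerline(sine_recording(5, 2, fs = 80)), "Nyquist|sample_rate")
})

test_that("movement detection matches a brute-force PVD/median oracle", {
  # 10-min background-noise recording with one injected 4-s burst
  fs <- 100
  withr::with_seed(31, {
    x <- stats::rnorm(600 * fs, 0, 0.1)
  })
  burst_idx <- which((seq_along(x) - 1) / fs >= 300 & (seq_along(x) - 1) / fs < 304)
  withr::with_seed(32, {
    x[burst_idx] <- x[burst_idx] + stats::runif(length(burst_idx), -1, 1)
  })
  rec <- raw_recording(x, sample_rate_hz = fs)
  mask <- detect_movement(rec)

  # independent oracle: direct PVD and centred running medians
  n_win <- 300
  pvd <- vapply(seq_len(n_win), function(w) {
    seg <- x[((w - 1) * 2 * fs + 1):(w * 2 * fs)]
    max(seg) - min(seg)
  }, numeric(1))
  floor_val <- 0.01 * stats::median(pvd)
  expected <- vapply(seq_len(n_win), function(w) {
    meds <- vapply(c(30, 60, 120, 300), function(scale_s) {
      half <- scale_s / 4  # half the context epoch, in 2-s windows
      ctx <- pvd[max(1, w - half):min(n_win, w + half)]
      max(stats::median(ctx), floor_val)
    }, numeric(1))
    as.integer(pvd[w] > 2.2 * min(meds))
  }, integer(1))

  flagged <- which(mask$movement == 1)
  burst_windows <- which(mask$start_s < 304 & mask$end_s > 300)
  expect_setequal(flagged, burst_windows)
  # oracle agrees on which windows exceed the multiscale threshold
  expect_setequal(which(expected == 1), burst_windows)
})

test_that("flat and stationary-sinusoid signals produce no movement flags", {
  const <- raw_recording(rep(2, 60 * 100), sample_rate_hz = 100)
  expect_true(all(detect_movement(const)$movement == 0))

  sine <- sine_recording(1, 120, fs = 100)
  expect_true(all(detect_movement(sine)$movement == 0))

  expect_error(detect_movement(raw_recording(numeric(0), 100)), "samples")
})

test_that("BCG band-pass keeps 6 Hz and rejects the respiratory band", {
  slow <- sine_recording(0.25, 60, fs = 200)
  out <- extract_bcg(slow)
  expect_lt(signal_rms(out$amplitude), 0.1 * signal_rms(slow$amplitude))

  mid <- sine_recording(6, 60, fs = 200)
  out_mid <- extract_bcg(mid)
  expect_lt(abs(signal_rms(out_mid$amplitude) / signal_rms(mid$amplitude) - 1), 0.12)

  zero <- raw_recording(rep(0, 1000), sample_rate_hz = 200)
  expect_true(all(extract_bcg(zero)$amplitude == 0))
})

test_that("heartbeat detection recovers a clean 1-Hz pulse train", {
  beats <- seq(1, 119, by = 1)
  rec <- pulse_train_recording(beats, 120, fs = 200)
  ev <- detect_heartbeats(rec)
  iv <- diff(ev$time_s)
  expect_gt(length(iv), 100)
  expect_true(all(iv >= 0.99 & iv <= 1.01))

  zero <- raw_recording(rep(0, 2000), sample_rate_hz = 200)
  expect_equal(nrow(detect_heartbeats(zero)), 0)
})

test_that("no heartbeats are reported inside movement windows", {
  beats <- seq(1, 119, by = 1)
  rec <- pulse_train_recording(beats, 120, fs = 200)
  x <- rec$amplitude
  burst <- which(rec$time_s >= 60 & rec$time_s < 64)
  withr::with_seed(9, x[burst] <- x[burst] + stats::runif(length(burst), -10, 10))
  rec2 <- raw_recording(x, sample_rate_hz = 200)
  mask <- detect_movement(rec2)
  expect_true(any(mask$movement == 1))
  ev <- detect_heartbeats(extract_bcg(rec2), mask)
  expect_false(any(in_movement(ev$time_s, mask)))
})

test_that("sym8 pyramid reconstructs exactly and isolates respiration", {
  withr::with_seed(21, x <- stats::rnorm(512))
  dec <- somnosense:::dwt_sym8(x, 8)
  expect_equal(somnosense:::idwt_sym8(dec), x, tolerance = 1e-10)

  fs <- 200
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  resp <- sin(2 * pi * 0.25 * t)
  bcg_amp <- numeric(length(t))
  for (b in seq(1, 119, by = 1)) {
    idx <- which(abs(t - b) <= 0.2)
    u <- t[idx] - b
    bcg_amp[idx] <- bcg_amp[idx] + exp(-u^2 / (2 * 0.05^2)) * cos(2 * pi * 6 * u)
  }
  rec <- raw_recording(resp + bcg_amp, sample_rate_hz = fs)
  bcg <- raw_recording(bcg_amp, sample_rate_hz = fs)
  out <- extract_respiration(rec, bcg)
  expect_equal(nrow(out), nrow(rec))
  expect_gt(stats::cor(out$amplitude, resp), 0.95)

  zero <- raw_recording(rep(0, 1000), sample_rate_hz = fs)
  expect_true(all(extract_respiration(zero, zero)$amplitude == 0))

  pure <- sine_recording(6, 30, fs = fs)
  cancelled <- extract_respiration(pure, pure)
  expect_lt(signal_rms(cancelled$amplitude), 0.05 * signal_rms(pure$amplitude))

  expect_error(extract_respiration(rec, raw_recording(1:10, fs)), "length")
})

test_that("breath detection finds sinusoid peaks at the right spacing", {
  resp <- sine_recording(0.25, 60, fs = 100)
  ev <- detect_breaths(resp)
  expect_gte(nrow(ev), 14)
  expect_lte(nrow(ev), 15)
  iv <- diff(ev$time_s)
  expect_true(all(iv >= 3.9 & iv <= 4.1))

  zero <- raw_recording(rep(0, 1000), sample_rate_hz = 100)
  expect_equal(nrow(detect_breaths(zero)), 0)
})

test_that("breath intervals recovered from low-noise simulation", {
  h <- hypnogram(rep("NREM", 8))
  cfg <- sim_config(sample_rate_hz = 200, noise_sd = 0.01)
  sim <- sim_recording(h, cfg, seed = 14)
  pp <- preprocess_recording(sim$recording)
  m <- match_events(pp$breaths$time_s, sim$truth$breath_times, tol_s = 1.5)
  ok <- !is.na(m$detected_time)
  pair_ok <- ok[-length(ok)] & ok[-1]
  err <- abs(diff(m$detected_time)[pair_ok] - diff(m$truth_time)[pair_ok])
  expect_lt(mean(err), 0.2)
})

test_that("full preprocessing keeps events out of movement windows", {
  h <- hypnogram(rep(c("Wake", "NREM"), each = 5))
  sim <- sim_recording(h, sim_config(sample_rate_hz = 200), seed = 17)
  pp <- preprocess_recording(sim$recording)
  expect_false(any(in_movement(pp$beats$time_s, pp$mask)))
  expect_false(any(in_movement(pp$breaths$time_s, pp$mask)))
  # determinism end to end
  pp2 <- preprocess_recording(sim$recording)
  expect_identical(pp$beats$time_s, pp2$beats$time_s)
  expect_identical(pp$mask$movement, pp2$mask$movement)
})
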