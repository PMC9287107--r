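test_that("overlap-weighted interval estimates match hand-worked cases", {
  # three 1.0-s intervals exactly tiling a 3-s window
  ev <- event_series(c(0, 1, 2, 3), "heartbeat")
  s <- scaled_intervals(ev, mask = NULL, timescale = 3, duration_s = 3)
  expect_equal(s$value, 1.0)

  # 40% covered by a 0.8-s interval, 60% by a 1.2-s interval:
  # (0.4*0.8 + 0.6*1.2) / 1.0 = 1.04
  ev2 <- event_series(c(-0.4, 0.4, 1.6), "heartbeat")
  s2 <- scaled_intervals(ev2, mask = NULL, timescale = 1, duration_s = 1)
  expect_equal(s2$value[1], 1.04, tolerance = 1e-12)

  # a window fully inside a movement episode is invalid
  mask <- make_mask(c(1, 1, 1, 0, 0))
  ev3 <- event_series(seq(0, 10, by = 1), "heartbeat")
  s3 <- scaled_intervals(ev3, mask, timescale = 3, duration_s = 10)
  expect_true(is.na(s3$value[1]))

  expect_error(scaled_intervals(ev3, mask, timescale = 4), "timescale")
})

test_that("estimator equals the brute-force weighted mean on random windows", {
  n_checked <- 0
  for (case in 1:40) {
    withr::with_seed(1000 + case, {
      t <- sample(TIMESCALES, 1)
      dur <- 60
      ev_times <- cumsum(stats::runif(80, 0.4, 1.6))
      ev_times <- ev_times[ev_times < dur]
      states <- stats::rbinom(30, 1, 0.15)
    })
    ev <- event_series(ev_times, "heartbeat")
    mask <- make_mask(states)
    s <- scaled_intervals(ev, mask, timescale = t, duration_s = dur)
    mask_iv <- somnosense:::mask_intervals(mask)
    for (w in s$window) {
      expected <- brute_scaled_value(ev$time_s, mask_iv, t, w, c(0.3, 2))
      expect_equal(s$value[w], expected, tolerance = 1e-12)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 300)
})

test_that("independent features follow their definitions", {
  const <- make_series(rep(1, 60), timescale = 1)
  f <- independent_features(const, 1, prefix = "hi")
  expect_equal(unname(f["hi_mean"]), 1)
  expect_equal(unname(f["hi_cv"]), 0)
  expect_equal(unname(f[paste0("hi_p", c("100_p0", "90_p10", "80_p20", "70_p30", "60_p40"))]),
               rep(1, 5))
  expect_equal(unname(f["hi_mad"]), 0)

  tri <- make_series(rep(c(0.8, 1.0, 1.2), each = 20), timescale = 1)
  f2 <- independent_features(tri, 1, prefix = "hi")
  expect_equal(unname(f2["hi_p100_p0"]), 1.5)

  # epoch fully invalid -> all nine invalid
  inv <- make_series(rep(NA_real_, 60), timescale = 1)
  f3 <- independent_features(inv, 1, prefix = "hi")
  expect_true(all(is.na(f3)))
})

test_that("ACD matches a direct evaluation on constant and step series", {
  const <- make_series(rep(1, 300), timescale = 1)
  expect_equal(compute_acd(const, 3), 0)

  # step at the centre of epoch 3 (t = 150 s): 1.0 before, 1.2 after
  step_vals <- c(rep(1.0, 150), rep(1.2, 150))
  stepped <- make_series(step_vals, timescale = 1)
  acd <- compute_acd(stepped, 3)
  expect_gt(acd, 0)
  # brute force over the same slide positions, step t over +/- 2 min
  u_seq <- seq(150 - 120, 150 + 120, by = 1)
  d <- vapply(u_seq, function(u) {
    st <- seq(0, 299)
    left <- step_vals[st > u - 30 & st <= u]
    right <- step_vals[st > u & st <= u + 30]
    abs(mean(left) - mean(right))
  }, numeric(1))
  expect_equal(acd, mean(d), tolerance = 1e-12)
  expect_equal(max(d), 0.2)
  # with half-open (u-30, u] halves the step is isolated at u = 149: the
  # last slide whose left half is all-1.0 and right half all-1.2
  expect_equal(u_seq[which.max(d)], 149)

  inv <- make_series(rep(NA_real_, 300), timescale = 1)
  expect_true(is.na(compute_acd(inv, 3)))
})

test_that("CHR ratios follow the ratio/invalidity rules", {
  hi <- make_series(rep(1, 60), timescale = 1, kind = "heartbeat")
  ri <- make_series(rep(4, 60), timescale = 1, kind = "breath")
  f <- chr_features(hi, ri, 1)
  expect_equal(unname(f["chr_mean_ratio"]), 0.25)
  pct_names <- grep("^chr_p", names(f), value = TRUE)
  expect_equal(unname(f[pct_names]), rep(0.25, 11))
  expect_true(is.na(f["chr_cv_ratio"]))  # 0/0

  hi2 <- make_series(rep(c(0.8, 1.0, 1.2), 20), timescale = 1)
  ri2 <- make_series(rep(c(3, 4, 5), 20), timescale = 1)
  f2 <- chr_features(hi2, ri2, 1)
  expect_equal(unname(f2["chr_p100_p0"]), 1.2 / 3.0)

  ri_wrong <- make_series(rep(4, 10), timescale = 3)
  expect_error(chr_features(hi, ri_wrong, 1), "timescale")
})

test_that("CHR features are invariant to a common rescaling", {
  withr::with_seed(5, {
    hi <- make_series(stats::runif(60, 0.8, 1.2), timescale = 1)
    ri <- make_series(stats::runif(60, 3, 5), timescale = 1)
  })
  f1 <- chr_features(hi, ri, 1)
  c_scale <- 3.7
  hi2 <- make_series(hi$value * c_scale, timescale = 1)
  ri2 <- make_series(ri$value * c_scale, timescale = 1)
  f2 <- chr_features(hi2, ri2, 1)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("BM features count movement runs correctly", {
  empty <- make_mask(rep(0, 90))
  expect_equal(unname(bm_features(empty, 1)), rep(0, 8))

  # one 6-s run inside epoch 1
  m1 <- make_mask(c(rep(0, 5), 1, 1, 1, rep(0, 82)))
  f1 <- bm_features(m1, 1)
  expect_equal(unname(f1["motion_ratio"]), 0.1)
  expect_equal(unname(f1["motion_nums"]), 1)
  expect_equal(unname(f1["largest_motion_ratio"]), 0.1)
  expect_equal(unname(f1["avg_motion_ratio"]), 0.1)

  # two runs, 4 s and 2 s
  m2 <- make_mask(c(1, 1, 0, 0, 1, rep(0, 85)))
  f2 <- bm_features(m2, 1)
  expect_equal(unname(f2["motion_ratio"]), 0.1)
  expect_equal(unname(f2["motion_nums"]), 2)
  expect_equal(unname(f2["largest_motion_ratio"]), 4 / 60)
  expect_equal(unname(f2["avg_motion_ratio"]), 0.05)

  # neighbour motion ratios, zero out of range
  f3 <- bm_features(m1, 2)
  expect_equal(unname(f3["motion_ratio_prev1"]), 0.1)
  expect_equal(unname(f3["motion_ratio_prev2"]), 0)
  expect_equal(unname(f3["motion_ratio_next1"]), 0)
})

test_that("assembled feature matrix has the full 41-column schema", {
  h <- hypnogram(rep("NREM", 10))
  cfg <- sim_config(sample_rate_hz = 100, noise_sd = 0.01,
                    movement_rate = c(Wake = 0, REM = 0, NREM = 0))
  sim <- sim_recording(h, cfg, seed = 23)
  feats <- extract_epoch_features(sim$recording, timescale = 9)
  expect_equal(nrow(feats), 10)
  expect_equal(names(feats), c("epoch_index", feature_names()))
  v <- feature_validity(feats)
  expect_true(all(as.matrix(v)))
})

test_that("a fully-movement epoch invalidates features 1-33, BM stays valid", {
  states <- c(rep(1, 30), rep(0, 60))  # epoch 1 all movement
  mask <- make_mask(states)
  ev_h <- event_series(seq(0.5, 179, by = 1), "heartbeat")
  ev_r <- event_series(seq(0.5, 179, by = 4), "breath")
  hi <- scaled_intervals(ev_h, mask, 9, duration_s = 180)
  ri <- scaled_intervals(ev_r, mask, 9, duration_s = 180)
  feats <- assemble_features(hi, ri, mask)
  v <- feature_validity(feats)
  expect_false(any(as.logical(v[1, 1:33])))
  expect_true(all(as.logical(v[1, 34:41])))
  expect_equal(feats$f34_motion_ratio[1], 1.0)
})

test_that("enlarging the movement mask never revalidates a window", {
  withr::with_seed(77, {
    ev <- event_series(cumsum(stats::runif(120, 0.6, 1.4)), "heartbeat")
    base_states <- stats::rbinom(45, 1, 0.1)
  })
  bigger <- pmax(base_states, c(rep(0, 10), rep(1, 5), rep(0, 30)))
  s_base <- scaled_intervals(ev, make_mask(base_states), 9, duration_s = 90)
  s_big <- scaled_intervals(ev, make_mask(bigger), 9, duration_s = 90)
  expect_true(all(!is.na(s_base$value[!is.na(s_big$value)])))
})

test_that("heartbeat variability separates Wake from NREM on simulator data", {
  h <- hypnogram(rep(c("Wake", "NREM"), each = 15))
  sim <- sim_recording(h, sim_config(sample_rate_hz = 100), seed = 29)
  feats <- extract_epoch_features(sim$recording, timescale = 9)
  cv_wake <- feats$f02_hi_cv[h$stage == "Wake"]
  cv_nrem <- feats$f02_hi_cv[h$stage == "NREM"]
  wt <- stats::wilcox.test(cv_wake, cv_nrem, alternative = "greater", exact = FALSE)
  expect_lt(wt$p.value, 0.05)
})
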