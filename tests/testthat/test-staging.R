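test_that("reference scores collapse to Wake/REM/NREM 60-s epochs", {
  expect_equal(reference_epochs(c("N2", "N2"))$stage, "NREM")
  # majority tie broken toward the earlier label
  expect_equal(reference_epochs(c("Wake", "REM"))$stage, "Wake")
  expect_equal(reference_epochs(c("REM", "REM", "Wake", "Wake"))$stage,
               c("REM", "Wake"))
  expect_equal(reference_epochs(c("N1", "N3", "R", "W"))$stage, c("NREM", "REM"))
  # 60-s input passes through
  expect_equal(reference_epochs(c("N3", "REM"), epoch_len_in_s = 60)$stage,
               c("NREM", "REM"))
  expect_error(reference_epochs(c("N2", "junk")), "unknown")
})

test_that("classifiers separate a linearly separable corpus and are deterministic", {
  df <- separable_features(30)
  test_df <- df[, feature_names()]
  for (clf in c("rf", "dt", "knn", "svm", "adaboost")) {
    pred <- train_and_predict(df, test_df, classifier = clf, seed = 3)
    acc <- mean(pred$stage == df$stage)
    expect_gte(acc, 0.99)
  }
  p1 <- train_and_predict(df, test_df, classifier = "rf", seed = 3)
  p2 <- train_and_predict(df, test_df, classifier = "rf", seed = 3)
  expect_identical(p1$stage, p2$stage)

  bad <- df[, 1:10]
  expect_error(train_and_predict(bad, test_df), "missing feature")
})

test_that("agreement metrics match the contingency-table oracle", {
  # perfect agreement
  s <- random_stages(50, seed = 1)
  ag <- agreement_metrics(s, s)
  expect_equal(ag$p0, 1)
  expect_equal(ag$kappa, 1)

  # hand-built example: 5 NREM / 3 REM / 2 Wake reference, all-NREM predicted
  ref <- c(rep("NREM", 5), rep("REM", 3), rep("Wake", 2))
  pred <- rep("NREM", 10)
  ag2 <- agreement_metrics(pred, ref)
  expect_equal(ag2$p0, 0.5)
  oracle <- brute_agreement(pred, ref)
  expect_equal(ag2$pe, oracle$pe)
  expect_equal(ag2$kappa, oracle$kappa)

  # random pairs: implementation vs oracle
  for (case in 1:50) {
    n <- 37
    p <- random_stages(n, seed = 100 + case)
    r <- random_stages(n, seed = 500 + case)
    a <- agreement_metrics(p, r)
    o <- brute_agreement(p, r)
    expect_equal(a$p0, o$p0, tolerance = 1e-12)
    expect_equal(a$pe, o$pe, tolerance = 1e-12)
    expect_equal(a$kappa, o$kappa, tolerance = 1e-12)
  }

  expect_error(agreement_metrics(rep("Wake", 3), rep("Wake", 4)), "length")
})

test_that("kappa is near zero for independent raters and bounded by 1", {
  p <- random_stages(10000, seed = 7)
  r <- random_stages(10000, seed = 8)
  k <- agreement_metrics(p, r)$kappa
  expect_lt(abs(k), 0.05)

  for (case in 1:20) {
    pr <- random_stages(60, seed = 900 + case)
    rf <- random_stages(60, seed = 950 + case)
    kk <- agreement_metrics(pr, rf)$kappa
    expect_lte(kk, 1)
    if (all(pr == rf)) expect_equal(kk, 1)
  }
})

test_that("consistent relabelling leaves p0 and kappa unchanged", {
  p <- random_stages(200, seed = 12)
  r <- random_stages(200, seed = 13)
  perm <- c(Wake = "REM", REM = "NREM", NREM = "Wake")
  a1 <- agreement_metrics(p, r)
  a2 <- agreement_metrics(unname(perm[p]), unname(perm[r]))
  expect_equal(a1$p0, a2$p0)
  expect_equal(a1$kappa, a2$kappa)
})

test_that("performance summary uses population-divisor dispersion", {
  s <- summarize_performance(c(80))
  expect_equal(s$mean_accuracy, 80)
  expect_equal(s$sd_accuracy, 0)
  s2 <- summarize_performance(c(1, 2, 3), c(0.1, 0.2, 0.3))
  expect_equal(s2$sd_accuracy, sqrt(2 / 3))
  expect_error(summarize_performance(numeric(0)), "summarize")
})

test_that("LOOCV visits each recording once and ignores corpus order", {
  df <- separable_features(20)
  mk_rec <- function(seed) {
    withr::with_seed(seed, {
      idx <- sample(nrow(df), 40)
    })
    f <- df[idx, feature_names()]
    list(features = f, reference = hypnogram(df$stage[idx]))
  }
  corpus <- list(a = mk_rec(1), b = mk_rec(2), c = mk_rec(3))
  cv <- loocv_stage(corpus, classifier = "rf", seed = 5)
  expect_setequal(names(cv$folds), c("a", "b", "c"))
  expect_equal(sum(vapply(cv$folds, function(f) f$agreement_pre$total, numeric(1))), 120)

  cv_perm <- loocv_stage(corpus[c(3, 1, 2)], classifier = "rf", seed = 5)
  td1 <- tidy(cv)[order(tidy(cv)$recording), ]
  td2 <- tidy(cv_perm)[order(tidy(cv_perm)$recording), ]
  expect_equal(td1, td2)

  expect_error(loocv_stage(corpus[1]), "two recordings")
})

test_that("a degenerate all-NREM fold is scored without error", {
  df <- separable_features(20)
  deg_f <- df[df$stage == "NREM", feature_names()]
  corpus <- list(
    a = list(features = df[, feature_names()], reference = hypnogram(df$stage)),
    b = list(features = deg_f, reference = hypnogram(rep("NREM", nrow(deg_f))))
  )
  cv <- loocv_stage(corpus, classifier = "rf", seed = 2)
  ag <- cv$folds$b$agreement_pre
  expect_true(is.finite(ag$pe))
  expect_true(is.finite(ag$kappa))
})

test_that("feature importance normalizes, dilutes on duplication, finds planted signal", {
  withr::with_seed(61, {
    n <- 240
    stages <- sample(SLEEP_STAGES, n, replace = TRUE)
    base <- matrix(stats::rnorm(n * 41, 0, 1), ncol = 41)
    colnames(base) <- feature_names()
    # plant the label signal exclusively in feature 34 (BM group)
    base[, 34] <- match(stages, SLEEP_STAGES) + stats::rnorm(n, 0, 0.1)
    feats <- tibble::as_tibble(as.data.frame(base))
  })
  fi <- feature_importance(feats, stages, seed = 9)
  expect_equal(sum(fi$per_feature$importance), 1, tolerance = 1e-9)
  expect_equal(fi$groups$group[1], "BM")

  expect_error(feature_importance(feats, stages, classifier = "svm"), "rf")

  # duplicating the informative feature splits, not doubles, its share
  single_share <- fi$per_feature$importance[34]
  feats_dup <- feats
  feats_dup$f35_motion_nums <- feats$f34_motion_ratio
  fi2 <- feature_importance(feats_dup, stages, seed = 9)
  combined <- fi2$per_feature$importance[34] + fi2$per_feature$importance[35]
  expect_lt(abs(combined - single_share) / single_share, 0.2)
})
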