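CLASSIFIERS <- c("rf", "svm", "dt", "knn", "adaboost")

check_feature_schema <- function(df, where) {
  missing <- setdiff(feature_names(), names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      where, " is missing feature column(s): ", paste(missing, collapse = ", ")
    ))
  }
}

feature_matrix <- function(df) {
  as.matrix(df[, feature_names(), drop = FALSE])
}

# inverse-class-frequency weights over the training labels (mean 1)
class_weights <- function(y) {
  freq <- table(y)
  w <- 1 / as.numeric(freq)
  w <- w / mean(w)
  names(w) <- names(freq)
  w
}

zscore_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}

zscore_apply <- function(x, z) sweep(sweep(x, 2, z$mu), 2, z$sd, "/")

# multiclass AdaBoost (SAMME) over rpart trees; written in-package since no
# boosting classifier ships with the installed stack
fit_adaboost_samme <- function(x, y, n_rounds = 50, maxdepth = 3, base_w = NULL) {
  k <- nlevels(y)
  n <- nrow(x)
  w <- if (is.null(base_w)) rep(1 / n, n) else base_w / sum(base_w)
  dat <- data.frame(.y = y, x, check.names = FALSE)
  models <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(
      .y ~ ., data = dat, weights = w * n, method = "class",
      control = rpart::rpart.control(maxdepth = maxdepth, cp = 0, minsplit = 5,
                                     xval = 0)
    )
    pred <- predict(fit, dat, type = "class")
    err <- sum(w * (pred != y))
    if (err >= 1 - 1 / k || err <= 0) {
      if (length(models) == 0 && err <= 0) {
        models[[1]] <- fit
        alphas <- 1
      }
      break
    }
    alpha <- log((1 - err) / err) + log(k - 1)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    models[[length(models) + 1]] <- fit
    alphas <- c(alphas, alpha)
  }
  structure(list(models = models, alphas = alphas, levels = levels(y)),
            class = "adaboost_samme")
}

predict_adaboost_samme <- function(obj, x) {
  votes <- matrix(0, nrow(x), length(obj$levels),
                  dimnames = list(NULL, obj$levels))
  dat <- as.data.frame(x, check.names = FALSE)
  for (m in seq_along(obj$models)) {
    pred <- predict(obj$models[[m]], dat, type = "class")
    idx <- cbind(seq_len(nrow(x)), match(as.character(pred), obj$levels))
    votes[idx] <- votes[idx] + obj$alphas[m]
  }
  obj$levels[max.col(votes, ties.method = "first")]
}

#' Train a stage classifier and predict test epochs
#'
#' Trains one of five classifiers on labelled 41-feature epochs and predicts
#' the stage of each test epoch. Inverse-class-frequency weights from the
#' training labels counter the NREM majority (NREM typically dominates a
#' night at ~64%) for the weight-capable models; features are z-scored from
#' the training fold for SVM and KNN, while tree models see raw features.
#' Deterministic given `seed`.
#'
#' @param train Tibble with the 41 feature columns plus a `stage` column.
#' @param test Tibble with the 41 feature columns.
#' @param classifier One of `"rf"` (random forest, 100 trees; the default
#'   analysis classifier), `"svm"`, `"dt"`, `"knn"`, `"adaboost"`.
#' @param seed RNG seed.
#' @param ... Passed to the underlying fitting function.
#' @return A [hypnogram()] of predicted test-epoch stages.
#' @export
train_and_predict <- function(train, test, classifier = "rf", seed = 1, ...) {
  classifier <- match.arg(classifier, CLASSIFIERS)
  check_feature_schema(train, "`train`")
  check_feature_schema(test, "`test`")
  if (!"stage" %in% names(train)) rlang::abort("`train` needs a `stage` column")
  y <- factor(stage_labels(train), levels = SLEEP_STAGES)
  y <- droplevels(y)
  x <- feature_matrix(train)
  xt <- feature_matrix(test)
  if (nlevels(y) == 1) {
    # degenerate training fold: only one stage observed
    return(hypnogram(rep(levels(y), nrow(xt)),
                     epoch_len_s = attr(test, "epoch_len_s") %||% 60))
  }
  cw <- class_weights(y)

  pred <- with_local_seed(seed, {
    switch(classifier,
      rf = {
        fit <- randomForest::randomForest(x = x, y = y, ntree = 100,
                                          classwt = cw[levels(y)], ...)
        as.character(predict(fit, xt))
      },
      svm = {
        z <- zscore_fit(x)
        fit <- e1071::svm(zscore_apply(x, z), y,
                          class.weights = cw[levels(y)], scale = FALSE, ...)
        as.character(predict(fit, zscore_apply(xt, z)))
      },
      dt = {
        dat <- data.frame(.y = y, x, check.names = FALSE)
        case_w <- unname(cw[as.character(y)])
        fit <- rpart::rpart(.y ~ ., data = dat, weights = case_w,
                            method = "class", ...)
        as.character(predict(fit, as.data.frame(xt, check.names = FALSE),
                             type = "class"))
      },
      knn = {
        z <- zscore_fit(x)
        as.character(class::knn(zscore_apply(x, z), zscore_apply(xt, z),
                                cl = y, k = 5, ...))
      },
      adaboost = {
        case_w <- unname(cw[as.character(y)])
        fit <- fit_adaboost_samme(x, y, base_w = case_w, ...)
        predict_adaboost_samme(fit, xt)
      }
    )
  })
  hypnogram(pred, epoch_len_s = attr(test, "epoch_len_s") %||% 60)
}

#' Recording-level leave-one-out cross-validation
#'
#' Each recording in the corpus serves exactly once as the held-out test
#' set while the classifier trains on all the others; predictions are
#' scored against the reference hypnogram both before and after rule-based
#' [fuse_hypnogram()] smoothing. Training rows are assembled in sorted
#' recording-id order, so per-recording results do not depend on the order
#' the corpus list is given in.
#'
#' @param corpus Named list; each element a list with `features` (tibble
#'   from [assemble_features()]) and `reference` (a [hypnogram()] of equal
#'   epoch count). Unnamed corpora get ids `rec01`, `rec02`, ...
#' @param classifier See [train_and_predict()].
#' @param seed RNG seed (one seed drives every fold deterministically).
#' @param fusion A [fusion_config()].
#' @return A `staging_cv` object; see [tidy.staging_cv()] and
#'   [glance.staging_cv()].
#' @export
loocv_stage <- function(corpus, classifier = "rf", seed = 1,
                        fusion = fusion_config()) {
  if (length(corpus) < 2) rlang::abort("LOOCV needs at least two recordings")
  if (is.null(names(corpus)) || any(names(corpus) == "")) {
    names(corpus) <- sprintf("rec%02d", seq_along(corpus))
  }
  ids <- sort(names(corpus))
  labelled <- lapply(ids, function(id) {
    f <- corpus[[id]]$features
    r <- as_hypnogram(corpus[[id]]$reference)
    if (nrow(f) != nrow(r)) {
      rlang::abort(sprintf(
        "recording %s: %d feature epochs vs %d reference epochs", id, nrow(f), nrow(r)
      ))
    }
    dplyr::mutate(f, stage = r$stage, .recording = id)
  })
  names(labelled) <- ids

  folds <- lapply(ids, function(id) {
    train <- dplyr::bind_rows(labelled[setdiff(ids, id)])
    test <- labelled[[id]]
    predicted <- train_and_predict(train, test, classifier, seed = seed)
    fused <- fuse_hypnogram(predicted, fusion)$hypnogram
    reference <- as_hypnogram(corpus[[id]]$reference)
    list(
      recording = id,
      predicted = predicted,
      fused = fused,
      reference = reference,
      agreement_pre = agreement_metrics(predicted, reference),
      agreement_post = agreement_metrics(fused, reference)
    )
  })
  names(folds) <- ids

  pool <- function(field) {
    agreement_metrics(
      unlist(lapply(folds, function(f) stage_labels(f[[field]]))),
      unlist(lapply(folds, function(f) stage_labels(f$reference)))
    )
  }
  structure(
    list(
      folds = folds,
      pooled_pre = pool("predicted"),
      pooled_post = pool("fused"),
      classifier = classifier,
      seed = seed
    ),
    class = "staging_cv"
  )
}

#' @export
print.staging_cv <- function(x, ...) {
  cat(sprintf(
    "# LOOCV staging (%s, %d recordings): pooled accuracy %.3f -> %.3f after fusion, kappa %.3f -> %.3f\n",
    x$classifier, length(x$folds),
    x$pooled_pre$p0, x$pooled_post$p0, x$pooled_pre$kappa, x$pooled_post$kappa
  ))
  invisible(x)
}

#' Random-forest feature importance, by feature and feature group
#'
#' Fits a random forest to labelled epochs and reports Gini importances
#' normalized to sum 1, plus the aggregate share of the four feature
#' groups: HI (features 1–9), RI (10–18), CHR (19–33), BM (34–41).
#'
#' @param features Tibble with the 41 feature columns.
#' @param stage Stage labels, one per row of `features`.
#' @param seed RNG seed.
#' @param classifier Must be `"rf"`; importances are a random-forest notion
#'   here, other classifiers are rejected.
#' @param ntree Number of trees.
#' @return List with `per_feature` and `groups` tibbles.
#' @export
feature_importance <- function(features, stage, seed = 1, classifier = "rf",
                               ntree = 200) {
  if (!identical(classifier, "rf")) {
    rlang::abort("feature importance is only defined for the rf classifier")
  }
  check_feature_schema(features, "`features`")
  y <- droplevels(factor(stage_labels(stage), levels = SLEEP_STAGES))
  x <- feature_matrix(features)
  imp <- with_local_seed(seed, {
    # bagged trees (mtry = p): every split sees every feature, so the
    # importance of a signal does not depend on how many correlated copies
    # of it happen to enter the candidate subset
    fit <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                      mtry = ncol(x),
                                      classwt = class_weights(y)[levels(y)])
    randomForest::importance(fit)[, "MeanDecreaseGini"]
  })
  share <- imp / sum(imp)
  group <- rep(c("HI", "RI", "CHR", "BM"), times = c(9, 9, 15, 8))
  per_feature <- tibble::tibble(
    feature = feature_names(), group = group, importance = unname(share)
  )
  groups <- per_feature |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(share = sum(.data$importance), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$share))
  list(per_feature = per_feature, groups = groups)
}
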