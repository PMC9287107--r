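INTER_PERCENTILE_PAIRS <- list(
  c(100, 0), c(90, 10), c(80, 20), c(70, 30), c(60, 40)
)
INTRA_PERCENTILE_PAIRS <- list(
  c(100, 0), c(90, 10), c(80, 20), c(70, 30), c(60, 40), c(50, 50),
  c(40, 60), c(30, 70), c(20, 80), c(10, 90), c(0, 100)
)

#' The 41 staging feature names
#'
#' Stable snake_case names for the per-epoch feature vector: 1–9 heartbeat
#' interval (HI) features, 10–18 respiratory interval (RI) features, 19–33
#' cardiorespiratory coordination (CHR) ratios, 34–41 body-movement (BM)
#' features.
#'
#' @return Character vector of 41 names in index order.
#' @export
feature_names <- function() {
  ind <- function(prefix) {
    c(
      paste0(prefix, "_mean"), paste0(prefix, "_cv"),
      vapply(INTER_PERCENTILE_PAIRS, function(p) {
        sprintf("%s_p%d_p%d", prefix, p[1], p[2])
      }, character(1)),
      paste0(prefix, "_mad"), paste0(prefix, "_acd")
    )
  }
  chr <- c(
    "chr_mean_ratio", "chr_cv_ratio",
    vapply(INTRA_PERCENTILE_PAIRS, function(p) {
      sprintf("chr_p%d_p%d", p[1], p[2])
    }, character(1)),
    "chr_mad_ratio", "chr_acd_ratio"
  )
  bm <- c(
    "motion_ratio", "motion_nums", "largest_motion_ratio",
    "avg_motion_ratio", "motion_ratio_prev1", "motion_ratio_prev2",
    "motion_ratio_next1", "motion_ratio_next2"
  )
  nm <- c(ind("hi"), ind("ri"), chr, bm)
  sprintf("f%02d_%s", seq_along(nm), nm)
}

# values of a scaled series whose window start lies in the given 60-s epoch
epoch_values <- function(series, epoch_index, epoch_len_s = 60) {
  a <- (epoch_index - 1) * epoch_len_s
  series$value[series$start_s >= a & series$start_s < a + epoch_len_s]
}

safe_ratio <- function(num, den) {
  if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
}

# percentile with linear interpolation between order statistics (type 7);
# P0 = min, P100 = max
pctl <- function(x, p) as.numeric(stats::quantile(x, p / 100, type = 7, names = FALSE))

#' Averaged cumulative difference (ACD) of a scaled series
#'
#' The moving average of the absolute difference between the mean of the
#' former 30 s and the latter 30 s of the series, slid in steps of the
#' series timescale over a context of +/- `q` minutes around the epoch
#' centre (clipped at the recording edges). Positions where either
#' half-window holds no valid value are skipped; `NA` when no position
#' qualifies.
#'
#' @param series A [scaled_intervals()] tibble.
#' @param epoch_index 1-based 60-s epoch index.
#' @param q Context half-width, minutes.
#' @param epoch_len_s Epoch length, seconds.
#' @return ACD in seconds, or `NA`.
#' @export
compute_acd <- function(series, epoch_index, q = 2, epoch_len_s = 60) {
  if (q < 0) rlang::abort("`q` must be non-negative")
  t <- series_timescale(series)
  span_end <- max(series$start_s) + t
  k <- (epoch_index - 0.5) * epoch_len_s
  u_seq <- seq(max(0, k - q * 60), min(span_end, k + q * 60), by = t)

  st <- series$start_s
  v <- series$value
  d <- vapply(u_seq, function(u) {
    left <- v[st > u - 30 & st <= u]
    right <- v[st > u & st <= u + 30]
    left <- left[!is.na(left)]
    right <- right[!is.na(right)]
    if (length(left) == 0 || length(right) == 0) return(NA_real_)
    abs(mean(left) - mean(right))
  }, numeric(1))
  d <- d[!is.na(d)]
  if (length(d) == 0) NA_real_ else mean(d)
}

# the statistics both the independent features and the CHR ratios draw on
epoch_stats <- function(series, epoch_index, epoch_len_s = 60, q = 2) {
  x <- epoch_values(series, epoch_index, epoch_len_s)
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    return(list(n_valid = length(x), mean = NA_real_, cv = NA_real_,
                mad = NA_real_, acd = NA_real_, pctl = NULL))
  }
  m <- mean(x)
  list(
    n_valid = length(x),
    mean = m,
    cv = if (m == 0) NA_real_ else stats::sd(x) / m,
    mad = stats::median(abs(x - stats::median(x))),
    acd = compute_acd(series, epoch_index, q = q, epoch_len_s = epoch_len_s),
    pctl = function(p) pctl(x, p)
  )
}

#' Independent features of one interval series over one epoch
#'
#' Nine statistics of the valid t-second interval estimates whose window
#' starts fall in the epoch: mean; coefficient of variation (SD/mean); five
#' inter-percentile ratios P_A/P_B for (A,B) in (100,0), (90,10), (80,20),
#' (70,30), (60,40); median absolute deviation; and the [compute_acd()]
#' context statistic. All nine are `NA` when fewer than two valid windows
#' fall in the epoch.
#'
#' @inheritParams compute_acd
#' @param prefix Name prefix (`"hi"` or `"ri"`).
#' @return Named numeric vector of length 9.
#' @export
independent_features <- function(series, epoch_index, epoch_len_s = 60,
                                 prefix = attr(series, "kind") %||% "hi") {
  prefix <- if (identical(prefix, "heartbeat")) "hi" else if (identical(prefix, "breath")) "ri" else prefix
  st <- epoch_stats(series, epoch_index, epoch_len_s)
  if (st$n_valid < 2) {
    out <- rep(NA_real_, 9)
  } else {
    pr <- vapply(INTER_PERCENTILE_PAIRS, function(p) {
      safe_ratio(st$pctl(p[1]), st$pctl(p[2]))
    }, numeric(1))
    out <- c(st$mean, st$cv, pr, st$mad, st$acd)
  }
  names(out) <- c(
    paste0(prefix, "_mean"), paste0(prefix, "_cv"),
    vapply(INTER_PERCENTILE_PAIRS, function(p) {
      sprintf("%s_p%d_p%d", prefix, p[1], p[2])
    }, character(1)),
    paste0(prefix, "_mad"), paste0(prefix, "_acd")
  )
  out
}

#' Cardiorespiratory coordination (CHR) features over one epoch
#'
#' Fifteen ratios of heartbeat-interval statistics to respiratory-interval
#' statistics on the shared timescale: ratio of means, ratio of CVs, eleven
#' intra-percentile ratios P_A(HI)/P_B(RI) for (A,B) from (100,0) down to
#' (0,100), ratio of MADs and ratio of ACDs. A ratio is `NA` when its
#' denominator is zero or either operand is invalid.
#'
#' @param hi,ri [scaled_intervals()] series sharing the same timescale.
#' @inheritParams compute_acd
#' @return Named numeric vector of length 15.
#' @export
chr_features <- function(hi, ri, epoch_index, epoch_len_s = 60) {
  if (!isTRUE(all.equal(series_timescale(hi), series_timescale(ri)))) {
    rlang::abort("`hi` and `ri` must share the same timescale")
  }
  sh <- epoch_stats(hi, epoch_index, epoch_len_s)
  sr <- epoch_stats(ri, epoch_index, epoch_len_s)
  p_ratio <- vapply(INTRA_PERCENTILE_PAIRS, function(p) {
    if (sh$n_valid < 2 || sr$n_valid < 2) return(NA_real_)
    safe_ratio(sh$pctl(p[1]), sr$pctl(p[2]))
  }, numeric(1))
  out <- c(
    safe_ratio(sh$mean, sr$mean),
    safe_ratio(sh$cv, sr$cv),
    p_ratio,
    safe_ratio(sh$mad, sr$mad),
    safe_ratio(sh$acd, sr$acd)
  )
  names(out) <- c(
    "chr_mean_ratio", "chr_cv_ratio",
    vapply(INTRA_PERCENTILE_PAIRS, function(p) {
      sprintf("chr_p%d_p%d", p[1], p[2])
    }, character(1)),
    "chr_mad_ratio", "chr_acd_ratio"
  )
  out
}

# motion ratio of one epoch (movement seconds / epoch length); NA outside span
epoch_motion_ratio <- function(mask, epoch_index, epoch_len_s = 60) {
  wl <- attr(mask, "window_len_s") %||% 2
  n_epochs <- floor(max(mask$end_s) / epoch_len_s)
  if (epoch_index < 1 || epoch_index > n_epochs) return(NA_real_)
  a <- (epoch_index - 1) * epoch_len_s
  w <- mask$movement[mask$start_s >= a & mask$start_s < a + epoch_len_s]
  sum(w) * wl / epoch_len_s
}

#' Body-movement (BM) features of one epoch
#'
#' Eight features read off the 2-s movement mask: the movement proportion
#' of the epoch; the number of maximal movement runs intersecting it; the
#' longest run clipped to the epoch, as a fraction of the epoch; the mean
#' run proportion (motion ratio / run count, 0 when no run); and the motion
#' ratios of the previous one and two and next one and two epochs (0 when
#' out of range).
#'
#' @param mask A movement mask from [detect_movement()].
#' @inheritParams compute_acd
#' @return Named numeric vector of length 8. Always valid.
#' @export
bm_features <- function(mask, epoch_index, epoch_len_s = 60) {
  a <- (epoch_index - 1) * epoch_len_s
  b <- a + epoch_len_s
  runs <- mask_intervals(mask)
  runs <- runs[runs$start_s < b & runs$end_s > a, , drop = FALSE]
  motion_ratio <- epoch_motion_ratio(mask, epoch_index, epoch_len_s)
  if (is.na(motion_ratio)) motion_ratio <- 0
  motion_nums <- nrow(runs)
  largest <- if (motion_nums == 0) 0 else {
    max(pmin(runs$end_s, b) - pmax(runs$start_s, a)) / epoch_len_s
  }
  avg <- if (motion_nums == 0) 0 else motion_ratio / motion_nums
  neighbor <- function(k) {
    r <- epoch_motion_ratio(mask, k, epoch_len_s)
    if (is.na(r)) 0 else r
  }
  c(
    motion_ratio = motion_ratio,
    motion_nums = motion_nums,
    largest_motion_ratio = largest,
    avg_motion_ratio = avg,
    motion_ratio_prev1 = neighbor(epoch_index - 1),
    motion_ratio_prev2 = neighbor(epoch_index - 2),
    motion_ratio_next1 = neighbor(epoch_index + 1),
    motion_ratio_next2 = neighbor(epoch_index + 2)
  )
}

#' Assemble the per-epoch 41-feature matrix
#'
#' One row per complete 60-s epoch: HI features 1–9, RI features 10–18, CHR
#' ratios 19–33, BM features 34–41, named per [feature_names()]. Entries
#' that are invalid (insufficient valid interval windows, zero denominators,
#' fully-movement epochs) are imputed with the per-feature median over the
#' valid epochs of the same recording; the pre-imputation validity pattern
#' is preserved as the `validity` attribute (a parallel logical tibble).
#'
#' @param hi,ri [scaled_intervals()] series on the shared timescale.
#' @param mask A movement mask covering the same span.
#' @param epoch_len_s Epoch length, seconds.
#' @return A tibble with `epoch_index` plus 41 feature columns; attribute
#'   `validity` holds the parallel validity tibble.
#' @export
assemble_features <- function(hi, ri, mask, epoch_len_s = 60) {
  n_epochs <- floor(max(mask$end_s) / epoch_len_s)
  if (n_epochs < 1) rlang::abort("span shorter than one epoch")
  rows <- lapply(seq_len(n_epochs), function(k) {
    c(
      independent_features(hi, k, epoch_len_s, prefix = "hi"),
      independent_features(ri, k, epoch_len_s, prefix = "ri"),
      chr_features(hi, ri, k, epoch_len_s),
      bm_features(mask, k, epoch_len_s)
    )
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- feature_names()
  validity <- !is.na(mat)

  # median imputation over the recording's valid epochs, feature by feature
  for (j in seq_len(ncol(mat))) {
    nas <- is.na(mat[, j])
    if (any(nas)) {
      med <- stats::median(mat[!nas, j])
      mat[nas, j] <- if (is.na(med)) 0 else med
    }
  }

  out <- tibble::as_tibble(as.data.frame(mat))
  out <- dplyr::bind_cols(tibble::tibble(epoch_index = seq_len(n_epochs)), out)
  attr(out, "validity") <- tibble::as_tibble(as.data.frame(validity))
  attr(out, "epoch_len_s") <- epoch_len_s
  class(out) <- c("epoch_features", class(out))
  out
}

#' Validity pattern of an assembled feature matrix
#' @param features Output of [assemble_features()].
#' @return Logical tibble, TRUE where the feature was computed (not imputed).
#' @export
feature_validity <- function(features) attr(features, "validity")

#' Features for one recording, from raw signal to feature matrix
#'
#' Convenience wrapper: [preprocess_recording()], [scaled_intervals()] for
#' beats and breaths at the chosen timescale, then [assemble_features()].
#'
#' @param rec A [raw_recording()].
#' @param timescale Interval-estimation timescale t, seconds (9 by default,
#'   the best-performing working point of the method).
#' @param powerline Stop-band for [remove_powerline()], or `NULL`.
#' @return An [assemble_features()] tibble.
#' @export
extract_epoch_features <- function(rec, timescale = 9, powerline = c(49, 51)) {
  pp <- preprocess_recording(rec, powerline = powerline)
  dur <- rec_duration(as_recording(rec))
  hi <- scaled_intervals(pp$beats, pp$mask, timescale, duration_s = dur)
  ri <- scaled_intervals(pp$breaths, pp$mask, timescale, duration_s = dur)
  assemble_features(hi, ri, pp$mask)
}
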