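#' Stage-fusion configuration
#'
#' Constants of the rule-based hypnogram postprocessor: the Wake-density
#' rule's window (5 min) and proportion threshold (0.8, strict), and the
#' REM-merge rule's gap thresholds, selected by the REM proportion P_REM of
#' the sequence — gaps under 20 min merge when P_REM < 5%, under 7 min when
#' P_REM > 10%, under 15 min for P_REM in \[5%, 10%\].
#'
#' @param wake_density_threshold Strict Wake proportion threshold.
#' @param wake_window_min Wake-density window, minutes.
#' @param rem_gap_low_min Merge threshold when P_REM < `p_rem_low`.
#' @param rem_gap_mid_min Merge threshold for the middle P_REM band.
#' @param rem_gap_high_min Merge threshold when P_REM > `p_rem_high`.
#' @param p_rem_low,p_rem_high P_REM band edges.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(wake_density_threshold = 0.8, wake_window_min = 5,
                          rem_gap_low_min = 20, rem_gap_mid_min = 15,
                          rem_gap_high_min = 7,
                          p_rem_low = 0.05, p_rem_high = 0.10) {
  if (wake_density_threshold <= 0 || wake_density_threshold >= 1) {
    rlang::abort("`wake_density_threshold` must lie in (0, 1)")
  }
  if (p_rem_low >= p_rem_high) rlang::abort("`p_rem_low` must be below `p_rem_high`")
  if (any(c(wake_window_min, rem_gap_low_min, rem_gap_mid_min, rem_gap_high_min) <= 0)) {
    rlang::abort("window and gap minutes must be positive")
  }
  structure(
    list(
      wake_density_threshold = wake_density_threshold,
      wake_window_min = wake_window_min,
      rem_gap_low_min = rem_gap_low_min,
      rem_gap_mid_min = rem_gap_mid_min,
      rem_gap_high_min = rem_gap_high_min,
      p_rem_low = p_rem_low,
      p_rem_high = p_rem_high
    ),
    class = "fusion_config"
  )
}

fusion_labels_in <- function(labels) {
  lab <- stage_labels(labels)
  bad <- setdiff(unique(lab), SLEEP_STAGES)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown stage label(s): ", paste(bad, collapse = ", ")))
  }
  lab
}

fusion_labels_out <- function(lab, template) {
  el <- if (is.data.frame(template)) epoch_len(template) else 60
  hypnogram(lab, epoch_len_s = el)
}

# maximal runs as a tibble: value, start index, end index
label_runs <- function(lab) {
  r <- rle(lab)
  e <- cumsum(r$lengths)
  tibble::tibble(value = r$values, start = e - r$lengths + 1, end = e)
}

#' Fusion rule 1: discrete REM before Wake becomes Wake
#'
#' Sleep progresses Wake -> NREM -> REM; an isolated single-epoch REM run
#' whose immediate successor is Wake is implausible and is relabelled Wake.
#' Multi-epoch REM runs are left alone.
#'
#' @param labels A hypnogram or stage vector.
#' @return A [hypnogram()].
#' @export
rule_rem_to_wake <- function(labels) {
  lab <- fusion_labels_in(labels)
  runs <- label_runs(lab)
  for (i in seq_len(nrow(runs))) {
    if (runs$value[i] == "REM" && runs$end[i] - runs$start[i] == 0 &&
        i < nrow(runs) && runs$value[i + 1] == "Wake") {
      lab[runs$start[i]] <- "Wake"
    }
  }
  fusion_labels_out(lab, labels)
}

#' Fusion rule 2: isolated epochs take the previous label
#'
#' A single interior epoch whose label differs from both neighbours is
#' relabelled as the previous epoch's label, in one left-to-right pass
#' (each test sees the already-updated left neighbour). Sequences shorter
#' than 3 epochs are returned unchanged.
#'
#' @inheritParams rule_rem_to_wake
#' @return A [hypnogram()].
#' @export
rule_isolated_epoch <- function(labels) {
  lab <- fusion_labels_in(labels)
  if (length(lab) >= 3) {
    for (i in 2:(length(lab) - 1)) {
      if (lab[i] != lab[i - 1] && lab[i] != lab[i + 1]) {
        lab[i] <- lab[i - 1]
      }
    }
  }
  fusion_labels_out(lab, labels)
}

#' Fusion rule 3: dense-Wake windows become all Wake
#'
#' Every 5-minute sliding window (stride one epoch) whose Wake proportion
#' strictly exceeds the threshold is fused to Wake. Windows are evaluated
#' on the input sequence in a single scan; changes apply afterwards, so the
#' result does not depend on scan order. With 60-s epochs and the default
#' 0.8 threshold only all-Wake windows qualify, so this rule is an
#' intentional no-op at the default resolution; it becomes active for
#' shorter epochs.
#'
#' @inheritParams rule_rem_to_wake
#' @param config A [fusion_config()].
#' @return A [hypnogram()].
#' @export
rule_wake_density <- function(labels, config = fusion_config()) {
  lab <- fusion_labels_in(labels)
  el <- if (is.data.frame(labels)) epoch_len(labels) else 60
  w <- max(1L, round(config$wake_window_min * 60 / el))
  if (length(lab) >= w) {
    is_wake <- lab == "Wake"
    to_wake <- rep(FALSE, length(lab))
    cs <- cumsum(c(0, is_wake))
    for (i in seq_len(length(lab) - w + 1)) {
      if ((cs[i + w] - cs[i]) / w > config$wake_density_threshold) {
        to_wake[i:(i + w - 1)] <- TRUE
      }
    }
    lab[to_wake] <- "Wake"
  }
  fusion_labels_out(lab, labels)
}

#' Proportion of REM epochs
#'
#' P_REM: the fraction of epochs labelled REM over the whole sequence.
#'
#' @inheritParams rule_rem_to_wake
#' @return A proportion in \[0, 1\].
#' @export
compute_p_rem <- function(labels) {
  lab <- fusion_labels_in(labels)
  if (length(lab) == 0) rlang::abort("empty hypnogram")
  mean(lab == "REM")
}

#' Fusion rule 4: merge nearby REM runs
#'
#' With P_REM computed on the input to this rule, the gap threshold G is
#' 20 min when P_REM < 5%, 7 min when P_REM > 10% and 15 min in between.
#' Every maximal non-REM gap strictly shorter than G lying between two REM
#' runs is relabelled REM; merging repeats until a fixed point (G stays
#' fixed at its input value). REM epochs are never removed by this rule.
#'
#' @inheritParams rule_wake_density
#' @return A [hypnogram()].
#' @export
rule_rem_merge <- function(labels, config = fusion_config()) {
  lab <- fusion_labels_in(labels)
  el <- if (is.data.frame(labels)) epoch_len(labels) else 60
  p_rem <- mean(lab == "REM")
  gap_min <- if (p_rem < config$p_rem_low) {
    config$rem_gap_low_min
  } else if (p_rem > config$p_rem_high) {
    config$rem_gap_high_min
  } else {
    config$rem_gap_mid_min
  }
  gap_epochs <- gap_min * 60 / el

  repeat {
    runs <- label_runs(lab)
    rem_idx <- which(runs$value == "REM")
    changed <- FALSE
    if (length(rem_idx) >= 2) {
      for (j in seq_len(length(rem_idx) - 1)) {
        a <- rem_idx[j]
        b <- rem_idx[j + 1]
        gap_len <- runs$start[b] - runs$end[a] - 1
        if (gap_len > 0 && gap_len < gap_epochs) {
          lab[(runs$end[a] + 1):(runs$start[b] - 1)] <- "REM"
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  fusion_labels_out(lab, labels)
}

#' Rule-based hypnogram fusion
#'
#' Applies the four smoothing rules in order — discrete-REM-before-Wake
#' ([rule_rem_to_wake()]), isolated-epoch ([rule_isolated_epoch()]),
#' Wake-density ([rule_wake_density()]) and REM-merge ([rule_rem_merge()],
#' internally iterated to a fixed point) — once each, and records the
#' intermediate sequences. The composition is idempotent: fusing an already
#' fused hypnogram changes nothing.
#'
#' @inheritParams rule_wake_density
#' @return A list of class `fusion_result`: `hypnogram` (the fused
#'   sequence) and `trace` (tibble with the label sequence after each rule
#'   and the number of epochs each rule changed).
#' @export
#' @examples
#' fuse_hypnogram(c("NREM", "REM", "Wake"))$hypnogram$stage
fuse_hypnogram <- function(labels, config = fusion_config()) {
  lab0 <- fusion_labels_in(labels)
  steps <- list(
    rule1_rem_to_wake = function(l) rule_rem_to_wake(l),
    rule2_isolated_epoch = function(l) rule_isolated_epoch(l),
    rule3_wake_density = function(l) rule_wake_density(l, config),
    rule4_rem_merge = function(l) rule_rem_merge(l, config)
  )
  el <- if (is.data.frame(labels)) epoch_len(labels) else 60
  cur <- hypnogram(lab0, epoch_len_s = el)
  trace <- tibble::tibble(
    rule = "input", n_changed = 0L, labels = list(stage_labels(cur))
  )
  for (nm in names(steps)) {
    nxt <- steps[[nm]](cur)
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      rule = nm,
      n_changed = sum(stage_labels(nxt) != stage_labels(cur)),
      labels = list(stage_labels(nxt))
    ))
    cur <- nxt
  }
  structure(list(hypnogram = cur, trace = trace), class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf(
    "# Fused hypnogram (%d epochs); epochs changed per rule: %s\n",
    nrow(x$hypnogram),
    paste(sprintf("%s=%d", sub("rule\\d_", "", x$trace$rule[-1]),
                  x$trace$n_changed[-1]), collapse = ", ")
  ))
  invisible(x)
}
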