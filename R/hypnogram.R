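#' Sleep stage alphabet
#'
#' The three-class staging alphabet used throughout the package, in the
#' conventional order Wake, REM, NREM (NREM collapses the AASM N1/N2/N3
#' stages).
#'
#' @format Character vector of length 3.
#' @export
SLEEP_STAGES <- c("Wake", "REM", "NREM")

#' Build a hypnogram tibble
#'
#' A hypnogram is the per-epoch sequence of sleep-stage labels over a night.
#' It is represented as a tibble with columns `epoch` (1-based index) and
#' `stage` (one of [SLEEP_STAGES]), carrying the epoch length in seconds as
#' the `epoch_len_s` attribute (60 s by default, the scoring timescale used
#' for classification).
#'
#' @param stage Character vector of stage labels, all in [SLEEP_STAGES].
#' @param epoch_len_s Epoch length in seconds.
#' @return A `hypnogram` tibble with columns `epoch` and `stage`.
#' @export
#' @examples
#' hypnogram(c("Wake", "NREM", "NREM", "REM"))
hypnogram <- function(stage, epoch_len_s = 60) {
  stage <- as.character(stage)
  if (length(stage) == 0) {
    rlang::abort("a hypnogram needs at least one epoch label")
  }
  bad <- setdiff(unique(stage), SLEEP_STAGES)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "unknown stage label(s): ", paste(bad, collapse = ", "),
      " (expected Wake, REM or NREM)"
    ))
  }
  if (!is.numeric(epoch_len_s) || length(epoch_len_s) != 1 || epoch_len_s <= 0) {
    rlang::abort("`epoch_len_s` must be a single positive number")
  }
  out <- tibble::tibble(epoch = seq_along(stage), stage = stage)
  attr(out, "epoch_len_s") <- as.numeric(epoch_len_s)
  class(out) <- c("hypnogram", class(out))
  out
}

#' @export
#' @rdname hypnogram
#' @param x A data frame with a `stage` column (and optionally `epoch`).
as_hypnogram <- function(x, epoch_len_s = attr(x, "epoch_len_s") %||% 60) {
  if (inherits(x, "hypnogram")) {
    return(x)
  }
  if (!is.data.frame(x) || !"stage" %in% names(x)) {
    rlang::abort("`x` must be a data frame with a `stage` column")
  }
  hypnogram(x$stage, epoch_len_s = epoch_len_s)
}

epoch_len <- function(h) attr(h, "epoch_len_s") %||% 60

stage_labels <- function(h) {
  if (is.data.frame(h)) as.character(h$stage) else as.character(h)
}

#' Epoch duration of a hypnogram, in minutes
#' @param h A [hypnogram()].
#' @return Total covered duration in minutes.
#' @export
hypnogram_duration_min <- function(h) {
  nrow(as_hypnogram(h)) * epoch_len(h) / 60
}

#' Collapse fine-grained reference sleep scores to Wake/REM/NREM epochs
#'
#' Clinical scoring software typically emits 30-second epochs over the
#' five-class AASM alphabet (Wake, REM, N1, N2, N3). This maps N1/N2/N3 to
#' NREM and resamples to the target epoch length: when several input epochs
#' form one output epoch the majority label wins, ties broken toward the
#' earlier label; when the input epoch is a multiple of the target, labels
#' are repeated.
#'
#' @param labels Data frame with a `stage` column, or a character vector of
#'   labels in `{Wake, W, REM, R, N1, N2, N3, NREM}`.
#' @param epoch_len_in_s Input epoch length in seconds (30 by default).
#' @param target_len_s Output epoch length in seconds (60 by default).
#' @return A [hypnogram()] at `target_len_s` resolution.
#' @export
#' @examples
#' reference_epochs(c("N2", "N2", "Wake", "REM"))  # -> NREM, Wake
reference_epochs <- function(labels, epoch_len_in_s = 30, target_len_s = 60) {
  lab <- if (is.data.frame(labels)) as.character(labels$stage) else as.character(labels)
  if (length(lab) == 0) rlang::abort("empty reference label sequence")
  map <- c(
    Wake = "Wake", W = "Wake", REM = "REM", R = "REM",
    N1 = "NREM", N2 = "NREM", N3 = "NREM", NREM = "NREM"
  )
  unknown <- setdiff(unique(lab), names(map))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown reference label(s): ", paste(unknown, collapse = ", ")))
  }
  lab <- unname(map[lab])

  if (target_len_s %% epoch_len_in_s == 0) {
    k <- target_len_s / epoch_len_in_s
    n_out <- floor(length(lab) / k)
    if (n_out == 0) rlang::abort("sequence shorter than one target epoch")
    out <- vapply(seq_len(n_out), function(i) {
      chunk <- lab[((i - 1) * k + 1):(i * k)]
      # majority vote; ties go to the label seen earliest in the chunk
      counts <- table(factor(chunk, levels = unique(chunk)))
      names(counts)[which.max(counts)]
    }, character(1))
  } else if (epoch_len_in_s %% target_len_s == 0) {
    k <- epoch_len_in_s / target_len_s
    out <- rep(lab, each = k)
  } else {
    rlang::abort("input epoch length must divide or be divided by the target length")
  }
  hypnogram(out, epoch_len_s = target_len_s)
}

#' @export
print.hypnogram <- function(x, ...) {
  el <- epoch_len(x)
  cat(sprintf(
    "# Hypnogram: %d epochs of %g s (%.1f min total)\n",
    nrow(x), el, nrow(x) * el / 60
  ))
  tab <- table(factor(x$stage, levels = SLEEP_STAGES))
  cat(sprintf(
    "# Wake %d | REM %d | NREM %d\n",
    tab[["Wake"]], tab[["REM"]], tab[["NREM"]]
  ))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
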