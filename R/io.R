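# Plain-text readers/writers for every intermediate artifact, so each
# stage of the pipeline can be run, inspected and resumed from disk.

#' Recording CSV I/O
#'
#' Two-column CSV `time_s,amplitude`; the sample rate is recovered from the
#' time column on read (or can be given explicitly).
#'
#' @param rec A [raw_recording()].
#' @param path File path.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns a recording tibble.
#' @export
write_recording_csv <- function(rec, path) {
  readr::write_csv(tibble::tibble(time_s = rec$time_s, amplitude = rec$amplitude), path)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param sample_rate_hz Optional explicit rate.
#' @export
read_recording_csv <- function(path, sample_rate_hz = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  as_recording(df, sample_rate_hz = sample_rate_hz)
}

#' Hypnogram CSV I/O (`epoch_index,label`)
#'
#' @param h A [hypnogram()].
#' @param path File path.
#' @export
write_hypnogram_csv <- function(h, path) {
  h <- as_hypnogram(h)
  readr::write_csv(tibble::tibble(epoch_index = h$epoch, label = h$stage), path)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @param epoch_len_s Epoch length of the stored hypnogram.
#' @export
read_hypnogram_csv <- function(path, epoch_len_s = 60) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  hypnogram(df$label[order(df$epoch_index)], epoch_len_s = epoch_len_s)
}

#' Event-series CSV I/O (`event_time_s`)
#'
#' @param events An [event_series()].
#' @param path File path.
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(tibble::tibble(event_time_s = events$time_s), path)
  invisible(path)
}

#' @rdname write_events_csv
#' @param kind Event kind of the stored series.
#' @export
read_events_csv <- function(path, kind = "heartbeat") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  event_series(df$event_time_s, kind = kind)
}

#' Movement-mask CSV I/O (`window_index,state`)
#'
#' @param mask A mask from [detect_movement()].
#' @param path File path.
#' @export
write_mask_csv <- function(mask, path) {
  readr::write_csv(tibble::tibble(window_index = mask$window, state = mask$movement), path)
  invisible(path)
}

#' @rdname write_mask_csv
#' @param window_len_s Window length of the stored mask.
#' @export
read_mask_csv <- function(path, window_len_s = 2) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  df <- df[order(df$window_index), ]
  out <- tibble::tibble(
    window = df$window_index,
    start_s = (df$window_index - 1) * window_len_s,
    end_s = df$window_index * window_len_s,
    movement = as.integer(df$state)
  )
  attr(out, "window_len_s") <- window_len_s
  class(out) <- c("movement_mask", class(out))
  out
}

#' Feature-matrix CSV I/O
#'
#' The feature tibble is written with its 41 named columns plus
#' `epoch_index`; the validity channel goes to a parallel CSV when a path
#' is given.
#'
#' @param features Output of [assemble_features()].
#' @param path File path for the feature matrix.
#' @param validity_path Optional path for the validity channel.
#' @export
write_features_csv <- function(features, path, validity_path = NULL) {
  readr::write_csv(tibble::as_tibble(features), path)
  if (!is.null(validity_path)) {
    v <- feature_validity(features)
    if (!is.null(v)) {
      readr::write_csv(dplyr::bind_cols(
        tibble::tibble(epoch_index = features$epoch_index), v
      ), validity_path)
    }
  }
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path, validity_path = NULL) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(validity_path) && file.exists(validity_path)) {
    v <- readr::read_csv(validity_path, show_col_types = FALSE)
    attr(out, "validity") <- v[, setdiff(names(v), "epoch_index")]
  }
  class(out) <- c("epoch_features", class(out))
  out
}

#' Ground-truth JSON I/O
#'
#' @param truth The `truth` element of a [sim_recording()].
#' @param path File path.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(
      beat_times = truth$beat_times,
      breath_times = truth$breath_times,
      movement = truth$movement,
      hypnogram = list(
        labels = stage_labels(truth$hypnogram),
        epoch_len_s = epoch_len(truth$hypnogram)
      )
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  movement <- tibble::as_tibble(j$movement)
  if (nrow(movement) == 0) {
    movement <- tibble::tibble(start_s = numeric(0), end_s = numeric(0))
  }
  list(
    beat_times = as.numeric(j$beat_times),
    breath_times = as.numeric(j$breath_times),
    movement = movement,
    hypnogram = hypnogram(j$hypnogram$labels, epoch_len_s = j$hypnogram$epoch_len_s)
  )
}

#' Pipeline config JSON round trip
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)  # keep names through JSON (objects, not arrays)
  } else {
    x
  }
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  named_num <- function(v) stats::setNames(as.numeric(v), names(v))
  pipeline_config(
    n_recordings = j$n_recordings, duration_min = j$duration_min,
    timescale = j$timescale, classifier = j$classifier, seed = j$seed,
    sim = do.call(sim_config, lapply(j$sim, function(v) {
      if (!is.null(names(v))) named_num(v) else as.numeric(v)
    })),
    fusion = do.call(fusion_config, j$fusion),
    out_dir = j$out_dir
  )
}

#' Write a pipeline report
#'
#' Per-recording and pooled metrics as CSV plus a JSON report carrying the
#' config hash and seed.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$per_recording, file.path(dir, "per_recording.csv"))
  readr::write_csv(report$pooled, file.path(dir, "pooled.csv"))
  jsonlite::write_json(
    list(
      schema_version = 1,
      config_hash = report$config_hash,
      seed = report$config$seed,
      classifier = report$config$classifier,
      timescale = report$config$timescale,
      per_recording = report$per_recording,
      pooled = report$pooled
    ),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Corpus manifest I/O
#'
#' A manifest lists, per recording, the paths of its feature CSV and
#' reference hypnogram CSV, so a staging run can be driven from disk.
#'
#' @param corpus Named list with `features`/`reference` elements (see
#'   [loocv_stage()]).
#' @param dir Directory to write per-recording CSVs and `manifest.json` to.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(names(corpus))) names(corpus) <- sprintf("rec%02d", seq_along(corpus))
  entries <- lapply(names(corpus), function(id) {
    fpath <- file.path(dir, paste0(id, "_features.csv"))
    hpath <- file.path(dir, paste0(id, "_reference.csv"))
    write_features_csv(corpus[[id]]$features, fpath)
    write_hypnogram_csv(corpus[[id]]$reference, hpath)
    list(id = id, features = basename(fpath), reference = basename(hpath))
  })
  jsonlite::write_json(entries, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_corpus
#' @param manifest Path to a `manifest.json`.
#' @export
read_corpus <- function(manifest) {
  dir <- dirname(manifest)
  entries <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  out <- lapply(entries, function(e) {
    list(
      features = read_features_csv(file.path(dir, e$features)),
      reference = read_hypnogram_csv(file.path(dir, e$reference))
    )
  })
  names(out) <- vapply(entries, function(e) e$id, character(1))
  out
}
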