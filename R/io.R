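#' Write traces to JSONL or long CSV
#'
#' JSONL is the canonical container (one record per measurement with the
#' ragged sample array inline); the long CSV (`subject_id, session_id,
#' hand, finger, label, rate_hz, t_s, force_gf`) is provided for
#' interoperability with spreadsheet tools.
#'
#' @param traces A `tf_traces` tibble.
#' @param path Output file; format chosen by extension (`.jsonl` or
#'   `.csv`).
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  validate_traces(traces)
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(traces))) {
      rec <- list(
        subject_id = traces$subject_id[i], session_id = traces$session_id[i],
        hand = traces$hand[i], finger = traces$finger[i],
        label = traces$label[i], rate_hz = traces$rate_hz[i],
        samples = traces$force[[i]]
      )
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  } else if (grepl("\\.csv$", path)) {
    long <- traces |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      tidyr::unnest_longer("force", values_to = "force_gf") |>
      dplyr::group_by(.data$.row) |>
      dplyr::mutate(t_s = (dplyr::row_number() - 1) / .data$rate_hz) |>
      dplyr::ungroup() |>
      dplyr::select("subject_id", "session_id", "hand", "finger", "label",
                    "rate_hz", "t_s", "force_gf")
    readr::write_csv(long, path)
  } else {
    tf_abort("unsupported trace format; use .jsonl or .csv", "tf_error_format")
  }
  invisible(path)
}

#' Read traces from JSONL or long CSV
#'
#' Validates every record (sampling rate, sample count, finite values);
#' malformed JSONL rows are reported with their line number, and a CSV
#' missing a required column is rejected naming the column. An empty file
#' yields an empty trace table with a warning.
#'
#' @param path A `.jsonl` or `.csv` file written by [write_traces()].
#' @return A `tf_traces` tibble.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) {
    tf_abort(paste0("file not found: ", path), "tf_error_format")
  }
  if (grepl("\\.jsonl$", path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      warning("empty trace file: ", path)
      return(empty_traces())
    }
    rows <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) NULL)
      need <- c("subject_id", "session_id", "hand", "finger", "rate_hz",
                "samples")
      if (is.null(rec) || !all(need %in% names(rec))) {
        tf_abort(sprintf("malformed JSONL record at line %d of %s", i, path),
                 "tf_error_format")
      }
      new_traces(rec$subject_id, rec$session_id, rec$hand, rec$finger,
                 rec$rate_hz, force = list(as.numeric(rec$samples)),
                 label = if (is.null(rec$label)) NA_integer_ else rec$label)
    })
    validate_traces(dplyr::bind_rows(rows))
  } else if (grepl("\\.csv$", path)) {
    long <- readr::read_csv(path, show_col_types = FALSE)
    if (!nrow(long)) {
      warning("empty trace file: ", path)
      return(empty_traces())
    }
    need <- c("subject_id", "session_id", "hand", "finger", "rate_hz",
              "t_s", "force_gf")
    missing_cols <- setdiff(need, names(long))
    if (length(missing_cols)) {
      tf_abort(paste0("CSV is missing required column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "tf_error_format")
    }
    if (!"label" %in% names(long)) long$label <- NA_integer_
    nested <- long |>
      dplyr::group_by(.data$subject_id, .data$session_id, .data$hand,
                      .data$finger, .data$rate_hz, .data$label) |>
      dplyr::arrange(.data$t_s, .by_group = TRUE) |>
      dplyr::summarise(
        force = list(.data$force_gf),
        .monotone = all(diff(.data$t_s) > 0),
        .groups = "drop"
      )
    if (!all(nested$.monotone)) {
      tf_abort("non-monotone time within a measurement", "tf_error_format")
    }
    nested$.monotone <- NULL
    validate_traces(nested)
  } else {
    tf_abort("unsupported trace format; use .jsonl or .csv", "tf_error_format")
  }
}

empty_traces <- function() {
  validate_empty <- tibble(
    subject_id = character(), session_id = character(), hand = character(),
    finger = character(), rate_hz = numeric(), label = integer(),
    force = list()
  )
  class(validate_empty) <- unique(c("tf_traces", class(validate_empty)))
  validate_empty
}

#' Write an encoder pulse log as CSV
#'
#' @param encoder Encoder log from [simulate_rig()].
#' @param path Output CSV (`pulse_time_s` column).
#' @return `path`, invisibly.
#' @export
write_encoder <- function(encoder, path) {
  readr::write_csv(tibble(pulse_time_s = encoder$pulse_times_s), path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects the analysis constants in one serializable object: the
#' measurement protocol, the band-pass edges, the outlier percentile, the
#' validity-threshold sweep, the feature grid and the master seed.
#'
#' @param protocol A [protocol_config()].
#' @param band Band-pass edges, Hz.
#' @param outlier_percentile Percentile for [outlier_filter()].
#' @param vf_thresholds Validity thresholds for [repeatability()].
#' @param seed Integer master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(protocol = protocol_config(), band = c(3.5, 7.5),
                       outlier_percentile = 1.25,
                       vf_thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9),
                       seed = 1L) {
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < protocol$rate_hz / 2)) {
    tf_abort("band must satisfy 0 < lo < hi < rate_hz/2",
             "tf_error_invalid_parameter")
  }
  structure(
    list(protocol = protocol, band = band,
         outlier_percentile = outlier_percentile,
         vf_thresholds = vf_thresholds, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' Unknown keys in the file are rejected rather than silently ignored.
#'
#' @param path A YAML file.
#' @return For `read_run_config()`, a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("protocol", "band", "outlier_percentile", "vf_thresholds", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    tf_abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
             "tf_error_format")
  }
  prot <- if (is.null(raw$protocol)) protocol_config() else {
    known_p <- c("target_gf", "hold_s", "tolerance_frac", "finger_sequence",
                 "rate_hz")
    unknown_p <- setdiff(names(raw$protocol), known_p)
    if (length(unknown_p)) {
      tf_abort(paste0("unknown protocol key(s): ",
                      paste(unknown_p, collapse = ", ")),
               "tf_error_format")
    }
    do.call(protocol_config, raw$protocol)
  }
  run_config(
    protocol = prot,
    band = if (is.null(raw$band)) c(3.5, 7.5) else as.numeric(raw$band),
    outlier_percentile = raw$outlier_percentile %||% 1.25,
    vf_thresholds = raw$vf_thresholds %||% c(0.5, 0.6, 0.7, 0.8, 0.9),
    seed = raw$seed %||% 1L
  )
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(
    list(protocol = unclass(config$protocol), band = config$band,
         outlier_percentile = config$outlier_percentile,
         vf_thresholds = config$vf_thresholds, seed = config$seed),
    path
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Thumb exclusion, preprocessing (outlier repair, band-pass, hold-window
#' extraction), tremor assessment, feature extraction and the repeatability
#' sweep, in order. Any stage failure aborts naming the stage and the
#' offending measurement. Rerunning with the same configuration and inputs
#' reproduces the outputs exactly; when `out_dir` is given, the artifacts
#' are written as CSV together with a JSON manifest carrying the config
#' hash, seed and package version.
#'
#' @param config A [run_config()].
#' @param traces A `tf_traces` tibble, or a path readable by
#'   [read_traces()].
#' @param out_dir Optional output directory.
#' @return A list with `assessments`, `features` and `repeatability`.
#' @export
run_pipeline <- function(config, traces, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(traces)) traces <- read_traces(traces)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      tf_abort(paste0("pipeline stage '", name, "' failed: ",
                      conditionMessage(e)),
               "tf_error_pipeline")
    })
  }
  kept <- stage("exclude_thumbs", exclude_thumbs(traces))
  windows <- stage("preprocess",
                   preprocess(kept, config$protocol,
                              lo_hz = config$band[1], hi_hz = config$band[2],
                              percentile = config$outlier_percentile))
  assessments <- stage("assess",
                       assess(windows, threshold = config$vf_thresholds[1],
                              band = config$band))
  features <- stage("features", build_features(windows))
  rep_report <- stage("repeatability",
                      repeatability(assessments,
                                    thresholds = config$vf_thresholds))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(assessments, file.path(out_dir, "assessments.csv"))
    readr::write_csv(features, file.path(out_dir, "features.csv"))
    readr::write_csv(rep_report, file.path(out_dir, "repeatability.csv"))
    manifest <- list(
      config_hash = rlang::hash(unclass(config)),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("tremorforce")),
      n_measurements = nrow(assessments)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(assessments = assessments, features = features,
       repeatability = rep_report)
}
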