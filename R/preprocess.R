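#' Percentile outlier repair
#'
#' Samples strictly below the given percentile of the measurement's own
#' distribution — typically brief contact-loss artifacts where the finger
#' tapped rather than pressed the gauge — are replaced by linear
#' interpolation between the nearest non-outlier neighbours; outliers at the
#' ends of the trace take the nearest non-outlier value. At the default
#' percentile (1.25) at most `ceiling(0.0125 * N)` samples can change.
#'
#' @param traces A `tf_traces` tibble.
#' @param percentile Percentile cutoff in percent (default 1.25).
#' @return The trace table with repaired force samples.
#' @export
outlier_filter <- function(traces, percentile = 1.25) {
  validate_traces(traces)
  stopifnot_scalar_num(percentile, "percentile", 0, 100)
  traces$force <- lapply(traces$force, outlier_filter_vec,
                         percentile = percentile)
  traces
}

outlier_filter_vec <- function(x, percentile = 1.25) {
  if (length(x) < 3L) {
    tf_abort("outlier repair needs at least 3 samples", "tf_error_degenerate_input")
  }
  q <- stats::quantile(x, percentile / 100, type = 7, names = FALSE)
  bad <- x < q
  if (!any(bad)) return(x)
  good <- which(!bad)
  if (length(good) < 2L) {
    tf_abort("fewer than 2 non-outlier samples; cannot interpolate",
             "tf_error_degenerate_input")
  }
  # rule = 2: leading/trailing outliers take the nearest non-outlier value
  repl <- stats::approx(good, x[good], xout = which(bad), rule = 2)$y
  x[bad] <- repl
  x
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero phase), retaining the tremor analysis band. The default 3.5-7.5 Hz
#' band isolates Parkinsonian action tremor: voluntary force changes and
#' baseline drift sit below it, physiological tremor mostly above it.
#' Response contract: amplitude ratio at least 0.9 at band centre, at most
#' 0.1 at 1.5 Hz and below, and at 10 Hz and above (40 Hz sampling).
#'
#' @param traces A `tf_traces` tibble.
#' @param lo_hz,hi_hz Band edges in Hz; must satisfy
#'   `lo_hz < hi_hz < rate_hz / 2`.
#' @return The trace table with filtered force samples (same lengths).
#' @export
bandpass <- function(traces, lo_hz = 3.5, hi_hz = 7.5) {
  validate_traces(traces)
  traces$force <- purrr::map2(traces$force, traces$rate_hz,
                              bandpass_vec, lo_hz = lo_hz, hi_hz = hi_hz)
  traces
}

bandpass_vec <- function(x, rate_hz, lo_hz = 3.5, hi_hz = 7.5) {
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < rate_hz / 2)) {
    tf_abort("band edges must satisfy 0 < lo_hz < hi_hz < rate_hz/2",
             "tf_error_invalid_parameter")
  }
  flt <- signal::butter(2, c(lo_hz, hi_hz) / (rate_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(flt, x))
}

#' Locate the protocol hold window
#'
#' Finds the first contiguous run of at least `hold_s` seconds in which the
#' raw force stays within `tolerance_frac * target_gf` of the target, and
#' truncates it to exactly `round(hold_s * rate_hz)` samples. The returned
#' indices refer to the raw trace, so the identical span can be cut from the
#' band-passed trace. A trace with no qualifying run raises a
#' measurement-invalid condition — under the live protocol such a
#' measurement is repeated.
#'
#' @param traces A `tf_traces` tibble of raw (pre-band-pass) traces. The
#'   window is usually *cut* from a filtered copy via the `cut_from`
#'   argument.
#' @param protocol A [protocol_config()].
#' @param cut_from Optional `tf_traces` with identical row order and sample
#'   lengths (e.g. the band-passed version of `traces`) from which the
#'   window samples are taken; defaults to `traces` itself.
#' @return A tibble of class `tf_windows`: metadata columns plus
#'   `start_index`, `n_samples`, `rate_hz` and a `samples` list-column.
#' @export
find_hold_window <- function(traces, protocol = protocol_config(),
                             cut_from = NULL) {
  validate_traces(traces)
  stopifnot(inherits(protocol, "protocol_config"))
  if (is.null(cut_from)) cut_from <- traces
  if (nrow(cut_from) != nrow(traces)) {
    tf_abort("`cut_from` must have the same rows as `traces`", "tf_error_format")
  }
  out <- traces
  n_hold <- round(protocol$hold_s * protocol$rate_hz)
  starts <- integer(nrow(traces))
  for (i in seq_len(nrow(traces))) {
    starts[i] <- hold_window_start(traces$force[[i]], traces$rate_hz[i],
                                   protocol,
                                   id = paste(traces$subject_id[i],
                                              traces$session_id[i],
                                              traces$hand[i],
                                              traces$finger[i]))
  }
  out$start_index <- starts
  out$n_samples <- n_hold
  out$samples <- purrr::map2(cut_from$force, starts,
                             function(x, s) x[s:(s + n_hold - 1L)])
  out$force <- NULL
  class(out) <- setdiff(class(out), "tf_traces")
  class(out) <- unique(c("tf_windows", class(out)))
  out
}

hold_window_start <- function(x, rate_hz, protocol, id = "") {
  n_hold <- round(protocol$hold_s * rate_hz)
  tol <- protocol$tolerance_frac * protocol$target_gf
  inside <- abs(x - protocol$target_gf) <= tol
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= n_hold)
  if (!length(hit)) {
    tf_abort(sprintf("no %gs hold within +/-%g gf of target for measurement %s; measurement would be repeated",
                     protocol$hold_s, tol, id),
             "tf_error_measurement_invalid")
  }
  starts[hit[1]]
}

#' Run the standard preprocessing chain
#'
#' Outlier repair, then zero-phase band-pass, then hold-window extraction at
#' indices located on the outlier-repaired *raw* trace (so the window is
#' anchored where the subject actually held the target force, and its
#' samples are taken from the filtered stream).
#'
#' @inheritParams find_hold_window
#' @param lo_hz,hi_hz Analysis band, Hz.
#' @param percentile Outlier percentile, percent.
#' @return A `tf_windows` tibble.
#' @export
#' @examples
#' tr <- simulate_trace(sim_params(seed = 3))
#' preprocess(tr)
preprocess <- function(traces, protocol = protocol_config(),
                       lo_hz = 3.5, hi_hz = 7.5, percentile = 1.25) {
  raw <- outlier_filter(traces, percentile = percentile)
  filtered <- bandpass(raw, lo_hz = lo_hz, hi_hz = hi_hz)
  find_hold_window(raw, protocol, cut_from = filtered)
}
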