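#' The 41-point feature grid
#'
#' @return Frequencies 3.5, 3.6, ..., 7.5 Hz.
#' @export
feature_grid <- function() seq(3.5, 7.5, by = 0.1)

#' Resample an amplitude spectrum onto the 41-point feature grid
#'
#' Linear interpolation of the one-sided amplitude curve at 3.5, 3.6, ...,
#' 7.5 Hz (0.1 Hz spacing), producing the fixed-length descriptor used by
#' the classifiers.
#'
#' @param spectrum A `tf_spectrum` of kind `"amplitude"` covering
#'   3.5-7.5 Hz.
#' @return Numeric vector of length 41.
#' @export
extract_features <- function(spectrum) {
  grid <- feature_grid()
  if (spectrum$freq_hz[1] > grid[1] ||
      spectrum$freq_hz[nrow(spectrum)] < grid[length(grid)]) {
    tf_abort("spectrum does not cover the 3.5-7.5 Hz feature band",
             "tf_error_invalid_parameter")
  }
  stats::approx(spectrum$freq_hz, spectrum$value, xout = grid)$y
}

#' Build the feature matrix for a set of hold windows
#'
#' Computes each window's one-sided amplitude spectrum and resamples it onto
#' the 41-point grid, returning one row per measurement with feature columns
#' `f3.50` ... `f7.50` plus the metadata and label.
#'
#' @param windows A `tf_windows` tibble from [preprocess()].
#' @return A tibble with 41 feature columns and a `label` column.
#' @export
#' @examples
#' prm <- default_cohort_params()
#' design <- cohort_design(tibble::tibble(
#'   subject_id = c("H1", "P1"), group = c("healthy", "pd"),
#'   ftmtrs_tremor = c(0L, 3L), n_sessions = 1L))
#' feats <- simulate_cohort(design, prm$healthy, prm$pd, seed = 1) |>
#'   exclude_thumbs() |>
#'   preprocess() |>
#'   build_features()
#' dim(feats)
build_features <- function(windows) {
  if (!inherits(windows, "tf_windows")) {
    tf_abort("`windows` must be a tf_windows table", "tf_error_format")
  }
  grid <- feature_grid()
  feats <- purrr::map2(windows$samples, windows$rate_hz, function(x, rate) {
    extract_features(amplitude_spectrum(x, rate))
  })
  mat <- do.call(rbind, feats)
  colnames(mat) <- sprintf("f%.2f", grid)
  meta <- windows[, intersect(c("subject_id", "session_id", "hand", "finger",
                                "label"), names(windows))]
  dplyr::bind_cols(as_tibble(meta), as_tibble(mat))
}

#' Column-wise standardization
#'
#' Centres every feature column to mean 0 and scales it to unit sample
#' standard deviation; constant columns map to all zeros (guarded division).
#' Applied to the inputs of the SVM and KNN classifiers.
#'
#' @param x A numeric matrix or data frame of feature columns (>= 2 rows).
#' @return A matrix of the same shape.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    tf_abort("standardization needs at least 2 rows", "tf_error_invalid_parameter")
  }
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[s == 0] <- Inf  # constant columns -> all zeros
  sweep(sweep(x, 2, mu, "-"), 2, s, "/")
}
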