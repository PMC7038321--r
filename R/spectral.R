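new_spectrum <- function(freq_hz, value, kind, n_samples, rate_hz) {
  out <- tibble(freq_hz = freq_hz, value = value)
  attr(out, "kind") <- kind
  attr(out, "n_samples") <- n_samples
  attr(out, "rate_hz") <- rate_hz
  class(out) <- unique(c("tf_spectrum", class(out)))
  out
}

one_sided_fft <- function(x, rate_hz) {
  if (length(x) < 8L) {
    tf_abort("spectrum estimation needs at least 8 samples", "tf_error_invalid_parameter")
  }
  n <- length(x)
  X <- stats::fft(x - mean(x))
  k <- 0:(n %/% 2)
  list(X = X[k + 1L], freq = k * rate_hz / n, n = n)
}

# scale factor 2 for interior bins; DC always excluded, Nyquist excluded
# when n is even (its bin has no mirror image)
one_sided_doubling <- function(n_bins, n) {
  s <- rep(2, n_bins)
  s[1] <- 1
  if (n %% 2 == 0) s[n_bins] <- 1
  s
}

#' One-sided amplitude spectrum
#'
#' Mean-subtracted, rectangular-windowed discrete Fourier transform of a
#' hold window, reported as one-sided amplitudes `2|X_k|/N` (the DC and, for
#' even `N`, the Nyquist bin are not doubled). A pure sinusoid of amplitude
#' `A` at an exact bin frequency yields amplitude `A` in that bin.
#'
#' @param x Numeric vector of force samples (a hold window), or a
#'   `tf_windows` row's `samples[[i]]`.
#' @param rate_hz Sampling rate, Hz.
#' @return A tibble of class `tf_spectrum` with columns `freq_hz`, `value`;
#'   `floor(N/2) + 1` rows spaced `rate_hz / N` apart.
#' @export
#' @examples
#' t <- (0:119) / 40
#' sp <- amplitude_spectrum(20 * sin(2 * pi * 6 * t), 40)
#' sp$freq_hz[which.max(sp$value)]
amplitude_spectrum <- function(x, rate_hz = 40) {
  ft <- one_sided_fft(x, rate_hz)
  amp <- one_sided_doubling(length(ft$X), ft$n) * Mod(ft$X) / ft$n
  new_spectrum(ft$freq, amp, "amplitude", ft$n, rate_hz)
}

#' One-sided power spectral density (periodogram)
#'
#' Single-segment periodogram of a mean-subtracted, rectangular-windowed
#' hold window: per-bin power `|X_k|^2 / N^2`, doubled for interior bins so
#' that the one-sided sum satisfies Parseval's identity (sum of bins equals
#' the mean square of the demeaned signal).
#'
#' @inheritParams amplitude_spectrum
#' @return A `tf_spectrum` tibble with `kind = "psd"`.
#' @export
power_spectral_density <- function(x, rate_hz = 40) {
  ft <- one_sided_fft(x, rate_hz)
  p <- one_sided_doubling(length(ft$X), ft$n) * Mod(ft$X)^2 / ft$n^2
  new_spectrum(ft$freq, p, "psd", ft$n, rate_hz)
}

#' Dominant frequency within a band
#'
#' Frequency of the maximal spectral value restricted to the analysis band
#' (default 3.5-7.5 Hz, the validated tremor range); exact ties resolve to
#' the lower frequency.
#'
#' @param spectrum A `tf_spectrum` (usually a PSD).
#' @param band Length-2 numeric, inclusive band edges in Hz.
#' @return The dominant frequency in Hz.
#' @export
dominant_frequency <- function(spectrum, band = c(3.5, 7.5)) {
  idx <- which(spectrum$freq_hz >= band[1] & spectrum$freq_hz <= band[2])
  if (!length(idx)) {
    tf_abort("no spectral bins inside the requested band", "tf_error_invalid_parameter")
  }
  v <- spectrum$value[idx]
  spectrum$freq_hz[idx[which.max(v)]]  # which.max takes the first = lowest
}

# trapezoidal integral of the piecewise-linear PSD curve over [a, b],
# with linearly interpolated values at the interval edges
trapz_interval <- function(freq, value, a, b) {
  a <- max(a, freq[1])
  b <- min(b, freq[length(freq)])
  if (b <= a) return(0)
  inner <- freq > a & freq < b
  fs <- c(a, freq[inner], b)
  vs <- c(stats::approx(freq, value, xout = a)$y,
          value[inner],
          stats::approx(freq, value, xout = b)$y)
  pracma::trapz(fs, vs)
}

#' Peak power around the dominant frequency
#'
#' Integral of the PSD curve over `f_d +/- halfwidth_hz` (default
#' +/- 0.3 Hz), by trapezoidal quadrature with linear interpolation at the
#' interval edges. This is the area under the spectral peak that the
#' validity statistic compares against the whole curve.
#'
#' @param psd A `tf_spectrum` of kind `"psd"`.
#' @param f_d Dominant frequency, Hz.
#' @param halfwidth_hz Integration half-width, Hz (default 0.3).
#' @return The peak power (same units as PSD x Hz).
#' @export
peak_power <- function(psd, f_d, halfwidth_hz = 0.3) {
  lo <- f_d - halfwidth_hz
  hi <- f_d + halfwidth_hz
  if (hi < psd$freq_hz[1] || lo > psd$freq_hz[nrow(psd)]) {
    tf_abort("peak interval does not intersect the spectrum support",
             "tf_error_invalid_parameter")
  }
  trapz_interval(psd$freq_hz, psd$value, lo, hi)
}

#' Peak power proportion
#'
#' The ratio of the peak power to the total power — the trapezoidal integral
#' of the full one-sided PSD — giving a scale-free statistic in `[0, 1]`
#' that measures how concentrated the signal's power is around the dominant
#' frequency. A strong tremor yields a value near 1; broadband noise spreads
#' power and yields a small value. Used as the measurement-validity
#' criterion: a measurement counts only if the proportion exceeds a set
#' threshold.
#'
#' @param psd A `tf_spectrum` of kind `"psd"`.
#' @param p_peak The peak power from [peak_power()].
#' @return A fraction in `[0, 1]`.
#' @export
peak_power_proportion <- function(psd, p_peak) {
  total <- pracma::trapz(psd$freq_hz, psd$value)
  if (total <= 0) {
    tf_abort("total spectral power is zero; assessment undefined",
             "tf_error_undefined_assessment")
  }
  min(p_peak / total, 1)
}

#' Assess tremor in preprocessed hold windows
#'
#' For each window (already outlier-repaired and band-passed) this computes
#' the periodogram, the dominant frequency in the analysis band, the peak
#' power over `f_d +/- 0.3 Hz`, and the peak power proportion; the
#' measurement is valid when the proportion exceeds `threshold`.
#'
#' @param windows A `tf_windows` tibble from [preprocess()] /
#'   [find_hold_window()].
#' @param threshold Validity cutoff on the peak power proportion.
#' @param band Analysis band in Hz for the dominant frequency.
#' @param halfwidth_hz Peak integration half-width, Hz.
#' @return A tibble of class `tf_assessments`: the window metadata plus
#'   `f_d`, `f1`, `f2`, `p_peak`, `v_f`, `threshold` and `valid`.
#' @export
#' @examples
#' simulate_trace(sim_params(tremor_amp_gf = 30, seed = 2)) |>
#'   preprocess() |>
#'   assess(threshold = 0.5)
assess <- function(windows, threshold = 0.5, band = c(3.5, 7.5),
                   halfwidth_hz = 0.3) {
  if (!inherits(windows, "tf_windows")) {
    tf_abort("`windows` must be a tf_windows table from preprocess()",
             "tf_error_format")
  }
  res <- purrr::map2(windows$samples, windows$rate_hz, function(x, rate) {
    psd <- power_spectral_density(x, rate)
    f_d <- dominant_frequency(psd, band)
    pp <- peak_power(psd, f_d, halfwidth_hz)
    vf <- peak_power_proportion(psd, pp)
    c(f_d = f_d, p_peak = pp, v_f = vf)
  })
  res <- unname(do.call(rbind, res))
  colnames(res) <- c("f_d", "p_peak", "v_f")
  out <- windows
  out$samples <- NULL
  out$f_d <- as.numeric(res[, "f_d"])
  out$f1 <- out$f_d - halfwidth_hz
  out$f2 <- out$f_d + halfwidth_hz
  out$p_peak <- as.numeric(res[, "p_peak"])
  out$v_f <- as.numeric(res[, "v_f"])
  out$threshold <- threshold
  out$valid <- out$v_f > threshold
  class(out) <- setdiff(class(out), "tf_windows")
  class(out) <- unique(c("tf_assessments", class(out)))
  out
}
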