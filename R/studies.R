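#' Encoder-vs-gauge frequency agreement (two-sample z-test)
#'
#' Repeatedly simulates the validation rig, estimating the rotation rate per
#' trial from the optical encoder pulse log and, independently, from the
#' frequency at the maximal value of the gauge signal's one-sided power
#' spectrum (full 0-20 Hz band). The two arms are compared with an unpooled
#' two-sample z statistic
#' `z = (mu_r - mu_oe) / sqrt(s_oe^2/n + s_r^2/n)` against the null
#' hypothesis that the mean frequencies agree.
#'
#' Each trial draws its own motor speed around the nominal rate
#' (`speed_jitter_frac`, default 1%), modelling DC-motor speed tolerance;
#' without trial-to-trial variation both arms would be deterministic and the
#' test degenerate.
#'
#' @param rig A [rig_params()] giving the nominal rig configuration;
#'   `duration_s` is replaced by `trial_s` per trial.
#' @param n_trials Number of trials per arm (default 40).
#' @param trial_s Trial duration in seconds (default 3).
#' @param seed Integer seed.
#' @param alpha Two-sided significance level (default 0.05).
#' @param speed_jitter_frac Per-trial fractional standard deviation of the
#'   motor speed.
#' @param gauge_offset_hz Deterministic offset added to the gauge-arm
#'   estimates (0 in normal use; nonzero to exercise the test's power).
#' @return A list of class `ztest_result` with per-arm means/SDs, `z`,
#'   `alpha` and `reject`.
#' @export
#' @examples
#' rig_validation(rig_params(rev_per_s = 7), n_trials = 10, seed = 1)
rig_validation <- function(rig, n_trials = 40L, trial_s = 3, seed = 1L,
                           alpha = 0.05, speed_jitter_frac = 0.01,
                           gauge_offset_hz = 0) {
  stopifnot(inherits(rig, "rig_params"))
  if (n_trials < 2L) {
    tf_abort("need at least 2 trials per arm", "tf_error_invalid_parameter")
  }
  speeds <- withr::with_seed(derive_seed(seed, 0L), {
    rig$rev_per_s * (1 + stats::rnorm(n_trials, 0, speed_jitter_frac))
  })
  f_oe <- numeric(n_trials)
  f_r <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    p <- rig
    p$rev_per_s <- speeds[i]
    p$duration_s <- trial_s
    p$seed <- derive_seed(seed, i)
    sim <- simulate_rig(p)
    f_oe[i] <- encoder_frequency(sim$encoder)
    psd <- power_spectral_density(sim$trace$force[[1]], sim$trace$rate_hz[1])
    f_r[i] <- dominant_frequency(psd, band = c(0, 20)) + gauge_offset_hz
  }
  zt <- two_sample_z(f_oe, f_r)
  crit <- stats::qnorm(1 - alpha / 2)
  structure(
    list(mu_oe = zt$mu_x, s_oe = zt$s_x, mu_r = zt$mu_y, s_r = zt$s_y,
         n = n_trials, z = zt$z, alpha = alpha, reject = abs(zt$z) > crit,
         rev_per_s = rig$rev_per_s),
    class = "ztest_result"
  )
}

# unpooled two-sample z statistic with per-arm sample SDs;
# z = (mean(y) - mean(x)) / sqrt(s_x^2/n_x + s_y^2/n_y)
two_sample_z <- function(x, y) {
  mu_x <- mean(x); s_x <- sd_sample(x)
  mu_y <- mean(y); s_y <- sd_sample(y)
  se <- sqrt(s_x^2 / length(x) + s_y^2 / length(y))
  z <- if (se > 0) {
    (mu_y - mu_x) / se
  } else if (mu_y == mu_x) 0 else Inf * sign(mu_y - mu_x)
  list(mu_x = mu_x, s_x = s_x, mu_y = mu_y, s_y = s_y, z = z)
}

#' @export
print.ztest_result <- function(x, ...) {
  cat(sprintf("<ztest_result> nominal %.2f rev/s, n = %d per arm\n",
              x$rev_per_s, x$n))
  cat(sprintf("  encoder %.4f Hz (sd %.4f) | gauge %.4f Hz (sd %.4f)\n",
              x$mu_oe, x$s_oe, x$mu_r, x$s_r))
  cat(sprintf("  z = %.3f, alpha = %g -> %s H0 (equal means)\n",
              x$z, x$alpha, if (x$reject) "reject" else "do not reject"))
  invisible(x)
}

#' @rdname tidy.metrics_report
#' @export
tidy.ztest_result <- function(x, ...) {
  tibble(
    arm = c("encoder", "gauge"),
    mean_hz = c(x$mu_oe, x$mu_r),
    sd_hz = c(x$s_oe, x$s_r),
    n = x$n
  )
}

#' @rdname glance.metrics_report
#' @export
glance.ztest_result <- function(x, ...) {
  tibble(mu_oe = x$mu_oe, s_oe = x$s_oe, mu_r = x$mu_r, s_r = x$s_r,
         n = x$n, z = x$z, alpha = x$alpha, reject = x$reject)
}

#' Repeated-measurement threshold sweep
#'
#' For each hand and each validity threshold, counts how many assessments
#' pass (`v_f > threshold`) and summarises the dominant frequency over the
#' passing measurements. Frequency statistics are withheld (`NA`) when
#' fewer than 2 measurements pass, too small a sample for a spread
#' estimate. Validity counts are monotone non-increasing in the threshold.
#'
#' @param assessments A `tf_assessments` tibble (must carry `hand`, `v_f`,
#'   `f_d`).
#' @param thresholds Numeric vector of validity cutoffs (default 0.5-0.9).
#' @return A tibble of class `repeatability_report` with columns `hand`,
#'   `threshold`, `valid_rel`, `valid_abs`, `total`, `mean_f`, `std_f`.
#' @export
repeatability <- function(assessments,
                          thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9)) {
  if (!nrow(assessments)) {
    tf_abort("no assessments supplied", "tf_error_invalid_parameter")
  }
  if (!all(c("hand", "v_f", "f_d") %in% names(assessments))) {
    tf_abort("assessments must carry hand, v_f and f_d", "tf_error_format")
  }
  out <- tidyr::expand_grid(hand = unique(assessments$hand),
                            threshold = thresholds) |>
    dplyr::rowwise() |>
    dplyr::mutate({
      a <- assessments[assessments$hand == .data$hand, ]
      ok <- a$v_f > .data$threshold
      nvalid <- sum(ok)
      tibble(
        valid_rel = nvalid / nrow(a),
        valid_abs = nvalid,
        total = nrow(a),
        mean_f = if (nvalid >= 2) mean(a$f_d[ok]) else NA_real_,
        std_f = if (nvalid >= 2) sd_sample(a$f_d[ok]) else NA_real_
      )
    }) |>
    dplyr::ungroup()
  class(out) <- unique(c("repeatability_report", class(out)))
  out
}
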