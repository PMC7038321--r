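#' Signal-generation parameters for a simulated tremor measurement
#'
#' Collects the parameters of the additive signal model used by
#' [simulate_trace()]: a voluntary ramp-and-hold force at the protocol target,
#' plus an amplitude-modulated tremor sinusoid, broadband measurement noise,
#' slow baseline drift, and (optionally) transient contact-loss intervals in
#' which the finger taps rather than presses the gauge.
#'
#' Parkinsonian action tremor is approximately sinusoidal with a stable
#' frequency but fluctuating amplitude, which is what the slow amplitude
#' modulation emulates. Physiological tremor of healthy subjects sits mostly
#' above 7 Hz, so healthy defaults place the sinusoid at 10 Hz where the
#' analysis band-pass (3.5-7.5 Hz) suppresses it.
#'
#' @param tremor_freq_hz Tremor frequency in Hz; Parkinsonian-like signals
#'   fall in 3.5-7.5 Hz, physiological tremor above 7 Hz.
#' @param tremor_amp_gf Tremor amplitude in gram-force (>= 0).
#' @param amp_mod_depth Fractional depth in `[0, 1]` of the slow sinusoidal
#'   modulation of tremor amplitude.
#' @param amp_mod_freq_hz Modulation frequency in Hz; should be well below
#'   `tremor_freq_hz`.
#' @param noise_sd_gf Standard deviation of additive white Gaussian
#'   measurement noise, gram-force.
#' @param drift_gf_per_s Linear baseline drift rate, gram-force per second.
#' @param tap_dropout_prob Per-second probability of a contact-loss interval
#'   during which the recorded force is clamped to 0 gf.
#' @param ramp_s Duration in seconds of the smooth ramp to the target force.
#' @param seed Integer seed; fully determines the generated samples.
#'
#' @return A list of class `sim_params`.
#' @seealso [simulate_trace()], [simulate_cohort()]
#' @export
#' @examples
#' sim_params(tremor_freq_hz = 6, tremor_amp_gf = 20, seed = 1)
sim_params <- function(tremor_freq_hz = 6,
                       tremor_amp_gf = 20,
                       amp_mod_depth = 0.1,
                       amp_mod_freq_hz = 0.5,
                       noise_sd_gf = 2,
                       drift_gf_per_s = 0.5,
                       tap_dropout_prob = 0,
                       ramp_s = 1,
                       seed = 1L) {
  stopifnot_scalar_num(tremor_freq_hz, "tremor_freq_hz", 0, strict_lower = TRUE)
  stopifnot_scalar_num(tremor_amp_gf, "tremor_amp_gf", 0)
  stopifnot_scalar_num(amp_mod_depth, "amp_mod_depth", 0, 1)
  stopifnot_scalar_num(amp_mod_freq_hz, "amp_mod_freq_hz", 0)
  stopifnot_scalar_num(noise_sd_gf, "noise_sd_gf", 0)
  stopifnot_scalar_num(drift_gf_per_s, "drift_gf_per_s")
  stopifnot_scalar_num(tap_dropout_prob, "tap_dropout_prob", 0, 1)
  stopifnot_scalar_num(ramp_s, "ramp_s", 0, strict_lower = TRUE)
  structure(
    list(
      tremor_freq_hz = tremor_freq_hz, tremor_amp_gf = tremor_amp_gf,
      amp_mod_depth = amp_mod_depth, amp_mod_freq_hz = amp_mod_freq_hz,
      noise_sd_gf = noise_sd_gf, drift_gf_per_s = drift_gf_per_s,
      tap_dropout_prob = tap_dropout_prob, ramp_s = ramp_s,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' Measurement-protocol configuration
#'
#' The protocol asks the subject to press one finger at a time to a target
#' force shown on screen and hold it there. The hold window is the segment
#' analysed for tremor; a measurement with no qualifying hold is repeated.
#'
#' @param target_gf Target force in gram-force (default 300).
#' @param hold_s Hold duration in seconds (default 3; 5 in the repeatability
#'   study).
#' @param tolerance_frac Half-width of the acceptance band around the target,
#'   as a fraction of `target_gf` (default 0.2).
#' @param finger_sequence Character vector of fingers measured per session,
#'   in order; defaults to both hands, little-to-little.
#' @param rate_hz Sampling rate in Hz (default 40).
#'
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(target_gf = 300,
                            hold_s = 3,
                            tolerance_frac = 0.2,
                            finger_sequence = NULL,
                            rate_hz = 40) {
  stopifnot_scalar_num(target_gf, "target_gf", 0, strict_lower = TRUE)
  stopifnot_scalar_num(hold_s, "hold_s", 0, strict_lower = TRUE)
  stopifnot_scalar_num(tolerance_frac, "tolerance_frac", 0, 1,
                       strict_lower = TRUE)
  if (tolerance_frac >= 1) {
    tf_abort("`tolerance_frac` must be in (0, 1)", "tf_error_invalid_parameter")
  }
  stopifnot_scalar_num(rate_hz, "rate_hz", 0, strict_lower = TRUE)
  if (is.null(finger_sequence)) {
    finger_sequence <- c(rev(fingers_one_hand), fingers_one_hand)
  }
  structure(
    list(target_gf = target_gf, hold_s = hold_s,
         tolerance_frac = tolerance_frac,
         finger_sequence = finger_sequence, rate_hz = rate_hz),
    class = "protocol_config"
  )
}

#' Cohort design for a simulated study
#'
#' @param subjects A data frame with columns `subject_id` (character),
#'   `group` (`"healthy"` or `"pd"`), `ftmtrs_tremor` (integer 0-4, the
#'   Fahn-Tolosa-Marin tremor rating; 0 for healthy subjects) and
#'   `n_sessions` (integer >= 1).
#' @param fingers_per_session Measurements per session (default 10, five
#'   fingers on each hand).
#'
#' @return A list of class `cohort_design`.
#' @seealso [default_cohort_design()], [simulate_cohort()]
#' @export
cohort_design <- function(subjects, fingers_per_session = 10L) {
  subjects <- as_tibble(subjects)
  need <- c("subject_id", "group", "ftmtrs_tremor", "n_sessions")
  missing_cols <- setdiff(need, names(subjects))
  if (length(missing_cols)) {
    tf_abort(paste0("design is missing column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "tf_error_invalid_parameter")
  }
  if (!all(subjects$group %in% c("healthy", "pd"))) {
    tf_abort("`group` must be 'healthy' or 'pd'", "tf_error_invalid_parameter")
  }
  if (!all(subjects$ftmtrs_tremor %in% 0:4)) {
    tf_abort("`ftmtrs_tremor` must be an integer in 0..4",
             "tf_error_invalid_parameter")
  }
  if (!all(subjects$n_sessions >= 1)) {
    tf_abort("`n_sessions` must be >= 1", "tf_error_invalid_parameter")
  }
  structure(
    list(subjects = subjects,
         fingers_per_session = as.integer(fingers_per_session)),
    class = "cohort_design"
  )
}

#' The shipped default study design
#'
#' 36 healthy subjects with one session each, plus 7 subjects with
#' Parkinson's disease carrying clinician tremor ratings 1-4 and 13 sessions
#' in total: 49 sessions of 10 finger measurements each, i.e. 490
#' measurements before thumb exclusion.
#'
#' @return A `cohort_design`.
#' @export
default_cohort_design <- function() {
  healthy <- tibble(
    subject_id = sprintf("H%02d", 1:36),
    group = "healthy",
    ftmtrs_tremor = 0L,
    n_sessions = 1L
  )
  pd <- tibble(
    subject_id = sprintf("P%02d", 1:7),
    group = "pd",
    ftmtrs_tremor = c(1L, 2L, 3L, 3L, 3L, 3L, 4L),
    n_sessions = c(1L, 1L, 1L, 1L, 7L, 1L, 1L)
  )
  cohort_design(dplyr::bind_rows(healthy, pd))
}

#' Default per-rating tremor parameters for a simulated cohort
#'
#' Clinician tremor ratings 0-4 map to tremor amplitudes 0, 5, 10, 20 and
#' 40 gf; healthy subjects carry a small 10 Hz physiological tremor that the
#' analysis band-pass removes.
#'
#' @param seed Base seed recorded in each parameter set.
#' @return A list with elements `healthy` (a `sim_params`) and `pd` (a list
#'   mapping rating `"0"`..`"4"` to `sim_params`).
#' @export
default_cohort_params <- function(seed = 1L) {
  amp_by_rating <- c(`0` = 0, `1` = 5, `2` = 10, `3` = 20, `4` = 40)
  pd <- lapply(amp_by_rating, function(a) {
    sim_params(tremor_freq_hz = 6, tremor_amp_gf = a, amp_mod_depth = 0.1,
               amp_mod_freq_hz = 0.5, noise_sd_gf = 2, drift_gf_per_s = 0.5,
               seed = seed)
  })
  list(
    healthy = sim_params(tremor_freq_hz = 10, tremor_amp_gf = 1.5,
                         amp_mod_depth = 0.1, amp_mod_freq_hz = 0.5,
                         noise_sd_gf = 2, drift_gf_per_s = 0.5, seed = seed),
    pd = pd
  )
}

#' Parameters for the motor-driven validation rig
#'
#' The rig rotates an eccentrically mounted elastic band with a DC motor so
#' that a periodically varying force is exerted on a strain gauge, while an
#' optical encoder logs rotation pulses. The elastic load can brake the motor
#' while stretching and release it while contracting, which modulates the
#' angular velocity within each revolution (`velocity_fluct_beta`) and
#' distorts the gauge signal away from a pure sinusoid.
#'
#' @param rev_per_s Motor rotation rate, revolutions per second (1-8).
#' @param force_mean_gf Mean force on the gauge, gram-force.
#' @param force_amp_gf Force oscillation amplitude (eccentricity times the
#'   elastic constant), gram-force.
#' @param velocity_fluct_beta Fractional within-revolution angular-velocity
#'   modulation in `[0, 1)`.
#' @param encoder_counts_per_rev Encoder pulses per revolution (>= 1).
#' @param duration_s Recording length in seconds; `duration_s * 40` must be
#'   an integer number of samples.
#' @param noise_sd_gf Gauge noise standard deviation, gram-force.
#' @param seed Integer seed.
#'
#' @return A list of class `rig_params`.
#' @seealso [simulate_rig()], [rig_validation()]
#' @export
rig_params <- function(rev_per_s = 7,
                       force_mean_gf = 300,
                       force_amp_gf = 50,
                       velocity_fluct_beta = 0,
                       encoder_counts_per_rev = 100L,
                       duration_s = 3,
                       noise_sd_gf = 2,
                       seed = 1L) {
  stopifnot_scalar_num(rev_per_s, "rev_per_s", 0, strict_lower = TRUE)
  if (rev_per_s >= 20) {
    tf_abort("`rev_per_s` must be below the 20 Hz Nyquist limit of the 40 Hz gauge",
             "tf_error_invalid_parameter")
  }
  stopifnot_scalar_num(force_amp_gf, "force_amp_gf", 0)
  stopifnot_scalar_num(velocity_fluct_beta, "velocity_fluct_beta", 0, 1)
  if (velocity_fluct_beta >= 1) {
    tf_abort("`velocity_fluct_beta` must be in [0, 1)",
             "tf_error_invalid_parameter")
  }
  stopifnot_scalar_num(duration_s, "duration_s", 0, strict_lower = TRUE)
  n <- duration_s * 40
  if (abs(n - round(n)) > 1e-9) {
    tf_abort("`duration_s` must give an integer sample count at 40 Hz",
             "tf_error_invalid_parameter")
  }
  stopifnot_scalar_num(noise_sd_gf, "noise_sd_gf", 0)
  if (encoder_counts_per_rev < 1) {
    tf_abort("`encoder_counts_per_rev` must be >= 1",
             "tf_error_invalid_parameter")
  }
  structure(
    list(rev_per_s = rev_per_s, force_mean_gf = force_mean_gf,
         force_amp_gf = force_amp_gf,
         velocity_fluct_beta = velocity_fluct_beta,
         encoder_counts_per_rev = as.integer(encoder_counts_per_rev),
         duration_s = duration_s, noise_sd_gf = noise_sd_gf,
         seed = as.integer(seed)),
    class = "rig_params"
  )
}
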