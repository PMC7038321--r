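#' Simulate the motor/pulley validation rig
#'
#' Models a DC motor rotating an eccentrically mounted elastic band against a
#' strain gauge, with an optical encoder logging rotation pulses. The gauge
#' reads `force_mean + force_amp * sin(theta(t)) + noise` at 40 Hz, where the
#' rotation phase follows
#' `dtheta/dt = 2*pi*rev_per_s*(1 + beta*sin(theta))`: with `beta = 0` the
#' rotation is uniform and the force a pure sinusoid; with `beta > 0` the
#' elastic load brakes and releases the motor within each revolution, which
#' injects harmonics into the gauge spectrum. Encoder pulses are emitted at
#' equal phase increments (`2*pi / counts_per_rev`).
#'
#' @param params A [rig_params()] object.
#' @return A list with elements `trace` (a one-row `tf_traces`) and
#'   `encoder` (a list with `pulse_times_s` and `counts_per_rev`).
#' @seealso [encoder_frequency()], [rig_validation()]
#' @export
#' @examples
#' rig <- simulate_rig(rig_params(rev_per_s = 3, velocity_fluct_beta = 0))
#' encoder_frequency(rig$encoder)
simulate_rig <- function(params) {
  stopifnot(inherits(params, "rig_params"))
  rate <- 40
  n <- round(params$duration_s * rate)
  t_samp <- (seq_len(n) - 1) / rate
  omega0 <- 2 * pi * params$rev_per_s
  beta <- params$velocity_fluct_beta

  if (beta == 0) {
    theta_samp <- omega0 * t_samp
    theta_end <- omega0 * params$duration_s
    dphase <- 2 * pi / params$encoder_counts_per_rev
    pulse_phases <- seq(0, theta_end, by = dphase)
    pulse_times <- pulse_phases / omega0
  } else {
    # integrate the phase ODE on a fine grid (RK4), then interpolate
    dt <- 1 / (rate * 25)
    n_fine <- ceiling(params$duration_s / dt) + 1L
    t_fine <- (seq_len(n_fine) - 1) * dt
    theta <- numeric(n_fine)
    f <- function(th) omega0 * (1 + beta * sin(th))
    for (i in seq_len(n_fine - 1L)) {
      k1 <- f(theta[i])
      k2 <- f(theta[i] + dt / 2 * k1)
      k3 <- f(theta[i] + dt / 2 * k2)
      k4 <- f(theta[i] + dt * k3)
      theta[i + 1L] <- theta[i] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    theta_samp <- stats::approx(t_fine, theta, xout = t_samp)$y
    dphase <- 2 * pi / params$encoder_counts_per_rev
    pulse_phases <- seq(0, theta[n_fine], by = dphase)
    # theta is strictly increasing (beta < 1), so invert by interpolation
    pulse_times <- stats::approx(theta, t_fine, xout = pulse_phases)$y
  }
  pulse_times <- pulse_times[pulse_times <= params$duration_s + 1e-12]

  force <- withr::with_seed(params$seed, {
    params$force_mean_gf + params$force_amp_gf * sin(theta_samp) +
      if (params$noise_sd_gf > 0) stats::rnorm(n, 0, params$noise_sd_gf) else 0
  })

  trace <- new_traces("rig", "rig-1", "left", "index", rate,
                      force = list(force))
  list(
    trace = trace,
    encoder = list(pulse_times_s = pulse_times,
                   counts_per_rev = params$encoder_counts_per_rev)
  )
}

#' Rotation rate from an encoder pulse log
#'
#' Estimates revolutions per second as
#' `(n_pulses - 1) / (counts_per_rev * elapsed)` where `elapsed` is the time
#' between the first and last pulse.
#'
#' @param log A list with `pulse_times_s` (ascending numeric) and
#'   `counts_per_rev` (integer >= 1), as returned by [simulate_rig()].
#' @return Rotation rate in revolutions per second (Hz for the gauge
#'   fundamental).
#' @export
encoder_frequency <- function(log) {
  pt <- log$pulse_times_s
  if (length(pt) < 2L) {
    tf_abort("need at least 2 encoder pulses to estimate a frequency",
             "tf_error_insufficient_data")
  }
  if (any(diff(pt) <= 0)) {
    tf_abort("pulse times must be strictly increasing", "tf_error_format")
  }
  (length(pt) - 1) / (log$counts_per_rev * (pt[length(pt)] - pt[1]))
}
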