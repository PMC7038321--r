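#' Construct a trace table
#'
#' A trace table holds one finger-force measurement per row: identifying
#' metadata, the sampling rate, an optional binary label (1 = Parkinson's
#' disease, 0 = healthy) and the force samples in gram-force as a
#' list-column. All package verbs take and return this shape, so calls
#' chain with the pipe.
#'
#' @param subject_id,session_id Character identifiers.
#' @param hand `"left"` or `"right"`.
#' @param finger One of `"thumb"`, `"index"`, `"middle"`, `"ring"`,
#'   `"little"`.
#' @param rate_hz Sampling rate, Hz.
#' @param force List of numeric vectors, gram-force.
#' @param label Optional 0/1 label (`NA` when unknown).
#'
#' @return A tibble of class `tf_traces`.
#' @export
new_traces <- function(subject_id, session_id, hand, finger, rate_hz,
                       force, label = NA_integer_) {
  out <- tibble(
    subject_id = as.character(subject_id),
    session_id = as.character(session_id),
    hand = as.character(hand),
    finger = as.character(finger),
    rate_hz = as.numeric(rate_hz),
    label = as.integer(label),
    force = force
  )
  validate_traces(out)
}

validate_traces <- function(traces) {
  need <- c("subject_id", "session_id", "hand", "finger", "rate_hz",
            "label", "force")
  missing_cols <- setdiff(need, names(traces))
  if (length(missing_cols)) {
    tf_abort(paste0("trace table is missing column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "tf_error_format")
  }
  if (any(traces$rate_hz <= 0)) {
    tf_abort("`rate_hz` must be positive", "tf_error_invalid_parameter")
  }
  bad <- vapply(traces$force,
                function(x) length(x) < 2L || !all(is.finite(x)),
                logical(1))
  if (any(bad)) {
    tf_abort(sprintf("trace row(s) %s have fewer than 2 samples or non-finite values",
                     paste(which(bad), collapse = ", ")),
             "tf_error_format")
  }
  class(traces) <- unique(c("tf_traces", class(traces)))
  traces
}

# Smooth ramp reaching exactly 1 at t = ramp_s (cubic smoothstep), then flat.
ramp_profile <- function(t, ramp_s) {
  u <- pmin(pmax(t / ramp_s, 0), 1)
  u * u * (3 - 2 * u)
}

#' Simulate one protocol-driven force measurement
#'
#' Generates a force trace following the measurement protocol: a smooth ramp
#' to the target force over `ramp_s`, a hold plateau at the target, plus an
#' amplitude-modulated tremor sinusoid, white measurement noise and linear
#' baseline drift. With `tap_dropout_prob > 0`, short contact-loss intervals
#' (0.1-0.3 s) clamp the recorded force to 0 gf, emulating a finger tapping
#' the gauge instead of pressing it. The trace covers the ramp, the protocol
#' hold time and a 1 s margin; the same seed always yields the same samples.
#'
#' @param params A [sim_params()] object.
#' @param protocol A [protocol_config()]; the sampling rate and target force
#'   come from here.
#' @param subject_id,session_id,hand,finger Metadata stored on the trace.
#' @param label Optional 0/1 class label.
#'
#' @return A one-row `tf_traces` tibble.
#' @export
#' @examples
#' tr <- simulate_trace(sim_params(tremor_freq_hz = 6, seed = 7))
#' length(tr$force[[1]])
simulate_trace <- function(params, protocol = protocol_config(),
                           subject_id = "S01", session_id = "S01-1",
                           hand = "left", finger = "index",
                           label = NA_integer_) {
  stopifnot(inherits(params, "sim_params"), inherits(protocol, "protocol_config"))
  rate <- protocol$rate_hz
  duration <- params$ramp_s + protocol$hold_s + 1
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate

  base <- protocol$target_gf * ramp_profile(t, params$ramp_s)

  x <- withr::with_seed(params$seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    mod_phase <- stats::runif(1, 0, 2 * pi)
    amp_t <- params$tremor_amp_gf *
      (1 + params$amp_mod_depth * sin(2 * pi * params$amp_mod_freq_hz * t + mod_phase))
    tremor <- amp_t * sin(2 * pi * params$tremor_freq_hz * t + phase)
    noise <- if (params$noise_sd_gf > 0) {
      stats::rnorm(n, 0, params$noise_sd_gf)
    } else {
      numeric(n)
    }
    drift <- params$drift_gf_per_s * t
    y <- base + tremor + noise + drift
    if (params$tap_dropout_prob > 0) {
      for (sec in 0:(floor(duration) - 1)) {
        if (stats::runif(1) < params$tap_dropout_prob) {
          start_s <- sec + stats::runif(1, 0, 0.7)
          len_s <- stats::runif(1, 0.1, 0.3)
          drop <- t >= start_s & t < start_s + len_s
          y[drop] <- 0
        }
      }
    }
    y
  })

  new_traces(subject_id, session_id, hand, finger, rate,
             force = list(x), label = label)
}

#' Simulate a whole study cohort
#'
#' One trace per (session, finger) of the design: healthy subjects use
#' `healthy_params`, subjects with Parkinson's disease the parameter set
#' matching their clinician tremor rating, so tremor amplitude is
#' non-decreasing in the rating under the defaults. Each subject's tremor
#' frequency is jittered (uniformly, `+/- freq_jitter_hz`) around the
#' nominal value so the cohort is not a single pure tone; all randomness,
#' including per-trace seeds, derives from `seed`.
#'
#' @param design A [cohort_design()].
#' @param healthy_params [sim_params()] for healthy subjects.
#' @param pd_params_by_ftmtrs Named list (`"0"`..`"4"`) of [sim_params()]
#'   keyed by tremor rating; an entry must exist for every rating present.
#' @param seed Integer master seed.
#' @param protocol A [protocol_config()].
#' @param freq_jitter_hz Half-width of the per-subject tremor-frequency
#'   jitter (default 0.5 Hz).
#'
#' @return A `tf_traces` tibble with one row per measurement and `label`
#'   0 (healthy) / 1 (PD).
#' @export
#' @examples
#' design <- cohort_design(tibble::tibble(
#'   subject_id = "P1", group = "pd", ftmtrs_tremor = 3L, n_sessions = 1L))
#' prm <- default_cohort_params()
#' nrow(simulate_cohort(design, prm$healthy, prm$pd, seed = 1))
simulate_cohort <- function(design,
                            healthy_params = default_cohort_params()$healthy,
                            pd_params_by_ftmtrs = default_cohort_params()$pd,
                            seed = 1L,
                            protocol = protocol_config(),
                            freq_jitter_hz = 0.5) {
  stopifnot(inherits(design, "cohort_design"))
  subjects <- design$subjects
  ratings_present <- unique(as.character(subjects$ftmtrs_tremor[subjects$group == "pd"]))
  missing_ratings <- setdiff(ratings_present, names(pd_params_by_ftmtrs))
  if (length(missing_ratings)) {
    tf_abort(paste0("no parameter entry for FTMTRS rating(s): ",
                    paste(missing_ratings, collapse = ", ")),
             "tf_error_configuration")
  }
  n_fingers <- design$fingers_per_session
  # finger/hand layout for one session: little-to-little across both hands
  layout <- tibble(
    hand = rep(c("left", "right"), each = 5),
    finger = c(rev(fingers_one_hand), fingers_one_hand)
  )[seq_len(n_fingers), ]

  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    base <- if (s$group == "healthy") {
      healthy_params
    } else {
      pd_params_by_ftmtrs[[as.character(s$ftmtrs_tremor)]]
    }
    subj_freq <- withr::with_seed(derive_seed(seed, i * 1000L), {
      base$tremor_freq_hz + stats::runif(1, -freq_jitter_hz, freq_jitter_hz)
    })
    for (sess in seq_len(s$n_sessions)) {
      for (j in seq_len(n_fingers)) {
        k <- k + 1L
        prm <- base
        prm$tremor_freq_hz <- subj_freq
        prm$seed <- derive_seed(seed, k)
        rows[[k]] <- simulate_trace(
          prm, protocol,
          subject_id = s$subject_id,
          session_id = paste0(s$subject_id, "-", sess),
          hand = layout$hand[j], finger = layout$finger[j],
          label = if (s$group == "pd") 1L else 0L
        )
      }
    }
  }
  validate_traces(dplyr::bind_rows(rows))
}

#' Drop thumb measurements from a dataset
#'
#' Thumb measurements are excluded uniformly because subjects with
#' Parkinson's disease could not maintain pressure on the thumb gauges;
#' exactly two measurements per session (one thumb per hand) are removed
#' under the standard protocol.
#'
#' @param traces A `tf_traces` tibble (each row must carry a `finger`).
#' @return The table without thumb rows.
#' @export
exclude_thumbs <- function(traces) {
  validate_traces(traces)
  dplyr::filter(traces, .data$finger != "thumb")
}
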