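# shared fixtures built in code

# a trace table from a bare sample vector
trace_from_samples <- function(x, rate_hz = 40, finger = "index",
                               hand = "left") {
  new_traces("T01", "T01-1", hand, finger, rate_hz, force = list(x))
}

# noise-free ramp + plateau + optional sinusoid, via the generator
clean_trace <- function(freq = 6, amp = 20, seed = 1) {
  simulate_trace(sim_params(
    tremor_freq_hz = freq, tremor_amp_gf = amp, amp_mod_depth = 0,
    amp_mod_freq_hz = 0.5, noise_sd_gf = 0, drift_gf_per_s = 0, seed = seed
  ))
}

# a two-subject mini cohort (1 healthy, 1 PD) for pipeline tests
mini_cohort <- function(seed = 1) {
  design <- cohort_design(tibble::tibble(
    subject_id = c("H1", "P1"), group = c("healthy", "pd"),
    ftmtrs_tremor = c(0L, 3L), n_sessions = c(1L, 1L)
  ))
  prm <- default_cohort_params()
  simulate_cohort(design, prm$healthy, prm$pd, seed = seed)
}

# 28 high-SNR left-hand measurements at a fixed tremor frequency,
# emulating 7 repetitions of the per-hand protocol without thumbs
repeat_hand_traces <- function(freq = 6.9, seed_base = 100,
                               protocol = protocol_config(hold_s = 5)) {
  fingers <- c("index", "middle", "ring", "little")
  rows <- lapply(1:28, function(i) {
    simulate_trace(
      sim_params(tremor_freq_hz = freq, tremor_amp_gf = 30, noise_sd_gf = 2,
                 seed = seed_base + i),
      protocol, subject_id = "P1", session_id = sprintf("P1-%d", (i - 1) %/% 4 + 1),
      hand = "left", finger = fingers[(i - 1) %% 4 + 1]
    )
  })
  dplyr::bind_rows(rows)
}

# spectrum constructor shortcut for quadrature tests
psd_fixture <- function(freq_hz, value, n = 120, rate = 40) {
  tremorforce:::new_spectrum(freq_hz, value, "psd", n, rate)
}
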