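test_that("noise-free generator holds the plateau exactly at the target", {
  tr <- simulate_trace(sim_params(tremor_amp_gf = 0, noise_sd_gf = 0,
                                  drift_gf_per_s = 0, seed = 1))
  x <- tr$force[[1]]
  # ramp is 1 s at 40 Hz; everything after sample 40 is plateau
  expect_true(all(x[41:length(x)] == 300))
  expect_length(x, 200)  # ramp 1 s + hold 3 s + 1 s margin
})

test_that("generated tremor places its spectral maximum at the set frequency", {
  tr <- clean_trace(freq = 6, amp = 20)
  w <- preprocess(tr)
  psd <- power_spectral_density(w$samples[[1]], 40)
  expect_equal(dominant_frequency(psd, c(0, 20)), 6.0)
})

test_that("generators are bit-identical under the same seed", {
  p <- sim_params(tremor_freq_hz = 5, tremor_amp_gf = 15, noise_sd_gf = 3,
                  tap_dropout_prob = 0.3, seed = 42)
  expect_identical(simulate_trace(p)$force[[1]], simulate_trace(p)$force[[1]])

  prm <- default_cohort_params()
  c1 <- mini_cohort(seed = 9)
  c2 <- mini_cohort(seed = 9)
  expect_identical(c1$label, c2$label)
  expect_identical(c1$force, c2$force)

  r1 <- simulate_rig(rig_params(seed = 5, velocity_fluct_beta = 0.3))
  r2 <- simulate_rig(rig_params(seed = 5, velocity_fluct_beta = 0.3))
  expect_identical(r1$trace$force, r2$trace$force)
  expect_identical(r1$encoder$pulse_times_s, r2$encoder$pulse_times_s)
})

test_that("with no noise or modulation, tremor energy concentrates at the set frequency", {
  # bin-aligned tones for a 3 s window (1/3 Hz bins); off-bin tones smear
  # power by rectangular-window leakage, a property of the estimator
  for (f in c(4, 6, 7)) {
    tr <- clean_trace(freq = f, amp = 20, seed = round(f * 10))
    w <- preprocess(tr)
    psd <- power_spectral_density(w$samples[[1]], 40)
    total <- sum(psd$value)
    near <- abs(psd$freq_hz - f) <= 0.35
    expect_gte(sum(psd$value[near]) / total, 0.99)
  }
})

test_that("cohort counts follow the design and thumb exclusion removes 2 per session", {
  coh <- mini_cohort()
  expect_equal(nrow(coh), 20)  # 2 sessions x 10 fingers
  expect_equal(nrow(exclude_thumbs(coh)), 16)
  expect_setequal(unique(coh$label), c(0L, 1L))

  one <- cohort_design(tibble::tibble(
    subject_id = "S", group = "healthy", ftmtrs_tremor = 0L, n_sessions = 1L))
  prm <- default_cohort_params()
  tr <- simulate_cohort(one, prm$healthy, prm$pd, seed = 1)
  expect_equal(nrow(tr), 10)
  expect_equal(nrow(exclude_thumbs(tr)), 8)
  # no thumbs -> unchanged
  expect_identical(exclude_thumbs(exclude_thumbs(tr)), exclude_thumbs(tr))
})

test_that("a missing FTMTRS parameter entry is a configuration error", {
  design <- cohort_design(tibble::tibble(
    subject_id = "P1", group = "pd", ftmtrs_tremor = 2L, n_sessions = 1L))
  prm <- default_cohort_params()
  expect_error(
    simulate_cohort(design, prm$healthy, prm$pd[c("0", "1")], seed = 1),
    class = "tf_error_configuration"
  )
})

test_that("invalid generator parameters are rejected", {
  expect_error(sim_params(tremor_freq_hz = 0), class = "tf_error_invalid_parameter")
  expect_error(sim_params(ramp_s = -1), class = "tf_error_invalid_parameter")
  expect_error(sim_params(noise_sd_gf = -2), class = "tf_error_invalid_parameter")
  expect_error(rig_params(rev_per_s = 25), class = "tf_error_invalid_parameter")
  expect_error(rig_params(duration_s = 0.33), class = "tf_error_invalid_parameter")
})
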