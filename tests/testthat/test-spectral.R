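test_that("one-sided spectrum geometry matches the window length", {
  t <- (0:119) / 40
  sp <- amplitude_spectrum(sin(2 * pi * 6 * t), 40)
  expect_equal(nrow(sp), 61)                      # floor(120/2) + 1
  expect_equal(diff(sp$freq_hz), rep(1 / 3, 60))  # bin spacing rate/N
  expect_equal(range(sp$freq_hz), c(0, 20))
  expect_error(amplitude_spectrum(rnorm(5), 40),
               class = "tf_error_invalid_parameter")
})

test_that("a sinusoid at an exact bin frequency recovers its amplitude", {
  t <- (0:119) / 40
  for (A in c(1, 7.3)) {
    sp <- amplitude_spectrum(A * sin(2 * pi * 6 * t), 40)
    expect_equal(sp$value[sp$freq_hz == 6], A, tolerance = 1e-9)
    expect_lt(max(sp$value[sp$freq_hz != 6]), 1e-9)
  }
  expect_true(all(amplitude_spectrum(rep(0, 120), 40)$value == 0))
})

test_that("the periodogram satisfies Parseval's identity", {
  set.seed(5)
  for (n in c(120, 200, 137)) {
    x <- rnorm(n, 300, 10)
    psd <- power_spectral_density(x, 40)
    xc <- x - mean(x)
    expect_equal(sum(psd$value), mean(xc^2), tolerance = 1e-9)
  }
  expect_true(all(power_spectral_density(rep(0, 120), 40)$value == 0))
})

test_that("a pure in-bin sinusoid concentrates its power in one bin", {
  t <- (0:119) / 40
  psd <- power_spectral_density(10 * sin(2 * pi * 6 * t), 40)
  expect_gte(psd$value[psd$freq_hz == 6] / sum(psd$value), 0.99)
})

test_that("dominant frequency is the in-band argmax with low-frequency tie-break", {
  t <- (0:119) / 40
  psd <- power_spectral_density(sin(2 * pi * 6 * t), 40)
  expect_equal(dominant_frequency(psd), 6.0)

  tied <- psd_fixture(seq(0, 20, by = 0.5), rep(0, 41))
  tied$value[tied$freq_hz %in% c(4, 6)] <- 1
  expect_equal(dominant_frequency(tied), 4.0)

  # off-bin sinusoid: leakage keeps the argmax within one bin
  psd2 <- power_spectral_density(sin(2 * pi * 5.45 * t), 40)
  expect_lte(abs(dominant_frequency(psd2) - 5.45), 1 / 3)

  expect_error(dominant_frequency(psd, band = c(30, 35)),
               class = "tf_error_invalid_parameter")
})

test_that("dominant frequency equals a brute-force in-band argmax", {
  set.seed(17)
  for (rep in 1:20) {
    psd <- power_spectral_density(rnorm(120, 300, 5), 40)
    inband <- psd[psd$freq_hz >= 3.5 & psd$freq_hz <= 7.5, ]
    brute <- inband$freq_hz[which(inband$value == max(inband$value))][1]
    expect_identical(dominant_frequency(psd), brute)
  }
})

test_that("peak power integrates the PSD curve over the +/- 0.3 Hz interval", {
  freqs <- seq(0, 20, by = 1 / 3)
  # uniform PSD of height c -> rectangle 0.6 * c
  for (c_ in c(1, 4.2)) {
    expect_equal(peak_power(psd_fixture(freqs, rep(c_, length(freqs))), 5.5),
                 0.6 * c_, tolerance = 1e-12)
  }
  # PSD zero outside one bin at f_d: hand-computed trapezoid
  h <- 3.7
  single <- rep(0, length(freqs))
  single[which.min(abs(freqs - 6))] <- h
  # edges at 6 +/- 0.3 interpolate to h * (1 - 0.3/(1/3)) = 0.1 h;
  # area = 2 * 0.3 * (0.1h + h)/2 = 0.33 h
  expect_equal(peak_power(psd_fixture(freqs, single), 6), 0.33 * h,
               tolerance = 1e-12)
  expect_equal(peak_power(psd_fixture(freqs, rep(0, length(freqs))), 6), 0)
  expect_error(peak_power(psd_fixture(freqs, single), 30),
               class = "tf_error_invalid_parameter")
})

test_that("peak power proportion behaves as a concentration statistic", {
  # uniform PSD supported on the 4 Hz analysis band -> 0.6 / 4
  freqs <- seq(3.5, 7.5, by = 0.1)
  unif <- psd_fixture(freqs, rep(2, length(freqs)))
  expect_equal(peak_power_proportion(unif, peak_power(unif, 5.5)), 0.15,
               tolerance = 1e-12)

  # noise-free in-band sinusoid at a bin centre
  t <- (0:119) / 40
  psd <- power_spectral_density(8 * sin(2 * pi * 6 * t), 40)
  vf <- peak_power_proportion(psd, peak_power(psd, dominant_frequency(psd)))
  expect_gte(vf, 0.99 - 1e-12)

  zero <- psd_fixture(freqs, rep(0, length(freqs)))
  expect_error(peak_power_proportion(zero, 0),
               class = "tf_error_undefined_assessment")
})

test_that("the proportion is invariant to uniform amplitude scaling", {
  set.seed(33)
  x <- rnorm(120, 0, 1) + 5 * sin(2 * pi * 6 * (0:119) / 40)
  vf_of <- function(z) {
    psd <- power_spectral_density(z, 40)
    peak_power_proportion(psd, peak_power(psd, dominant_frequency(psd)))
  }
  expect_equal(vf_of(17.3 * x), vf_of(x), tolerance = 1e-12)
  expect_equal(vf_of(0.001 * x), vf_of(x), tolerance = 1e-9)
})

test_that("white-noise windows rarely concentrate power", {
  n_low <- 0
  for (s in 1:100) {
    set.seed(s)
    tr <- trace_from_samples(rnorm(200, 300, 5))
    w <- preprocess(tr, protocol_config(tolerance_frac = 0.9))
    a <- assess(w)
    n_low <- n_low + (a$v_f < 0.5)
  }
  expect_gte(n_low, 95)
})

test_that("assessment composes the statistics and applies the threshold", {
  tr <- clean_trace(freq = 6, amp = 30)
  a <- assess(preprocess(tr), threshold = 0.5)
  expect_true(a$valid)
  expect_equal(a$f_d, 6.0)
  expect_equal(c(a$f1, a$f2), c(5.7, 6.3))
  expect_true(a$v_f >= 0 && a$v_f <= 1)
  # threshold 0 on any nonzero signal -> valid
  expect_true(assess(preprocess(tr), threshold = 0)$valid)
  # pure noise at a strict threshold -> invalid
  set.seed(2)
  noisy <- trace_from_samples(rnorm(200, 300, 5))
  expect_false(assess(preprocess(noisy, protocol_config(tolerance_frac = 0.9)),
                      threshold = 0.9)$valid)
})

test_that("simulated tremor frequencies are recovered within a bin", {
  for (f in c(4, 5.5, 7)) {
    ok <- 0
    for (s in 1:40) {
      tr <- simulate_trace(sim_params(tremor_freq_hz = f, tremor_amp_gf = 20,
                                      noise_sd_gf = 4, seed = s))
      a <- assess(preprocess(tr))
      ok <- ok + (abs(a$f_d - f) <= 0.35)
    }
    expect_gte(ok, 38)
  }
})
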