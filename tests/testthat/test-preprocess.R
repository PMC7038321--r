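test_that("outlier repair replaces dropouts by interpolation and nothing else", {
  # constant trace: no sample is strictly below its own percentile
  const <- trace_from_samples(rep(300, 200))
  expect_identical(outlier_filter(const)$force[[1]], rep(300, 200))

  # two dropouts among 200 samples: the 1.25th percentile is 300, both
  # zeros interpolate between 300-valued neighbours
  x <- c(rep(300, 58), 0, rep(300, 60), 0, rep(300, 80))
  fixed <- outlier_filter(trace_from_samples(x))$force[[1]]
  expect_equal(fixed, rep(300, 200))

  # leading outlier takes the nearest non-outlier value
  y <- c(0, rep(300, 199))
  expect_equal(outlier_filter(trace_from_samples(y))$force[[1]],
               rep(300, 200))
})

test_that("outlier repair alters at most ceiling(0.0125 N) samples", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(50:400, 1)
    x <- rnorm(n, 300, 20)
    fixed <- outlier_filter_vec(x)
    # brute-force count of sub-percentile samples
    q <- quantile(x, 0.0125, type = 7, names = FALSE)
    expect_identical(which(fixed != x), which(x < q))
    expect_lte(sum(fixed != x), ceiling(0.0125 * n))
  }
})

test_that("outlier repair is idempotent on dropout-repair fixtures", {
  x <- c(rep(300, 100), 0, rep(300, 60), 0, 0, rep(300, 37))
  once <- outlier_filter_vec(x)
  expect_equal(outlier_filter_vec(once), once)
  # plateau with a shallow deterministic ripple and two dropouts
  y <- 300 + 5 * sin(2 * pi * 6 * (0:199) / 40)
  y[c(50, 130)] <- 0
  once_y <- outlier_filter_vec(y)
  expect_equal(outlier_filter_vec(once_y), once_y)
})

test_that("band-pass response meets its attenuation contract", {
  rate <- 40
  t <- (0:479) / rate
  rms_mid <- function(x) sqrt(mean(x[81:400]^2))  # avoid edge transients
  pass <- bandpass_vec(sin(2 * pi * 5.5 * t), rate)
  expect_gte(rms_mid(pass) / rms_mid(sin(2 * pi * 5.5 * t)), 0.9)
  for (f in c(1, 1.5, 10, 15)) {
    stop_ <- bandpass_vec(sin(2 * pi * f * t), rate)
    expect_lte(rms_mid(stop_) / rms_mid(sin(2 * pi * f * t)), 0.1)
  }
  expect_identical(bandpass_vec(rep(0, 100), rate), rep(0, 100))
  expect_length(bandpass_vec(rnorm(137), rate), 137)
})

test_that("band-pass is linear", {
  set.seed(8)
  x <- rnorm(300); y <- rnorm(300)
  a <- 2.5; b <- -1.2
  lhs <- bandpass_vec(a * x + b * y, 40)
  rhs <- a * bandpass_vec(x, 40) + b * bandpass_vec(y, 40)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("band edges outside Nyquist are rejected", {
  expect_error(bandpass_vec(rnorm(100), 40, 3.5, 25),
               class = "tf_error_invalid_parameter")
  expect_error(bandpass_vec(rnorm(100), 40, 8, 5),
               class = "tf_error_invalid_parameter")
})

test_that("hold-window search finds the plateau and enforces the exact length", {
  rate <- 40
  # ramp over 1 s then exact 300 gf plateau of 4 s
  x <- c(seq(0, 300, length.out = rate), rep(300, 4 * rate))
  w <- find_hold_window(trace_from_samples(x))
  expect_equal(w$n_samples, 120)
  expect_length(w$samples[[1]], 120)
  # first in-tolerance sample: ramp enters [240, 360] before the plateau
  expect_equal(w$start_index, min(which(abs(x - 300) <= 60)))

  # extended 5 s hold on a 6 s plateau -> 200 samples
  x5 <- c(seq(0, 300, length.out = rate), rep(300, 6 * rate))
  w5 <- find_hold_window(trace_from_samples(x5), protocol_config(hold_s = 5))
  expect_equal(w5$n_samples, 200)
  expect_length(w5$samples[[1]], 200)

  # a trace that never reaches the tolerance band is invalid
  expect_error(find_hold_window(trace_from_samples(rep(100, 200))),
               class = "tf_error_measurement_invalid")
})

test_that("window indices refer to the raw trace so filtered samples can be cut", {
  tr <- clean_trace(freq = 6, amp = 20)
  filt <- bandpass(tr)
  w <- find_hold_window(tr, cut_from = filt)
  s <- w$start_index
  expect_identical(w$samples[[1]], filt$force[[1]][s:(s + 119)])
  # the same span on the raw trace stays inside the tolerance band
  expect_true(all(abs(tr$force[[1]][s:(s + 119)] - 300) <= 60))
})
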