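test_that("amplitude spectrum localizes a pure tone and normalizes to 1", {
  fs <- 150
  t <- (0:374) / fs
  data <- array(0, c(20, 1, 375))
  for (e in 1:20) data[e, 1, ] <- 3 * sin(2 * pi * 10 * t + e)
  ep <- make_epochs(data, fs = fs)
  sp <- amplitude_spectrum(ep, "ch1")
  expect_equal(sp$freqs[which.max(sp$amp)], 10, tolerance = 0.41)
  band <- sp$freqs >= 4 & sp$freqs <= 20
  expect_equal(sum(sp$amp[band]), 1, tolerance = 1e-9)
  expect_equal(sp$n_epochs_averaged, 20)
  # max-normalization variant scales the band maximum to one
  spm <- amplitude_spectrum(ep, "ch1", norm = "max")
  expect_equal(max(spm$amp[band]), 1, tolerance = 1e-9)
})

test_that("white-noise spectra are flat over the normalization band", {
  set.seed(31)
  data <- array(rnorm(500 * 1 * 375), c(500, 1, 375))
  sp <- amplitude_spectrum(make_epochs(data), "ch1")
  band <- sp$amp[sp$freqs >= 4 & sp$freqs <= 20]
  expect_lt(max(band) / min(band), 2)
})

test_that("spectrum estimation validates its inputs", {
  ep <- make_epochs(array(rnorm(375), c(1, 1, 375)))
  expect_error(amplitude_spectrum(ep, "nope"), "not present")
  # 5 samples at 150 Hz: bins at 0 and 30 Hz only, none inside 4-20 Hz
  short <- make_epochs(array(rnorm(5), c(1, 1, 5)))
  expect_error(amplitude_spectrum(short, "ch1"), "normalization band")
})

fake_spectrum <- function(freqs, amp) {
  structure(list(freqs = freqs, amp = amp, n_epochs_averaged = 1,
                 source_channel = "POOL", norm = "sum",
                 norm_band = c(4, 20)), class = "rsvp_spectrum")
}

test_that("IAF peaks round to the nearest 0.5 Hz", {
  f <- seq(0, 30, by = 0.2)
  amp <- exp(-((f - 10.2)^2) / 2) + 0.01
  est <- estimate_iaf(fake_spectrum(f, amp), rate_hz = 1)
  expect_equal(est$iaf_hz, 10.0)
  expect_equal(est$method, "detected")
  amp2 <- exp(-((f - 10.8)^2) / 2) + 0.01
  expect_equal(estimate_iaf(fake_spectrum(f, amp2), 1)$iaf_hz, 11.0)
})

test_that("flat spectra fall back to 10 Hz", {
  f <- seq(0, 30, by = 0.2)
  est <- estimate_iaf(fake_spectrum(f, rep(1, length(f))), rate_hz = 1)
  expect_equal(est$iaf_hz, 10.0)
  expect_equal(est$method, "fallback")
})

test_that("SSVEP harmonic bins are masked before the peak search", {
  f <- seq(0, 30, by = 0.2)
  # alpha peak at 9 Hz flanked by strong 8 and 12 Hz harmonic lines
  amp <- 0.5 * exp(-((f - 9)^2) / 1) + 0.02
  amp[abs(f - 8) < 0.11] <- 3
  amp[abs(f - 12) < 0.11] <- 2
  est <- estimate_iaf(fake_spectrum(f, amp), rate_hz = 4)
  expect_equal(est$iaf_hz, 9.0)
  expect_equal(est$method, "detected")
  expect_equal(est$excluded_freqs, c(4, 8, 12))
  # without masking the 8 Hz line would win: brute-force argmax check
  in_band <- f >= 7.5 & f <= 12.5
  expect_equal(f[in_band][which.max(amp[in_band])], 8)
})

test_that("IAF search requires coverage of the search band", {
  f <- seq(0, 6, by = 0.2)
  expect_error(estimate_iaf(fake_spectrum(f, rep(1, length(f))), 1),
               "search band")
})

test_that("reference simulations recover the configured IAF at both rates", {
  for (rate in c(1, 4)) for (f0 in c(9, 10, 11)) {
    ep <- prep_epochs(rate, 20, seed = 3, iaf_true = f0)
    est <- estimate_iaf(amplitude_spectrum(ep, "POOL"), rate)
    expect_equal(est$iaf_hz, f0)
    expect_equal(est$method, "detected")
  }
})

test_that("alpha-free reference calibrations trigger the 10 Hz fallback", {
  ep <- prep_epochs(1, 100, seed = 1, alpha_amp = 0)
  est <- estimate_iaf(amplitude_spectrum(ep, "POOL"), 1)
  expect_equal(est$iaf_hz, 10.0)
  expect_equal(est$method, "fallback")
})
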