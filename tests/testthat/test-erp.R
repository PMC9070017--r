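test_that("class averages baseline-correct and average correctly", {
  fs <- 150
  n <- 150
  wave <- sin(2 * pi * 3 * (0:(n - 1)) / fs) + 2   # constant offset removed
  data <- array(0, c(4, 1, n))
  data[1, 1, ] <- wave; data[2, 1, ] <- wave
  data[3, 1, ] <- wave; data[4, 1, ] <- -wave
  ep <- make_epochs(data, fs = fs, window = c(-200, 800),
                    labels = c("target", "target", "nontarget", "nontarget"))
  avg <- average_erp(ep, "ch1")
  # identical epochs: average equals any one (after baseline removal)
  centered <- wave - mean(wave[ep$times >= -200 & ep$times < 0])
  expect_equal(avg$target, centered, tolerance = 1e-12)
  # epoch + negation: zero mean (their baselines cancel symmetrically)
  expect_equal(avg$nontarget,
               (centered + (-wave - mean(-wave[ep$times >= -200 & ep$times < 0]))) / 2,
               tolerance = 1e-12)
  expect_error(average_erp(make_epochs(data, fs = fs, window = c(-200, 800),
                                       labels = rep("target", 4)), "ch1"),
               "both classes")
})

test_that("peak detection finds extrema and honors tie/boundary rules", {
  times <- seq(-200, 800 - 1000 / 150, by = 1000 / 150)
  # monotone ramp: extrema at window boundaries
  ramp <- seq_along(times)
  lat <- detect_peaks(ramp, times = times)
  expect_lt(abs(lat["n200_lat"] - 200), 4)        # minimum at window start
  expect_lt(abs(lat["p300_lat"] - 450), 4)        # maximum at window end
  # flat input: earliest sample of each window
  flat <- detect_peaks(rep(0, length(times)), times = times)
  expect_lt(abs(flat["n200_lat"] - 200), 4)
  expect_lt(abs(flat["p300_lat"] - 300), 4)
})

test_that("peak amplitude is the 9-sample mean around the latency", {
  times <- seq(-200, 800 - 1000 / 150, by = 1000 / 150)
  const <- rep(5, length(times))
  expect_equal(peak_amplitude(const, 300, times), 5)
  # triangular peak: smoothing pulls the mean below the apex
  tri <- pmax(0, 10 - abs(seq_along(times) - 80))
  lat <- times[80]
  expect_lt(peak_amplitude(tri, lat, times), 10)
  expect_warning(peak_amplitude(const, times[2], times), "clipped")
})

test_that("simulated target ERPs are recovered at the right latencies", {
  ep <- prep_epochs(1, 30, seed = 5, window = c(-200, 800))
  s <- erp_summary(ep, "POOL")
  expect_lt(abs(s$latencies["n200_lat"] - 250), 20)
  expect_lt(abs(s$latencies["p300_lat"] - 375), 20)
  # target effects carry the component signs
  expect_lt(s$target_effects["n200"], 0)
  expect_gt(s$target_effects["p300"], 0)
  # Pz-only shows the same signs
  sp <- erp_summary(ep, "Pz")
  expect_lt(sp$target_effects["n200"], 0)
  expect_gt(sp$target_effects["p300"], 0)
})

test_that("injected P300 amplitude is recovered in the noise-free case", {
  # unfiltered path: isolates peak labeling + 9-point averaging from the
  # spectral bite of the 1 Hz high-pass (a sigma = 25 ms bump has
  # substantial sub-1 Hz energy)
  sch <- make_schedule(1, 10, 10, seed = 6)
  rec <- synthesize_recording(sch, sim_params(seed = 6, noise_amp = 0,
                                              alpha_amp = 0, ssvep_amp = 0))
  rec <- pool_channels(resample_recording(rec, 150))
  ep <- epoch_recording(rec, c(-200, 800))
  s <- erp_summary(ep, "Pz")
  # analytic oracle: the 9-sample mean of a sigma = 25 ms Gaussian at
  # 150 Hz retains mean(exp(-(t_k/sigma)^2/2)) ~ 80.6% of the 8 uV apex
  offs <- (-4:4) * (1000 / 150)
  expected <- 8 * mean(exp(-offs^2 / (2 * 25^2)))
  expect_equal(unname(s$amplitudes["p300", "target"]), expected,
               tolerance = 0.05)
  expect_equal(s$amplitudes["p300", "nontarget"], 0, tolerance = 0.2)
})
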