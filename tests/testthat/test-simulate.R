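test_that("null signal settings give an all-zero recording", {
  sch <- make_schedule(1, 2, 10, seed = 1)
  rec <- synthesize_recording(sch, sim_params(
    alpha_amp = 0, n200_amp = 0, p300_amp = 0, ssvep_amp = 0,
    noise_amp = 0, blink_rate = 0))
  expect_true(all(rec$data == 0))
  expect_equal(nrow(rec$data), 7)
  expect_equal(rec$fs, 300)
})

test_that("synthesis is bit-reproducible under a fixed seed", {
  sch <- make_schedule(4, 3, 10, seed = 2)
  r1 <- synthesize_recording(sch, sim_params(seed = 9, blink_rate = 4))
  r2 <- synthesize_recording(sch, sim_params(seed = 9, blink_rate = 4))
  expect_identical(r1$data, r2$data)
  r3 <- synthesize_recording(sch, sim_params(seed = 10, blink_rate = 4))
  expect_false(identical(r3$data, r1$data))
})

test_that("SSVEP-only 4 Hz recording has spectral maxima at 4, 8, 12 Hz", {
  sch <- make_schedule(4, 5, 10, seed = 3)
  rec <- synthesize_recording(sch, sim_params(
    alpha_amp = 0, n200_amp = 0, p300_amp = 0, noise_amp = 0,
    ssvep_amp = 3))
  # brute-force FFT peak location on the raw Oz trace
  x <- rec$data["Oz", ]
  n <- length(x)
  amp <- Mod(stats::fft(x))[1:(n %/% 2)]
  f <- (seq_len(n %/% 2) - 1) * rec$fs / n
  df <- f[2] - f[1]
  for (target_f in c(4, 8, 12)) {
    sel <- f > target_f - 1 & f < target_f + 1
    expect_lt(abs(f[sel][which.max(amp[sel])] - target_f), df + 1e-9)
  }
  # harmonic amplitude ordering follows the configured relative amplitudes
  peak_amp <- sapply(c(4, 8, 12), function(tf) max(amp[abs(f - tf) < 0.5]))
  expect_true(peak_amp[1] > peak_amp[2] && peak_amp[2] > peak_amp[3])
})

test_that("alpha-only spectrum peaks within one bin of the true IAF", {
  for (f0 in c(9, 11)) {
    sch <- make_schedule(1, 5, 10, seed = 4)
    rec <- synthesize_recording(sch, sim_params(
      iaf_true = f0, n200_amp = 0, p300_amp = 0, ssvep_amp = 0,
      noise_amp = 0, alpha_env_mod = 0, erd_depth = 0, seed = 4))
    rec <- pool_channels(rec)
    ep <- epoch_recording(rec, c(-1250, 1250))
    sp <- amplitude_spectrum(ep, "POOL")
    df <- sp$freqs[2] - sp$freqs[1]
    expect_lt(abs(sp$freqs[which.max(sp$amp)] - f0), df + 1e-9)
  }
})

test_that("injected attenuation halves the target-epoch alpha envelope", {
  # Hilbert-envelope oracle, independent of the wavelet pipeline.
  # Over the measured 300-800 ms window the raised-cosine ramps occupy
  # 50 ms at each edge, so the expected envelope ratio for d = 0.5 is
  # 1 - d * 450/500 = 0.55.
  sch <- make_schedule(1, 20, 10, seed = 6)
  rec <- synthesize_recording(sch, sim_params(
    erd_depth = 0.5, n200_amp = 0, p300_amp = 0, ssvep_amp = 0,
    noise_amp = 0, alpha_env_mod = 0, seed = 6))
  env <- hilbert_envelope(rec$data["Oz", ])
  fs <- rec$fs
  win_mean <- function(onset_ms)
    mean(env[round((onset_ms + 300) / 1000 * fs):round((onset_ms + 800) / 1000 * fs)])
  ev <- rec$events
  m_t <- mean(sapply(ev$onset_ms[ev$class == "target"], win_mean))
  m_n <- mean(sapply(ev$onset_ms[ev$class == "nontarget"], win_mean))
  expect_lt(abs(m_t / m_n - 0.55), 0.05)
})

test_that("erd depth is recovered by the wavelet pipeline within 0.1", {
  d_hat <- sapply(c(0.2, 0.5, 0.8), function(d) {
    ep <- prep_epochs(1, 20, seed = 7, erd_depth = d)
    iaf <- estimate_iaf(amplitude_spectrum(ep, "POOL"), 1)
    k <- select_iaf_layer(layer_freqs(), iaf$iaf_hz)
    sc <- cwt_scaleogram(ep, channels = "POOL", layers = k)
    estimate_erd_depth(sc, 1)
  })
  expect_true(all(abs(d_hat - c(0.2, 0.5, 0.8)) <= 0.1))
  expect_true(all(diff(d_hat) > 0))
})

test_that("artifact injection returns accurate ground truth", {
  sch <- make_schedule(1, 10, 10, seed = 8)
  rec <- synthesize_recording(sch, sim_params(seed = 8))
  rec <- bandpass_notch(rec)
  rec <- resample_recording(rec, 150)
  inj <- inject_artifacts(rec, n_per_rule = 2, seed = 3)
  expect_equal(nrow(inj$ground_truth), 8)
  expect_setequal(unique(inj$ground_truth$rule),
                  c("gradient", "difference", "absolute", "low_activity"))
  # no injections -> empty ground truth, untouched data
  none <- inject_artifacts(rec, n_per_rule = 0)
  expect_equal(nrow(none$ground_truth), 0)
  expect_identical(none$data, rec$data)
})

test_that("simulation rejects inconsistent parameters", {
  expect_error(sim_params(erd_depth = 1.5), "erd_depth")
  expect_error(sim_params(alpha_amp = -1), "amplitudes")
  expect_error(sim_params(nonsense = 1), "unknown")
  sch <- make_schedule(4, 1, 10, seed = 1)
  expect_error(synthesize_recording(sch, sim_params(fs = 20)), "twice")
})
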