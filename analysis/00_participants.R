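# Shared definition of the synthetic cohort used by the analysis
# scripts: 12 simulated participants with individual alpha frequencies,
# attenuation depths, and alpha amplitudes drawn once (seeded) to mimic
# between-participant variability.  Source this file from the numbered
# scripts.

library(rsvpalpha)

participants <- local({
  set.seed(20260924)
  data.frame(
    id = sprintf("P%02d", 1:12),
    seed = 101:112,
    iaf_true = sample(seq(9, 11.5, by = 0.5), 12, replace = TRUE),
    erd_depth = round(runif(12, 0.25, 0.7), 2),
    alpha_amp = round(runif(12, 6, 14), 1)
  )
})

n_trials <- 40          # desk-scale calibration length used throughout

simulate_participant <- function(p, rate) {
  sch <- make_schedule(rate, n_trials, 10, seed = p$seed)
  synthesize_recording(sch, sim_params(seed = p$seed, iaf_true = p$iaf_true,
                                       erd_depth = p$erd_depth,
                                       alpha_amp = p$alpha_amp))
}

preprocess_recording <- function(rec) {
  rec <- bandpass_notch(rec)
  rec <- resample_recording(rec, 150)
  pool_channels(rec)
}

dir.create("results", showWarnings = FALSE)
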