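# Classifier comparison on one reference calibration per rate: the three
# alpha time-series models, the uniform-random control, and the RDA/KDE
# ERP reference, each scored by mean balanced accuracy over 10 stratified
# 80/20 splits; plus baseline/response window tuning for the logistic
# regression criterion model.

source("analysis/00_participants.R")

cv <- cv_spec(10, 0.2)
rows <- list()
tuning <- list()
for (rate in c(1, 4)) {
  sch <- make_schedule(rate, n_trials, 10, seed = 77)
  rec0 <- synthesize_recording(sch, sim_params(seed = 77))
  rec <- preprocess_recording(rec0)
  ep <- epoch_recording(rec, c(-1250, 1250))
  iaf <- estimate_iaf(amplitude_spectrum(ep, "POOL"), rate)
  k <- select_iaf_layer(layer_freqs(), iaf$iaf_hz)
  z <- ztransform(cwt_scaleogram(ep, channels = posterior_channels(),
                                 layers = k))
  feats <- extract_alpha_features(z, 1)
  for (m in c("logreg_l2", "svc", "tangent_space", "uniform_random")) {
    r <- train_eval(feats, m, cv, seed = 77)
    rows[[length(rows) + 1]] <- data.frame(
      rate_hz = rate, model = m, mean_balanced_acc = r$mean_balanced_acc,
      sd_splits = sd(r$per_split_balanced_acc))
  }
  # ERP reference: 2-45 Hz filtered, 0..+500 ms epochs, all 7 channels
  erp_rec <- resample_recording(bandpass_notch(rec0, 2, 45, NULL), 150)
  erp_ep <- epoch_recording(erp_rec, c(0, 500))
  r <- rda_kde_eval(erp_ep, cv, seed = 77)
  rows[[length(rows) + 1]] <- data.frame(
    rate_hz = rate, model = "rda_kde",
    mean_balanced_acc = r$mean_balanced_acc,
    sd_splits = sd(r$per_split_balanced_acc))

  tg <- tune_windows(ep, iaf$iaf_hz, grid_step_ms = 150,
                     cv = cv_spec(5, 0.2), seed = 77)
  tuning[[sprintf("%dhz", rate)]] <- list(
    best = as.list(tg$best), best_score = tg$best_score,
    default_score = tg$default_score)
  message(sprintf("%d Hz tuned: %s", rate,
                  paste(names(tg$best), tg$best, collapse = ", ")))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/06_classifiers.csv", row.names = FALSE)
jsonlite::write_json(tuning, "results/06_tuning.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
print(tab)
message("wrote results/06_classifiers.csv and results/06_tuning.json")
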