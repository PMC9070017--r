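# Alpha attenuation across the synthetic cohort: within-participant
# Mann-Whitney tests of target vs non-target alpha (pooled signal and
# Pz-only, both rates), then across-participant Wilcoxon comparisons
# mirroring the calibration analyses: target vs non-target medians per
# rate, and the 1 Hz vs 4 Hz attenuation-size comparison.

source("analysis/00_participants.R")

rows <- list()
for (i in seq_len(nrow(participants))) {
  p <- participants[i, ]
  for (rate in c(1, 4)) {
    ep <- epoch_recording(preprocess_recording(simulate_participant(p, rate)),
                          c(-1250, 1250))
    iaf <- estimate_iaf(amplitude_spectrum(ep, "POOL"), rate)
    k <- select_iaf_layer(layer_freqs(), iaf$iaf_hz)
    for (src in c("POOL", "Pz")) {
      z <- ztransform(cwt_scaleogram(ep, channels = src, layers = k))
      a <- alpha_activity(z, 1, source = src)
      rows[[length(rows) + 1]] <- data.frame(
        id = p$id, rate_hz = rate, source = src, iaf_hz = iaf$iaf_hz,
        erd_depth = p$erd_depth,
        median_target = a$class_medians["target"],
        median_nontarget = a$class_medians["nontarget"],
        attenuation = a$attenuation, mwu_p = a$mwu_p)
    }
  }
  message(sprintf("%s done (iaf %.1f, d %.2f)", p$id, p$iaf_true, p$erd_depth))
}
within <- do.call(rbind, rows)
rownames(within) <- NULL
write.csv(within, "results/03_within_participant.csv", row.names = FALSE)

sig <- aggregate(mwu_p ~ id + rate_hz, within, min)
for (rate in c(1, 4))
  message(sprintf(
    "%d Hz: %d/12 participants show significant attenuation in >=1 source",
    rate, sum(sig$mwu_p[sig$rate_hz == rate] < 0.05)))

# across-participant tests (pooled source), as in the calibration analyses
across <- list()
for (rate in c(1, 4)) for (src in c("POOL", "Pz")) {
  w <- within[within$rate_hz == rate & within$source == src, ]
  tvn <- paired_median_test(w$median_target, w$median_nontarget)
  across[[length(across) + 1]] <- data.frame(
    comparison = sprintf("target_vs_nontarget_%dhz_%s", rate, src),
    median_1 = median(w$median_target), median_2 = median(w$median_nontarget),
    statistic = tvn$statistic, p = tvn$p_two_sided)
}
for (src in c("POOL", "Pz")) {
  a1 <- within$attenuation[within$rate_hz == 1 & within$source == src]
  a4 <- within$attenuation[within$rate_hz == 4 & within$source == src]
  cmp <- paired_median_test(a1, a4)
  across[[length(across) + 1]] <- data.frame(
    comparison = sprintf("attenuation_1hz_vs_4hz_%s", src),
    median_1 = median(a1), median_2 = median(a4),
    statistic = cmp$statistic, p = cmp$p_two_sided)
}
across <- do.call(rbind, across)
write.csv(across, "results/03_across_participants.csv", row.names = FALSE)
print(across)
message("wrote results/03_within_participant.csv and results/03_across_participants.csv")
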