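# Generate the reference synthetic calibrations (1 Hz and 4 Hz) and
# write them out as EDF + events CSV, plus a bookkeeping summary.
# Raw EDF files are bulky and land under scratch/; the summary table of
# event counts goes to results/.

source("analysis/00_participants.R")

dir.create("scratch/data", recursive = TRUE, showWarnings = FALSE)
rows <- list()
for (rate in c(1, 4)) {
  sch <- make_schedule(rate, 100, 10, seed = 1)
  rec <- synthesize_recording(sch, sim_params(seed = 1))
  stem <- sprintf("scratch/data/reference_%dhz", rate)
  write_edf(rec, paste0(stem, ".edf"))
  write_events_csv(rec, paste0(stem, "_events.csv"))
  ev <- sch$events
  rows[[as.character(rate)]] <- data.frame(
    rate_hz = rate, n_trials = sch$n_trials, seq_len = sch$seq_len,
    n_events = nrow(ev), n_target = sum(ev$class == "target"),
    n_nontarget = sum(ev$class == "nontarget"),
    duration_s = round(max(ev$onset_ms) / 1000 + 2, 1))
  message(sprintf("%d Hz: %d events (%d targets), %.0f s, %d channels",
                  rate, nrow(ev), sum(ev$class == "target"),
                  max(ev$onset_ms) / 1000, nrow(rec$data)))
}
summary_tab <- do.call(rbind, rows)
write.csv(summary_tab, "results/01_schedule_summary.csv", row.names = FALSE)
message("wrote results/01_schedule_summary.csv")
# Each calibration carries exactly one target per 10-letter sequence, so
# the class ratio is fixed at 9:1 regardless of presentation rate.
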