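# Pooled occipitoparietal amplitude spectra and IAF estimates for the
# reference calibrations written by 01_simulate.R.  Reads the EDF files
# back in (exercising the I/O path) and writes the averaged spectra and
# the IAF estimates.  Expect a 10 Hz alpha peak at both rates and, at
# 4 Hz, flanking SSVEP harmonic lines at 8 and 12 Hz.

source("analysis/00_participants.R")

iafs <- list()
for (rate in c(1, 4)) {
  stem <- sprintf("scratch/data/reference_%dhz", rate)
  rec <- read_edf(paste0(stem, ".edf"))
  rec <- read_events_csv(rec, paste0(stem, "_events.csv"))
  ep <- epoch_recording(preprocess_recording(rec), c(-1250, 1250))
  sp <- amplitude_spectrum(ep, "POOL")
  est <- estimate_iaf(sp, rate)
  write.csv(data.frame(freq = sp$freqs, amp = sp$amp),
            sprintf("results/02_spectrum_%dhz.csv", rate),
            row.names = FALSE)
  iafs[[sprintf("%dhz", rate)]] <-
    list(iaf_hz = est$iaf_hz, method = est$method,
         excluded_freqs = est$excluded_freqs)
  band <- sp$freqs >= 6 & sp$freqs <= 14
  message(sprintf("%d Hz: IAF %.1f Hz (%s); band 6-14 Hz peak at %.1f Hz",
                  rate, est$iaf_hz, est$method,
                  sp$freqs[band][which.max(sp$amp[band])]))
}
jsonlite::write_json(iafs, "results/02_iaf.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("wrote results/02_spectrum_{1,4}hz.csv and results/02_iaf.json")
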