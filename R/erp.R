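#' Class-average ERP waveforms
#'
#' Baseline-corrects every epoch by subtracting its mean over the
#' baseline window (default -200 to 0 ms), then averages samplewise
#' within each stimulus class.
#'
#' @param epochs An `rsvp_epochs` object (e.g. a -200..+800 ms
#'   segmentation).
#' @param channel Channel label to average.
#' @param baseline Length-2 ms baseline window (half-open).
#' @return A list of class `rsvp_erp_avg`: `target`, `nontarget`
#'   (numeric waveforms, uV), `times` (ms), `fs`, `channel`.
#' @export
average_erp <- function(epochs, channel = "POOL", baseline = c(-200, 0)) {
  stopifnot(inherits(epochs, "rsvp_epochs"))
  ci <- match(channel, epochs$channels)
  if (is.na(ci)) stop("channel not present: ", channel)
  tms <- epochs$times
  bidx <- which(tms >= baseline[1] & tms < baseline[2])
  if (!length(bidx)) stop("baseline window outside the epoch")
  x <- matrix(epochs$data[, ci, ], nrow = dim(epochs$data)[1])
  x <- x - rowMeans(x[, bidx, drop = FALSE])
  labels <- epochs$labels
  if (!any(labels == "target") || !any(labels == "nontarget"))
    stop("both classes must be present")
  structure(list(target = colMeans(x[labels == "target", , drop = FALSE]),
                 nontarget = colMeans(x[labels == "nontarget", , drop = FALSE]),
                 times = tms, fs = epochs$fs, channel = channel),
            class = "rsvp_erp_avg")
}

#' Detect N200 and P300 peak latencies on the target average
#'
#' The N200 latency is the time of the voltage minimum within
#' `n200_window` (default 200-350 ms) and the P300 latency the maximum
#' within `p300_window` (default 300-450 ms); exact ties resolve to the
#' earliest latency.
#'
#' @param erp_avg An `rsvp_erp_avg` (peaks are searched on its `target`
#'   waveform) or a numeric waveform with a matching `times` argument.
#' @param n200_window,p300_window Search windows (ms, half-open).
#' @param times Sample times in ms (taken from `erp_avg` when available).
#' @return Named numeric `c(n200_lat, p300_lat)` in ms.
#' @export
detect_peaks <- function(erp_avg, n200_window = c(200, 350),
                         p300_window = c(300, 450), times = NULL) {
  if (inherits(erp_avg, "rsvp_erp_avg")) {
    wave <- erp_avg$target
    times <- erp_avg$times
  } else {
    wave <- erp_avg
    if (is.null(times)) stop("`times` required for a bare waveform")
  }
  win_idx <- function(w) {
    i <- which(times >= w[1] & times <= w[2])
    if (!length(i)) stop("peak window outside the epoch")
    i
  }
  ni <- win_idx(n200_window)
  pi_ <- win_idx(p300_window)
  c(n200_lat = times[ni[which.min(wave[ni])]],
    p300_lat = times[pi_[which.max(wave[pi_])]])
}

#' Mean amplitude around a labeled peak
#'
#' Averages the voltage over `lat` plus/minus `half_width` samples (9
#' samples by default, about 53 ms at 150 Hz).  Windows clipped by the
#' epoch edge use the available samples with a warning.
#'
#' @param wave Numeric waveform (uV).
#' @param lat Peak latency in ms.
#' @param times Sample times (ms) matching `wave`.
#' @param half_width Samples on each side of the peak (default 4).
#' @return Mean amplitude (uV).
#' @export
peak_amplitude <- function(wave, lat, times, half_width = 4) {
  i0 <- which.min(abs(times - lat))
  idx <- (i0 - half_width):(i0 + half_width)
  ok <- idx >= 1 & idx <= length(wave)
  if (!all(ok))
    warning("peak window clipped by the epoch edge; using available samples")
  mean(wave[idx[ok]])
}

#' ERP component summary with target effects
#'
#' Computes class-average waveforms, detects N200/P300 latencies on the
#' target average, measures mean amplitudes (plus/minus 4 samples) around
#' those latencies for both classes — non-target amplitudes reuse the
#' target-derived latencies — and reports the target effects
#' (target minus non-target per component).
#'
#' @inheritParams average_erp
#' @inheritParams detect_peaks
#' @return A list of class `rsvp_erp_summary` with `latencies`,
#'   `amplitudes` (matrix component x class), `target_effects`, `source`,
#'   and the `avg` waveforms.
#' @export
erp_summary <- function(epochs, channel = "POOL", baseline = c(-200, 0),
                        n200_window = c(200, 350), p300_window = c(300, 450)) {
  avg <- average_erp(epochs, channel, baseline)
  lats <- detect_peaks(avg, n200_window, p300_window)
  amps <- sapply(c(target = "target", nontarget = "nontarget"), function(cl)
    c(n200 = peak_amplitude(avg[[cl]], lats["n200_lat"], avg$times),
      p300 = peak_amplitude(avg[[cl]], lats["p300_lat"], avg$times)))
  structure(list(latencies = lats, amplitudes = amps,
                 target_effects = amps[, "target"] - amps[, "nontarget"],
                 source = channel, avg = avg),
            class = "rsvp_erp_summary")
}

#' @export
print.rsvp_erp_summary <- function(x, ...) {
  cat(sprintf("ERP summary (%s): N200 %.0f ms, P300 %.0f ms\n", x$source,
              x$latencies["n200_lat"], x$latencies["p300_lat"]))
  cat(sprintf("  target effects: N200 %.3f uV, P300 %.3f uV\n",
              x$target_effects["n200"], x$target_effects["p300"]))
  invisible(x)
}
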