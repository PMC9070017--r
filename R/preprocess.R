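#' Zero-phase Butterworth band-pass plus mains notch
#'
#' Filters every channel of a recording with a zero-phase
#' (forward-backward) Butterworth band-pass, realized as a cascade of an
#' order-`order` high-pass at `low_hz` and an order-`order` low-pass at
#' `high_hz` (order 8 gives a 48 dB/octave design slope per edge),
#' followed by a second-order notch at `notch_hz` (quality factor
#' `notch_q`).  Length, events and channel order are preserved.
#'
#' @param recording An `rsvp_recording`.
#' @param low_hz,high_hz Band edges (Hz), `0 < low < high < fs/2`.
#' @param notch_hz Notch center frequency (Hz); `NULL` disables it.
#' @param order Butterworth order per band edge (even).
#' @param notch_q Notch quality factor.
#' @return The filtered `rsvp_recording`.
#' @export
bandpass_notch <- function(recording, low_hz = 1, high_hz = 45,
                           notch_hz = 60, order = 8, notch_q = 30) {
  stopifnot(inherits(recording, "rsvp_recording"))
  fs <- recording$fs
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  sos <- c(butter_sos(order, low_hz, fs, "high"),
           butter_sos(order, high_hz, fs, "low"))
  if (!is.null(notch_hz)) {
    if (notch_hz >= fs / 2) stop("notch frequency must be below Nyquist")
    sos <- c(sos, notch_biquad(notch_hz, fs, notch_q))
  }
  for (ci in seq_len(nrow(recording$data)))
    recording$data[ci, ] <- sos_filtfilt(sos, recording$data[ci, ])
  recording
}

#' Resample a recording
#'
#' Changes the sampling rate to `target_fs` and rescales event sample
#' indices (rounded to the nearest sample).  Integer downsampling factors
#' decimate directly — the analyses apply this after a 45 Hz low-pass, so
#' no further anti-aliasing is required; non-integer ratios go through a
#' polyphase rational resampler.
#'
#' @param recording An `rsvp_recording`.
#' @param target_fs Target sampling rate (Hz), `<= fs`.
#' @return The resampled `rsvp_recording`.
#' @export
resample_recording <- function(recording, target_fs = 150) {
  stopifnot(inherits(recording, "rsvp_recording"))
  fs <- recording$fs
  if (target_fs > fs) stop("`target_fs` must not exceed the current rate")
  if (target_fs == fs) return(recording)
  ratio <- target_fs / fs
  if (abs(fs / target_fs - round(fs / target_fs)) < 1e-9) {
    k <- round(fs / target_fs)
    recording$data <- recording$data[, seq(1, ncol(recording$data), by = k),
                                     drop = FALSE]
  } else {
    fr <- as.integer(attr(fractions_int(ratio), "pq"))
    recording$data <- t(apply(recording$data, 1, function(x)
      signal::resample(x, fr[1], fr[2])))
  }
  if (nrow(recording$events))
    recording$events$sample <- as.integer(
      round((recording$events$sample - 1) * ratio) + 1)
  recording$fs <- target_fs
  recording
}

# small rational approximation p/q of a ratio in (0, 1]
fractions_int <- function(x, max_q = 1000) {
  q <- seq_len(max_q)
  p <- round(x * q)
  err <- abs(p / q - x)
  i <- which.min(err)
  structure(x, pq = c(p[i], q[i]))
}

#' Append a pooled (averaged) virtual channel
#'
#' Adds a channel `"POOL"` equal to the samplewise arithmetic mean of the
#' given subset, mirroring the pooled occipitoparietal signal (Pz, Oz,
#' PO7, PO8) used throughout the analyses.
#'
#' @param recording An `rsvp_recording`.
#' @param subset Channel labels to average.
#' @return The recording with an appended `"POOL"` channel.
#' @export
pool_channels <- function(recording, subset = posterior_channels()) {
  stopifnot(inherits(recording, "rsvp_recording"))
  miss <- setdiff(subset, recording$channels)
  if (length(miss)) stop("channel(s) not present: ", paste(miss, collapse = ", "))
  pool <- colMeans(recording$data[match(subset, recording$channels), ,
                                  drop = FALSE])
  recording$data <- rbind(recording$data, POOL = pool)
  recording$channels <- c(recording$channels, "POOL")
  recording
}

#' Segment a recording into stimulus-locked epochs
#'
#' Cuts one epoch per event over the half-open window
#' `[start_ms, end_ms)` relative to stimulus onset (onset maps to the
#' sample at t = 0).  Events whose window falls outside the recording are
#' dropped with a warning and recorded in `dropped`.
#'
#' @param recording An `rsvp_recording`.
#' @param window_ms Length-2 numeric, `c(start_ms, end_ms)`.
#' @return An object of class `rsvp_epochs`: list with `data`
#'   (epoch x channel x sample array), `window`, `fs`, `labels`,
#'   `channels`, `times` (ms of each sample), `events`, `dropped`.
#' @export
epoch_recording <- function(recording, window_ms = c(-1250, 1250)) {
  stopifnot(inherits(recording, "rsvp_recording"), length(window_ms) == 2,
            window_ms[1] < window_ms[2])
  fs <- recording$fs
  n_samp <- round((window_ms[2] - window_ms[1]) / 1000 * fs)
  off <- round(window_ms[1] / 1000 * fs)
  ev <- recording$events
  n_total <- ncol(recording$data)
  starts <- ev$sample + off
  ok <- starts >= 1 & (starts + n_samp - 1) <= n_total
  if (any(!ok))
    warning(sprintf("dropped %d epoch(s) whose window exceeds the recording",
                    sum(!ok)))
  keep <- which(ok)
  data <- array(0, dim = c(length(keep), nrow(recording$data), n_samp),
                dimnames = list(NULL, recording$channels, NULL))
  for (j in seq_along(keep)) {
    s0 <- starts[keep[j]]
    data[j, , ] <- recording$data[, s0:(s0 + n_samp - 1)]
  }
  structure(list(data = data, window = window_ms, fs = fs,
                 labels = ev$class[keep], channels = recording$channels,
                 times = window_ms[1] + (seq_len(n_samp) - 1) * 1000 / fs,
                 events = ev[keep, , drop = FALSE], dropped = which(!ok)),
            class = "rsvp_epochs")
}

#' @export
print.rsvp_epochs <- function(x, ...) {
  cat(sprintf(
    "RSVP epochs: %d epochs x %d channels x %d samples at %g Hz, window [%g, %g) ms\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
    x$window[1], x$window[2]))
  invisible(x)
}

#' Subset epochs
#'
#' @param epochs An `rsvp_epochs` object.
#' @param i Epoch indices (or logical mask) to keep.
#' @return The subsetted `rsvp_epochs`.
#' @export
subset_epochs <- function(epochs, i) {
  epochs$data <- epochs$data[i, , , drop = FALSE]
  epochs$labels <- epochs$labels[i]
  epochs$events <- epochs$events[i, , drop = FALSE]
  epochs
}
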