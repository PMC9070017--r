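#' Epoch-averaged amplitude spectrum
#'
#' Computes the per-epoch FFT amplitude of one channel with a Hann taper
#' applied to the outer 20% of each epoch (10% per edge, i.e. a Tukey
#' window with taper ratio 0.2), compensates the taper's variance loss
#' (division by the window RMS), averages the amplitudes across epochs,
#' and normalizes so that the summed amplitude over `norm_band` equals 1.
#'
#' @param epochs An `rsvp_epochs` object.
#' @param channel Channel label to analyze (e.g. `"POOL"`).
#' @param taper Total tapered fraction of the epoch (default 0.2).
#' @param norm_band Normalization band in Hz (default `c(4, 20)`).
#' @param norm Either `"sum"` (band amplitudes sum to one, the default)
#'   or `"max"` (band maximum scaled to one).
#' @return A list of class `rsvp_spectrum`: `freqs` (Hz), `amp`
#'   (normalized amplitude), `n_epochs_averaged`, `source_channel`.
#' @export
amplitude_spectrum <- function(epochs, channel = "POOL", taper = 0.2,
                               norm_band = c(4, 20),
                               norm = c("sum", "max")) {
  stopifnot(inherits(epochs, "rsvp_epochs"))
  norm <- match.arg(norm)
  ci <- match(channel, epochs$channels)
  if (is.na(ci)) stop("channel not present: ", channel)
  n_ep <- dim(epochs$data)[1]
  if (n_ep < 1) stop("at least one epoch is required")
  n <- dim(epochs$data)[3]
  w <- tukey_window(n, taper)
  corr <- 1 / sqrt(mean(w^2))          # periodic variance correction
  x <- t(epochs$data[, ci, , drop = FALSE][, 1, ]) # sample x epoch
  if (n_ep == 1) x <- matrix(epochs$data[1, ci, ], ncol = 1)
  xw <- x * w
  sp <- stats::mvfft(xw)
  nf <- floor(n / 2) + 1
  amp <- (2 / n) * abs(sp[seq_len(nf), , drop = FALSE]) * corr
  amp[1, ] <- amp[1, ] / 2             # DC is not doubled
  mean_amp <- rowMeans(amp)
  freqs <- (seq_len(nf) - 1) * epochs$fs / n
  band <- freqs >= norm_band[1] & freqs <= norm_band[2]
  if (!any(band))
    stop("spectrum grid does not cover the normalization band")
  denom <- if (norm == "sum") sum(mean_amp[band]) else max(mean_amp[band])
  if (denom <= 0) denom <- 1
  structure(list(freqs = freqs, amp = mean_amp / denom,
                 n_epochs_averaged = n_ep, source_channel = channel,
                 norm = norm, norm_band = norm_band),
            class = "rsvp_spectrum")
}

# Tukey (tapered cosine) window; `taper` = total tapered fraction
tukey_window <- function(n, taper) {
  if (taper <= 0) return(rep(1, n))
  w <- rep(1, n)
  edge <- floor(taper * n / 2)
  if (edge > 0) {
    k <- seq_len(edge)
    ramp <- 0.5 * (1 - cos(pi * (k - 1) / edge))
    w[k] <- ramp
    w[n - k + 1] <- ramp
  }
  w
}

#' Estimate the individual alpha frequency (IAF)
#'
#' Searches 7.5-12.5 Hz for the most prominent spectral peak after
#' masking bins within `mask_hw` Hz of the SSVEP harmonics (k x
#' `rate_hz`, k = 1..3).  A qualifying peak must be a local maximum with
#' prominence of at least `min_prom_frac` of its height; the winning
#' frequency is rounded to the nearest 0.5 Hz.  When no qualifying peak
#' exists (e.g. a flat or alpha-free spectrum) the estimate falls back to
#' 10 Hz, mirroring the manual convention for peakless records.
#'
#' @param spectrum An `rsvp_spectrum`.
#' @param rate_hz Presentation rate whose harmonics are masked.
#' @param search_band Search range in Hz (default `c(7.5, 12.5)`).
#' @param mask_hw Half-width of each harmonic mask in Hz (default 0.25).
#' @param min_prom_frac Minimum peak prominence as a fraction of peak
#'   height (default 0.05).
#' @return A list of class `rsvp_iaf`: `iaf_hz`, `method`
#'   (`"detected"`/`"fallback"`), `excluded_freqs`.
#' @export
estimate_iaf <- function(spectrum, rate_hz, search_band = c(7.5, 12.5),
                         mask_hw = 0.25, min_prom_frac = 0.05) {
  stopifnot(inherits(spectrum, "rsvp_spectrum"))
  f <- spectrum$freqs
  if (min(f) > search_band[1] || max(f) < search_band[2])
    stop("spectrum grid does not cover the IAF search band")
  a <- spectrum$amp
  harmonics <- rate_hz * 1:3
  masked <- rep(FALSE, length(f))
  for (h in harmonics) masked <- masked | abs(f - h) <= mask_hw
  aa <- a
  aa[masked] <- NA_real_

  in_band <- which(f >= search_band[1] & f <= search_band[2] & !masked)
  best <- NA_real_
  best_amp <- -Inf
  for (i in in_band) {
    if (i == 1 || i == length(f)) next
    left <- prev_finite(aa, i, -1L)
    right <- prev_finite(aa, i, +1L)
    if (is.na(left) || is.na(right)) next
    if (aa[i] < left || aa[i] < right) next
    prom <- peak_prominence(aa, i)
    if (prom < min_prom_frac * aa[i]) next
    if (aa[i] > best_amp) {
      best_amp <- aa[i]
      best <- f[i]
    }
  }
  if (is.na(best)) {
    structure(list(iaf_hz = 10.0, method = "fallback",
                   excluded_freqs = harmonics), class = "rsvp_iaf")
  } else {
    structure(list(iaf_hz = round(best * 2) / 2, method = "detected",
                   excluded_freqs = harmonics), class = "rsvp_iaf")
  }
}

prev_finite <- function(x, i, step) {
  j <- i + step
  while (j >= 1 && j <= length(x) && is.na(x[j])) j <- j + step
  if (j < 1 || j > length(x)) NA_real_ else x[j]
}

# topographic prominence: height above the higher of the two saddle
# minima separating the peak from the nearest higher ground
peak_prominence <- function(x, i) {
  n <- length(x)
  side_min <- function(step) {
    m <- Inf
    j <- i + step
    while (j >= 1 && j <= n) {
      v <- x[j]
      if (!is.na(v)) {
        if (v > x[i]) return(m)
        m <- min(m, v)
      }
      j <- j + step
    }
    m
  }
  l <- min(side_min(-1L), x[i])
  r <- min(side_min(+1L), x[i])
  x[i] - max(l, r)
}
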