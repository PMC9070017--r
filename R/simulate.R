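#' Default channel montage
#'
#' Ordered labels of the seven-channel dry-electrode montage used for
#' RSVP calibration recordings.
#' @return Character vector.
#' @export
rsvp_channels <- function() {
  c("FCz", "F7", "Pz", "P4", "PO7", "PO8", "Oz")
}

#' Occipitoparietal channel subset pooled in the analyses
#' @return Character vector.
#' @export
posterior_channels <- function() {
  c("Pz", "Oz", "PO7", "PO8")
}

#' Simulation parameters for synthetic RSVP-EEG
#'
#' Returns the reference parameter set for [synthesize_recording()], with
#' any field overridable by name.  Amplitudes are in microvolts, latencies
#' and windows in milliseconds relative to stimulus onset.
#'
#' @param ... Named overrides of the defaults listed below.
#'
#' @details Defaults describe the reference scenario: posterior-dominant
#' alpha at `iaf_true = 10` Hz with amplitude 10 uV and a smooth random
#' envelope; fractional alpha attenuation `erd_depth = 0.5` inside
#' `erd_window = c(300, 800)` ms after each target (raised-cosine 50 ms
#' ramps); Gaussian N200 (negative, 250 ms, posterior) and P300 (positive,
#' 375 ms, Pz-dominant) templates with sigma 25 ms on target epochs only;
#' SSVEP at the presentation rate with 2nd/3rd harmonics at relative
#' amplitudes 0.6/0.4, phase-locked to stimulus onsets and active only
#' during letter sequences; 1/f background noise with RMS 4 uV; blink
#' transients disabled by default (`blink_rate = 0` events/min) so that
#' artifact content is controlled explicitly, either by raising
#' `blink_rate` or via [inject_artifacts()].
#'
#' @return A list of class `rsvp_sim_params`.
#' @export
sim_params <- function(...) {
  p <- list(
    iaf_true = 10,            # Hz, individual alpha frequency of the simulated participant
    alpha_amp = 10,           # uV carrier amplitude of the posterior alpha rhythm
    alpha_env_mod = 0.3,      # fractional depth of the slow random alpha envelope
    erd_depth = 0.5,          # fractional attenuation d of the alpha envelope after targets
    erd_window = c(300, 800), # ms after target onset
    erd_ramp_ms = 50,         # raised-cosine ramp at each edge of erd_window
    n200_amp = 5,             # uV (applied negative)
    p300_amp = 8,             # uV (positive)
    n200_lat = 250,           # ms
    p300_lat = 375,           # ms
    erp_sigma_ms = 25,        # Gaussian template width
    ssvep_amp = 3,            # uV at the fundamental (presentation rate)
    ssvep_harmonics = c(0.6, 0.4),  # relative amplitude of 2nd and 3rd harmonics
    noise_amp = 4,            # uV RMS of the 1/f background
    noise_exponent = 1,       # power ~ 1/f^noise_exponent
    blink_rate = 0,           # events per minute
    blink_amp = 150,          # uV peak, frontal-dominant
    fs = 300,                 # Hz
    channel_gains = c(FCz = 0.2, F7 = 0.1, Pz = 0.8, P4 = 0.6,
                      PO7 = 1, PO8 = 1, Oz = 1),
    erp_gains_n200 = c(FCz = 0.3, F7 = 0.1, Pz = 0.7, P4 = 0.6,
                       PO7 = 1, PO8 = 1, Oz = 0.9),
    erp_gains_p300 = c(FCz = 0.5, F7 = 0.1, Pz = 1, P4 = 0.8,
                       PO7 = 0.6, PO8 = 0.6, Oz = 0.6),
    blink_gains = c(FCz = 0.8, F7 = 1, Pz = 0.1, P4 = 0.1,
                    PO7 = 0.05, PO8 = 0.05, Oz = 0.05),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown sim parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  if (p$erd_depth < 0 || p$erd_depth > 1) stop("`erd_depth` must lie in [0, 1]")
  amps <- c(p$alpha_amp, p$n200_amp, p$p300_amp, p$ssvep_amp,
            p$noise_amp, p$blink_amp)
  if (any(amps < 0)) stop("amplitudes must be >= 0")
  structure(p, class = "rsvp_sim_params")
}

# raised-cosine attenuation profile: 0 outside the window, 1 in its core,
# half-cosine ramps of `ramp` ms at each edge
erd_profile <- function(t_ms, window, ramp) {
  p <- numeric(length(t_ms))
  lo <- window[1]; hi <- window[2]
  core <- t_ms >= lo + ramp & t_ms <= hi - ramp
  up <- t_ms >= lo & t_ms < lo + ramp
  dn <- t_ms > hi - ramp & t_ms <= hi
  p[core] <- 1
  p[up] <- 0.5 * (1 - cos(pi * (t_ms[up] - lo) / ramp))
  p[dn] <- 0.5 * (1 + cos(pi * (t_ms[dn] - (hi - ramp)) / ramp))
  p
}

# 1/f^(exponent/2) amplitude-shaped Gaussian noise, unit RMS
pink_noise <- function(n, exponent) {
  white <- stats::rnorm(n)
  if (exponent == 0) return(white)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))          # avoid division by zero at DC
  f <- pmin(f, n - f + 1)            # mirror for negative frequencies
  shaped <- spec * f^(-exponent / 2)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Synthesize a multichannel RSVP-EEG recording
#'
#' Renders the event timeline of a [make_schedule()] schedule into a
#' continuous 7-channel voltage matrix containing, per [sim_params()]:
#' 1/f background noise; an amplitude-modulated alpha oscillation whose
#' envelope is multiplied by `(1 - erd_depth)` inside `erd_window` after
#' each target (smooth ramps); N200/P300 Gaussian templates on target
#' epochs; SSVEP sinusoids at the presentation rate and its 2nd/3rd
#' harmonics, phase-locked to stimulus onsets; and optional blink
#' transients dominant on frontal channels.  Deterministic given
#' `params$seed`.
#'
#' @param schedule An `rsvp_schedule`.
#' @param params An `rsvp_sim_params` list.
#' @return An object of class `rsvp_recording`: list with `data`
#'   (channel x sample matrix, uV), `fs`, `channels`, and `events`
#'   (data frame with `sample`, `onset_ms`, `class`, `trial`, `position`).
#' @export
synthesize_recording <- function(schedule, params = sim_params()) {
  stopifnot(inherits(schedule, "rsvp_schedule"))
  p <- params
  fs <- p$fs
  top <- 3 * schedule$rate_hz
  if (fs <= 2 * max(p$iaf_true, top))
    stop("sampling rate must exceed twice the highest synthesized frequency")
  channels <- rsvp_channels()
  ev <- schedule$events
  dur_ms <- if (nrow(ev)) max(ev$onset_ms) + 2000 else 2000
  n <- ceiling(dur_ms / 1000 * fs)
  t <- (seq_len(n) - 1) / fs          # seconds
  t_ms <- t * 1000

  set.seed(as.integer(p$seed))

  # --- background 1/f noise, independent per channel ---
  data <- matrix(0, nrow = length(channels), ncol = n,
                 dimnames = list(channels, NULL))
  if (p$noise_amp > 0) {
    for (ci in seq_along(channels))
      data[ci, ] <- p$noise_amp * pink_noise(n, p$noise_exponent)
  }

  # --- alpha rhythm with slow random envelope and post-target attenuation ---
  if (p$alpha_amp > 0) {
    env <- rep(1, n)
    if (p$alpha_env_mod > 0) {
      slow <- stats::filter(stats::rnorm(n), rep(1 / fs, fs), sides = 2)
      slow[is.na(slow)] <- 0
      slow <- as.numeric(slow) / max(stats::sd(slow), 1e-12)
      env <- pmax(1 + p$alpha_env_mod * slow, 0.05)
    }
    if (p$erd_depth > 0 && nrow(ev)) {
      att <- numeric(n)
      for (on in ev$onset_ms[ev$class == "target"]) {
        rel <- t_ms - on
        span <- rel >= p$erd_window[1] - 1 & rel <= p$erd_window[2] + 1
        att[span] <- pmax(att[span],
                          erd_profile(rel[span], p$erd_window, p$erd_ramp_ms))
      }
      env <- env * (1 - p$erd_depth * att)
    }
    phase0 <- stats::runif(1, 0, 2 * pi)
    carrier <- cos(2 * pi * p$iaf_true * t + phase0)
    alpha <- p$alpha_amp * env * carrier
    gains <- p$channel_gains[channels]
    data <- data + outer(as.numeric(gains), alpha)
  }

  # --- ERP templates on target stimuli ---
  if (nrow(ev) && (p$n200_amp > 0 || p$p300_amp > 0)) {
    sig <- p$erp_sigma_ms / 1000
    for (on in ev$onset_ms[ev$class == "target"]) {
      rel <- t - on / 1000
      span <- which(rel > 0 & rel < 0.8)
      if (!length(span)) next
      bump_n <- exp(-((rel[span] - p$n200_lat / 1000)^2) / (2 * sig^2))
      bump_p <- exp(-((rel[span] - p$p300_lat / 1000)^2) / (2 * sig^2))
      contrib <- -p$n200_amp * outer(as.numeric(p$erp_gains_n200[channels]), bump_n) +
        p$p300_amp * outer(as.numeric(p$erp_gains_p300[channels]), bump_p)
      data[, span] <- data[, span] + contrib
    }
  }

  # --- SSVEP: fundamental + 2nd/3rd harmonics, phase-locked to onsets,
  #     active only while a letter sequence is on screen ---
  if (p$ssvep_amp > 0 && nrow(ev)) {
    amps <- p$ssvep_amp * c(1, p$ssvep_harmonics)
    rate <- schedule$rate_hz
    for (tr in unique(ev$trial)) {
      onsets <- ev$onset_ms[ev$trial == tr]
      t0 <- min(onsets) / 1000
      t1 <- max(onsets) / 1000 + 1 / rate
      span <- which(t >= t0 & t < t1)
      if (!length(span)) next
      wave <- numeric(length(span))
      for (h in 1:3)
        wave <- wave + amps[h] * cos(2 * pi * h * rate * (t[span] - t0))
      gains <- p$channel_gains[channels]    # visual response: posterior-dominant
      data[, span] <- data[, span] + outer(as.numeric(gains), wave)
    }
  }

  # --- blink transients: 400 ms biphasic, frontal-dominant ---
  if (p$blink_rate > 0 && p$blink_amp > 0) {
    n_blinks <- stats::rpois(1, p$blink_rate * dur_ms / 60000)
    if (n_blinks > 0) {
      starts <- sort(stats::runif(n_blinks, 0, dur_ms / 1000 - 0.4))
      for (b in starts) {
        rel <- t - b
        span <- which(rel >= 0 & rel < 0.4)
        shape <- numeric(length(span))
        r <- rel[span]
        main <- r < 0.3
        shape[main] <- sin(pi * r[main] / 0.3)^2
        shape[!main] <- -0.25 * sin(pi * (r[!main] - 0.3) / 0.1)^2
        data[, span] <- data[, span] +
          p$blink_amp * outer(as.numeric(p$blink_gains[channels]), shape)
      }
    }
  }

  events <- data.frame(sample = round(ev$onset_ms / 1000 * fs) + 1L,
                       onset_ms = ev$onset_ms, class = ev$class,
                       trial = ev$trial, position = ev$position)
  new_recording(data, fs, channels, events,
                meta = list(rate_hz = schedule$rate_hz, params = p))
}

new_recording <- function(data, fs, channels, events, meta = list()) {
  stopifnot(nrow(data) == length(channels), !anyDuplicated(channels))
  if (nrow(events) && (any(events$sample < 1) || any(events$sample > ncol(data))))
    stop("event sample indices outside data bounds")
  structure(list(data = data, fs = fs, channels = channels,
                 events = events, meta = meta),
            class = "rsvp_recording")
}

#' @export
print.rsvp_recording <- function(x, ...) {
  cat(sprintf("RSVP recording: %d channels x %d samples at %g Hz (%d events)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}

#' Inject known artifact-rule violations into a recording
#'
#' Adds (or, for the low-activity rule, substitutes) contamination at
#' seeded event positions so that the affected stimulus-locked epochs
#' violate chosen rejection rules, returning the modified recording
#' together with the ground-truth list of contaminated events.  Inject
#' after filtering/resampling when the goal is to validate
#' [flag_epochs()] against exact thresholds, since subsequent filtering
#' reshapes the injected waveforms.
#'
#' @param recording An `rsvp_recording`.
#' @param rules Character subset of
#'   `c("gradient", "difference", "absolute", "low_activity")`.
#' @param n_per_rule Events contaminated per rule.
#' @param channel Channel label receiving the contamination.
#' @param seed Integer seed for event selection.
#' @return The recording, with an added `ground_truth` element: data frame
#'   of `event_index` and `rule`.
#' @export
inject_artifacts <- function(recording,
                             rules = c("gradient", "difference",
                                       "absolute", "low_activity"),
                             n_per_rule = 3L, channel = "Pz", seed = 1L) {
  stopifnot(inherits(recording, "rsvp_recording"))
  rules <- match.arg(rules, several.ok = TRUE)
  ev <- recording$events
  fs <- recording$fs
  ci <- match(channel, recording$channels)
  if (is.na(ci)) stop("channel not present: ", channel)
  total <- length(rules) * n_per_rule
  gt <- data.frame(event_index = integer(0), rule = character(0))
  if (total > 0 && nrow(ev) >= total) {
    set.seed(as.integer(seed))
    picked <- sample(nrow(ev), total)
    gt <- data.frame(event_index = picked,
                     rule = rep(rules, each = n_per_rule))
    for (k in seq_len(nrow(gt))) {
      onset <- ev$sample[gt$event_index[k]]
      # place contamination 100 ms after stimulus onset
      i0 <- onset + round(0.1 * fs)
      recording$data[ci, ] <- inject_one(recording$data[ci, ], gt$rule[k],
                                         i0, fs)
    }
  }
  recording$ground_truth <- gt
  recording
}

inject_one <- function(x, rule, i0, fs) {
  n <- length(x)
  idx <- function(len) i0 + seq_len(len) - 1L
  switch(rule,
    gradient = {            # +-250 uV square alternation: huge sample-to-sample jumps
      len <- max(4L, round(0.02 * fs))
      ii <- idx(len); ii <- ii[ii <= n]
      x[ii] <- x[ii] + 250 * rep_len(c(1, -1), length(ii))
    },
    difference = {           # slow swing -70 -> +70 uV within 50 ms, peaks under 75 uV
      len <- round(0.04 * fs)
      ii <- idx(len); ii <- ii[ii <= n]
      x[ii] <- 70 * sin(seq(-pi / 2, pi / 2, length.out = length(ii)))
    },
    absolute = {             # smooth 110 uV bump, gentle slope
      len <- round(0.4 * fs)
      ii <- idx(len); ii <- ii[ii <= n]
      r <- seq(-1, 1, length.out = length(ii))
      x[ii] <- x[ii] + 110 * exp(-r^2 / 0.18)
    },
    low_activity = {         # replace 300 ms with a constant level
      len <- round(0.3 * fs)
      ii <- idx(len); ii <- ii[ii <= n]
      x[ii] <- x[max(1L, i0 - 1L)]
    })
  x
}
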