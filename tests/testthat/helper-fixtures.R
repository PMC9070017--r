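# Shared fixtures, memoized per test run: several test files reuse the
# same simulated calibrations, so build each distinct configuration once.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixtures)) assign(key, build(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# simulate -> filter -> downsample -> pool -> 2.5 s epochs
prep_epochs <- function(rate = 1, n_trials = 30, seed = 5,
                        window = c(-1250, 1250), ...) {
  key <- paste("prep", rate, n_trials, seed, paste(window, collapse = ","),
               paste(utils::capture.output(dput(list(...))), collapse = ""),
               sep = "|")
  memo(key, function() {
    sch <- make_schedule(rate, n_trials, 10, seed)
    rec <- synthesize_recording(sch, sim_params(seed = seed, ...))
    rec <- bandpass_notch(rec)
    rec <- resample_recording(rec, 150)
    rec <- pool_channels(rec)
    epoch_recording(rec, window)
  })
}

# reference-scenario alpha features at the IAF layer (posterior channels)
ref_alpha_features <- function(rate = 1, n_trials = 30, seed = 5) {
  key <- paste("feat", rate, n_trials, seed, sep = "|")
  memo(key, function() {
    ep <- prep_epochs(rate, n_trials, seed)
    iaf <- estimate_iaf(amplitude_spectrum(ep, "POOL"), rate)
    k <- select_iaf_layer(layer_freqs(), iaf$iaf_hz)
    z <- ztransform(cwt_scaleogram(ep, channels = posterior_channels(),
                                   layers = k))
    extract_alpha_features(z, 1)
  })
}

# independent brute-force evaluation of the four rejection rules
brute_rules <- function(x, fs, grad = 50, diff_v = 125, diff_win = 50,
                        abs_v = 75, low_v = 0.5, low_win = 100) {
  n <- length(x)
  r <- character(0)
  dt_ms <- 1000 / fs
  for (i in 2:n)
    if (abs(x[i] - x[i - 1]) / dt_ms > grad) { r <- c(r, "gradient"); break }
  wd <- max(2, round(diff_win / 1000 * fs))
  for (i in 1:(n - wd + 1))
    if (max(x[i:(i + wd - 1)]) - min(x[i:(i + wd - 1)]) > diff_v) {
      r <- c(r, "difference"); break
    }
  if (any(abs(x) > abs_v)) r <- c(r, "absolute")
  wl <- max(2, round(low_win / 1000 * fs))
  for (i in 1:(n - wl + 1))
    if (max(x[i:(i + wl - 1)]) - min(x[i:(i + wl - 1)]) < low_v) {
      r <- c(r, "low_activity"); break
    }
  r
}

new_features_for_test <- function(X, y) {
  rsvpalpha:::new_features(X, y, meta = list(n_channels = 1,
                                             n_samples = ncol(X)))
}

# independent analytic-signal envelope (FFT Hilbert transform); used as
# an oracle against the wavelet path
hilbert_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# hand-built epochs object for synthetic unit tests
make_epochs <- function(data, fs = 150, window = NULL, labels = NULL,
                        channels = NULL) {
  d <- dim(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[2]))
  if (is.null(labels)) labels <- rep("nontarget", d[1])
  if (is.null(window)) window <- c(0, d[3] / fs * 1000)
  dimnames(data) <- list(NULL, channels, NULL)
  structure(list(data = data, window = window, fs = fs, labels = labels,
                 channels = channels,
                 times = window[1] + (seq_len(d[3]) - 1) * 1000 / fs,
                 events = data.frame(sample = seq_len(d[1]),
                                     onset_ms = seq_len(d[1]), class = labels,
                                     trial = seq_len(d[1]),
                                     position = rep(1L, d[1])),
                 dropped = integer(0)),
            class = "rsvp_epochs")
}

# hand-built z-unit scaleogram for classifier/alpha unit tests
make_zscaleogram <- function(data, fs = 150, window = c(-1250, 1250),
                             labels = NULL, channels = NULL,
                             freqs = NULL) {
  d <- dim(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[2]))
  if (is.null(labels)) labels <- rep("nontarget", d[1])
  if (is.null(freqs)) freqs <- layer_freqs()[seq_len(d[3])]
  dimnames(data) <- list(NULL, channels, NULL, NULL)
  structure(list(data = data, layer_freqs = freqs,
                 layer_index = seq_len(d[3]), full_grid = layer_freqs(),
                 units = "zscore", window = window, fs = fs,
                 times = window[1] + (seq_len(d[4]) - 1) * 1000 / fs,
                 labels = labels, channels = channels,
                 baseline_window = c(-600, -100), excluded = integer(0)),
            class = "rsvp_scaleogram")
}
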