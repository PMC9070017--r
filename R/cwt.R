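#' Center frequencies of the wavelet layer grid
#'
#' The default scaleogram uses 48 logarithmically spaced center
#' frequencies from 4 to 16 Hz inclusive:
#' `f_k = 4 * 4^((k - 1)/47)`, `k = 1..48`.
#'
#' @param n_layers Number of layers.
#' @param f_range Length-2 range in Hz.
#' @return Numeric vector of center frequencies.
#' @export
layer_freqs <- function(n_layers = 48, f_range = c(4, 16)) {
  f_range[1] * (f_range[2] / f_range[1])^((seq_len(n_layers) - 1) /
                                            (n_layers - 1))
}

# complex Morlet kernel at center frequency f, parameter c (ratio of
# center frequency to spectral bandwidth), sampled at fs and truncated at
# +-4 sigma_t.  The wavelet family is normalized to unit energy
# (sum |psi|^2 / fs = 1); the returned convolution kernel additionally
# carries a per-layer voltage calibration so that a unit-amplitude
# cosine at the layer's center frequency yields magnitude 1 (uV in, uV
# out).  Without that units conversion the sqrt(sigma_t) amplitude
# factor of unit-energy wavelets tilts tone responses toward lower
# layers, breaking cross-layer peak localization.
morlet_wavelet <- function(f, fs, c = 5, n_sigma = 4) {
  sigma_t <- c / (2 * pi * f)
  half <- round(n_sigma * sigma_t * fs)
  tau <- (-half:half) / fs
  g <- exp(-tau^2 / (2 * sigma_t^2))
  amp <- sqrt(fs / sum(g^2))          # unit-energy scale
  psi <- amp * g * exp(1i * 2 * pi * f * tau)
  psi * 2 / (amp * sum(g))            # voltage calibration of the output
}

#' Continuous wavelet scaleogram of stimulus-locked epochs
#'
#' Convolves every epoch and channel with complex Morlet wavelets
#' (center-frequency/bandwidth parameter `c = 5`) at 48 logarithmically
#' spaced center frequencies spanning 4-16 Hz, each scaled wavelet
#' normalized to unit energy, and stores the complex magnitude (or,
#' optionally, the real part) over the full epoch.  Output is calibrated
#' to input voltage per layer: a unit-amplitude tone at a layer's center
#' frequency produces magnitude 1 at that layer, so the layer whose
#' time-averaged magnitude peaks identifies the tone's frequency.
#'
#' @param epochs An `rsvp_epochs` object.
#' @param channels Channel labels to transform (default: all — restrict
#'   to the analyzed channels to save memory).
#' @param layers Integer indices into the 48-layer grid to compute
#'   (default: all).  Restricting to the IAF layer makes repeated runs
#'   cheap; layer indexing and center frequencies are unchanged.
#' @param n_layers,f_range Layer grid definition (see [layer_freqs()]).
#' @param c Morlet parameter (cycles; spectral bandwidth = f / c).
#' @param output `"magnitude"` (default) or `"real"`.
#' @return A list of class `rsvp_scaleogram`: `data` (epoch x channel x
#'   layer x sample), `layer_freqs` (computed layers), `layer_index`
#'   (their indices in the full grid), `full_grid`, `units`
#'   (`"magnitude_uV"` or `"real_uV"`), plus `window`, `fs`, `times`,
#'   `labels`, `channels` inherited from the epochs.
#' @export
cwt_scaleogram <- function(epochs, channels = NULL, layers = NULL,
                           n_layers = 48, f_range = c(4, 16), c = 5,
                           output = c("magnitude", "real")) {
  stopifnot(inherits(epochs, "rsvp_epochs"))
  output <- match.arg(output)
  grid <- layer_freqs(n_layers, f_range)
  if (is.null(layers)) layers <- seq_len(n_layers)
  stopifnot(all(layers >= 1 & layers <= n_layers))
  if (is.null(channels)) channels <- epochs$channels
  ci <- match(channels, epochs$channels)
  if (anyNA(ci)) stop("channel(s) not present: ",
                      paste(channels[is.na(ci)], collapse = ", "))
  fs <- epochs$fs
  n_ep <- dim(epochs$data)[1]
  n_s <- dim(epochs$data)[3]
  f_min <- min(grid[layers])
  m_max <- 2 * round(4 * (c / (2 * pi * f_min)) * fs) + 1
  if (n_s < m_max)
    stop(sprintf(paste0("epochs too short for the %.2f Hz layer: need at ",
                        "least %d samples (%.0f ms), got %d"),
                 f_min, m_max, m_max / fs * 1000, n_s))
  nfft <- 2^ceiling(log2(n_s + m_max - 1))

  # batch all (epoch, channel) series as columns of one matrix
  x <- matrix(0, nrow = nfft, ncol = n_ep * length(ci))
  for (j in seq_along(ci))
    x[seq_len(n_s), (j - 1) * n_ep + seq_len(n_ep)] <-
      t(matrix(epochs$data[, ci[j], ], nrow = n_ep))
  fx <- stats::mvfft(x)

  out <- array(0, dim = c(n_ep, length(ci), length(layers), n_s),
               dimnames = list(NULL, channels, NULL, NULL))
  for (k in seq_along(layers)) {
    f <- grid[layers[k]]
    w <- morlet_wavelet(f, fs, c)
    m0 <- (length(w) + 1) / 2
    fw <- stats::fft(c(w, rep(0, nfft - length(w))))
    y <- stats::mvfft(fx * fw, inverse = TRUE) / nfft
    seg <- y[m0:(m0 + n_s - 1), , drop = FALSE]
    vals <- if (output == "magnitude") Mod(seg) else Re(seg)
    for (j in seq_along(ci))
      out[, j, k, ] <- t(vals[, (j - 1) * n_ep + seq_len(n_ep)])
  }
  structure(list(data = out, layer_freqs = grid[layers],
                 layer_index = layers, full_grid = grid,
                 units = if (output == "magnitude") "magnitude_uV" else "real_uV",
                 window = epochs$window, fs = fs, times = epochs$times,
                 labels = epochs$labels, channels = channels,
                 morlet_c = c),
            class = "rsvp_scaleogram")
}

#' @export
print.rsvp_scaleogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "RSVP scaleogram: %d epochs x %d channels x %d layers x %d samples (%s)\n",
    d[1], d[2], d[3], d[4], x$units))
  invisible(x)
}
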