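#' Baseline Z-transform of a scaleogram
#'
#' Standardizes every sample of each (epoch, channel, layer) series
#' against the mean and standard deviation of that epoch's own baseline
#' window (default -600 to -100 ms before stimulus onset):
#' `z[t] = (x[t] - mu_b) / sd_b`.  Epochs with a zero baseline standard
#' deviation in any transformed series are flagged degenerate, excluded,
#' and listed in `excluded`.
#'
#' @param scaleogram An `rsvp_scaleogram` in voltage-magnitude units.
#' @param baseline_window Length-2 ms window relative to stimulus onset
#'   (half-open, like all sample windows in this package).
#' @return The Z-scored `rsvp_scaleogram` (units `"zscore"`) with
#'   `baseline_window` and `excluded` elements.
#' @export
ztransform <- function(scaleogram, baseline_window = c(-600, -100)) {
  stopifnot(inherits(scaleogram, "rsvp_scaleogram"))
  if (scaleogram$units == "zscore")
    stop("scaleogram is already Z-transformed")
  tms <- scaleogram$times
  bidx <- which(tms >= baseline_window[1] & tms < baseline_window[2])
  if (length(bidx) < 2)
    stop("baseline window must contain at least two samples inside the epoch")
  d <- dim(scaleogram$data)
  m <- scaleogram$data
  dim(m) <- c(d[1] * d[2] * d[3], d[4])
  mb <- m[, bidx, drop = FALSE]
  mu <- rowMeans(mb)
  sd_b <- sqrt(rowSums((mb - mu)^2) / (length(bidx) - 1))
  degen <- sd_b <= 0
  excluded <- integer(0)
  if (any(degen)) {
    # map flat rows back to epoch indices (epoch varies fastest)
    excluded <- sort(unique(((which(degen) - 1) %% d[1]) + 1))
    message(sprintf("ztransform: excluded %d degenerate epoch(s): %s",
                    length(excluded), paste(excluded, collapse = ", ")))
    sd_b[degen] <- 1           # placeholder; rows are dropped below
  }
  z <- (m - mu) / sd_b
  dim(z) <- d
  dimnames(z) <- dimnames(scaleogram$data)
  scaleogram$data <- z
  scaleogram$units <- "zscore"
  scaleogram$baseline_window <- baseline_window
  scaleogram$excluded <- excluded
  if (length(excluded)) {
    keep <- setdiff(seq_len(d[1]), excluded)
    scaleogram$data <- scaleogram$data[keep, , , , drop = FALSE]
    scaleogram$labels <- scaleogram$labels[keep]
  }
  scaleogram
}

#' Select the wavelet layer closest to the individual alpha frequency
#'
#' @param scaleogram An `rsvp_scaleogram` (any units).
#' @param iaf IAF in Hz (within the layer grid range).
#' @return Integer index into the scaleogram's layers whose center
#'   frequency is nearest `iaf`; exact ties resolve to the lower
#'   frequency.
#' @export
select_iaf_layer <- function(scaleogram, iaf) {
  f <- if (inherits(scaleogram, "rsvp_scaleogram")) scaleogram$layer_freqs
       else scaleogram
  if (iaf < min(f) - 1e-9 || iaf > max(f) + 1e-9)
    stop("`iaf` outside the layer frequency range")
  which.min(abs(f - iaf))          # which.min takes the first (lower) on ties
}

#' Alpha activity and the alpha attenuation effect
#'
#' For each epoch, averages the Z-scored values of the chosen wavelet
#' layer and source channel within the response window (default 300-800
#' ms post-stimulus).  Reports per-class medians, the alpha attenuation
#' effect (target median minus non-target median; negative values mean
#' target-related desynchronization), and a two-sided Mann-Whitney U test
#' of target vs non-target per-epoch alpha.
#'
#' @param scaleogram_z A Z-scored `rsvp_scaleogram`.
#' @param layer Layer index within the scaleogram (see
#'   [select_iaf_layer()]).
#' @param response_window Length-2 ms window (half-open).
#' @param source Source channel label (`"POOL"` or `"Pz"` in the primary
#'   analyses).
#' @return A list of class `rsvp_alpha_measures`: `per_epoch` (data frame
#'   epoch, class, z_mean), `class_medians`, `attenuation`, `mwu`
#'   (a `TestResult` from [independent_test()]), `baseline_window`,
#'   `response_window`, `source`, `layer_freq`.
#' @export
alpha_activity <- function(scaleogram_z, layer, response_window = c(300, 800),
                           source = "POOL") {
  stopifnot(inherits(scaleogram_z, "rsvp_scaleogram"))
  if (scaleogram_z$units != "zscore")
    stop("scaleogram must be Z-transformed first")
  ci <- match(source, scaleogram_z$channels)
  if (is.na(ci)) stop("source channel not present: ", source)
  stopifnot(layer >= 1, layer <= dim(scaleogram_z$data)[3])
  tms <- scaleogram_z$times
  ridx <- which(tms >= response_window[1] & tms < response_window[2])
  if (!length(ridx)) stop("response window outside the epoch")
  z <- scaleogram_z$data[, ci, layer, ridx, drop = FALSE]
  per <- rowMeans(matrix(z, nrow = dim(scaleogram_z$data)[1]))
  labels <- scaleogram_z$labels
  if (!all(c("target", "nontarget") %in% labels))
    stop("both classes must be present to measure attenuation")
  med <- c(target = stats::median(per[labels == "target"]),
           nontarget = stats::median(per[labels == "nontarget"]))
  mwu <- independent_test(per[labels == "target"],
                          per[labels == "nontarget"])
  structure(list(per_epoch = data.frame(epoch = seq_along(per),
                                        class = labels, z_mean = per),
                 class_medians = med,
                 attenuation = unname(med["target"] - med["nontarget"]),
                 mwu = mwu, mwu_p = mwu$p_two_sided,
                 baseline_window = scaleogram_z$baseline_window,
                 response_window = response_window, source = source,
                 layer_freq = scaleogram_z$layer_freqs[layer]),
            class = "rsvp_alpha_measures")
}

#' @export
print.rsvp_alpha_measures <- function(x, ...) {
  cat(sprintf(
    "Alpha activity (%s, %.2f Hz layer): target Mdn = %.3f, non-target Mdn = %.3f\n",
    x$source, x$layer_freq, x$class_medians["target"],
    x$class_medians["nontarget"]))
  cat(sprintf("  attenuation = %.3f, Mann-Whitney p = %.4g\n",
              x$attenuation, x$mwu_p))
  invisible(x)
}

#' Estimate the injected alpha-attenuation depth
#'
#' Recovers the fractional envelope attenuation d from a
#' magnitude-domain scaleogram as `1 - mean(target) / mean(non-target)`
#' of the epoch-mean wavelet magnitude at the chosen layer, measured over
#' an interior window (default 400-700 ms) that avoids the attenuation
#' ramps and wavelet temporal smoothing at the window edges.
#'
#' @param scaleogram An `rsvp_scaleogram` in magnitude units.
#' @param layer Layer index.
#' @param window Measurement window (ms).
#' @param source Source channel.
#' @return Estimated depth (scalar).
#' @export
estimate_erd_depth <- function(scaleogram, layer, window = c(400, 700),
                               source = "POOL") {
  stopifnot(inherits(scaleogram, "rsvp_scaleogram"))
  if (scaleogram$units == "zscore")
    stop("depth estimation needs magnitude units, not z-scores")
  ci <- match(source, scaleogram$channels)
  if (is.na(ci)) stop("source channel not present: ", source)
  ridx <- which(scaleogram$times >= window[1] & scaleogram$times < window[2])
  m <- rowMeans(matrix(scaleogram$data[, ci, layer, ridx, drop = FALSE],
                       nrow = dim(scaleogram$data)[1]))
  labels <- scaleogram$labels
  1 - mean(m[labels == "target"]) / mean(m[labels == "nontarget"])
}
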