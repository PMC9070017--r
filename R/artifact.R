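#' Flag epochs violating artifact-rejection rules
#'
#' Deterministic implementation of the four threshold rules used for
#' semi-automatic epoch review: (a) voltage gradients above
#' `grad_uv_ms` uV/ms between consecutive samples; (b) voltage
#' differences above `diff_uv` uV within any sliding window of
#' `diff_win_ms`; (c) absolute voltage above `abs_uv` anywhere; and
#' (d) activity below `low_uv` (max minus min) sustained for at least
#' `low_win_ms`.  An epoch is flagged if any checked channel violates any
#' rule.  Sliding windows step one sample; window lengths are rounded to
#' the nearest sample count.
#'
#' @param epochs An `rsvp_epochs` object (raw filtered voltage, no
#'   baseline correction).
#' @param channels Channel labels to check (default: all).
#' @param grad_uv_ms,diff_uv,diff_win_ms,abs_uv,low_uv,low_win_ms Rule
#'   thresholds; defaults are 50 uV/ms, 125 uV in 50 ms, 75 uV, and
#'   0.5 uV over 100 ms.
#' @return A list of class `rsvp_rejection`: `keep_mask` (logical per
#'   epoch), `reasons` (list of character vectors per epoch),
#'   `retention` (kept fraction per class), and a `table` data frame
#'   (epoch, label, kept, reasons).
#' @export
flag_epochs <- function(epochs, channels = NULL,
                        grad_uv_ms = 50, diff_uv = 125, diff_win_ms = 50,
                        abs_uv = 75, low_uv = 0.5, low_win_ms = 100) {
  stopifnot(inherits(epochs, "rsvp_epochs"))
  fs <- epochs$fs
  if (is.null(fs) || is.na(fs)) stop("sampling rate missing from epochs")
  if (is.null(channels)) channels <- epochs$channels
  ci <- match(channels, epochs$channels)
  if (anyNA(ci)) stop("channel(s) not present: ",
                      paste(channels[is.na(ci)], collapse = ", "))
  n_ep <- dim(epochs$data)[1]
  win_d <- max(2L, round(diff_win_ms / 1000 * fs))
  win_l <- max(2L, round(low_win_ms / 1000 * fs))
  reasons <- vector("list", n_ep)
  for (e in seq_len(n_ep)) {
    r <- character(0)
    for (c0 in ci) {
      x <- epochs$data[e, c0, ]
      if (!("gradient" %in% r) &&
          any(abs(diff(x)) * fs / 1000 > grad_uv_ms)) r <- c(r, "gradient")
      if (!("difference" %in% r) &&
          max(roll_range(x, win_d)) > diff_uv) r <- c(r, "difference")
      if (!("absolute" %in% r) && any(abs(x) > abs_uv)) r <- c(r, "absolute")
      if (!("low_activity" %in% r) &&
          min(roll_range(x, win_l)) < low_uv) r <- c(r, "low_activity")
      if (length(r) == 4L) break
    }
    reasons[[e]] <- r
  }
  keep <- lengths(reasons) == 0L
  retention <- tapply(keep, epochs$labels, mean)
  tab <- data.frame(epoch = seq_len(n_ep), label = epochs$labels,
                    kept = keep,
                    reasons = vapply(reasons, paste, "", collapse = ";"))
  structure(list(keep_mask = keep, reasons = reasons,
                 retention = retention, table = tab,
                 thresholds = c(grad_uv_ms = grad_uv_ms, diff_uv = diff_uv,
                                diff_win_ms = diff_win_ms, abs_uv = abs_uv,
                                low_uv = low_uv, low_win_ms = low_win_ms)),
            class = "rsvp_rejection")
}

# range (max - min) over every sliding window of `w` samples
roll_range <- function(x, w) {
  n <- length(x)
  if (w >= n) return(max(x) - min(x))
  mx <- roll_extreme(x, w, max)
  mn <- roll_extreme(x, w, min)
  mx - mn
}

# vectorized running extreme: reduce over the w shifted copies
roll_extreme <- function(x, w, fun) {
  n <- length(x)
  m <- n - w + 1
  pfun <- if (identical(fun, max)) pmax else pmin
  out <- x[seq_len(m)]
  for (k in seq_len(w - 1)) out <- pfun(out, x[(1 + k):(m + k)])
  out
}

#' @export
print.rsvp_rejection <- function(x, ...) {
  cat(sprintf("Artifact rejection: %d/%d epochs kept\n",
              sum(x$keep_mask), length(x$keep_mask)))
  invisible(x)
}
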