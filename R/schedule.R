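#' RSVP stimulus alphabet
#'
#' The 28-character stimulus set used by the RSVP speller calibration:
#' the 26 capital letters plus `"_"` (space) and `"<"` (backspace).
#'
#' @return Character vector of length 28.
#' @export
rsvp_alphabet <- function() {
  c(LETTERS, "_", "<")
}

#' Generate an RSVP calibration stimulus schedule
#'
#' Builds the event timeline of one calibration block.  Each trial consists
#' of a 1 s target-letter prompt, a 500 ms fixation cross, a steady stream
#' of `seq_len` letter stimuli at `rate_hz`, and a 750 ms blank gap before
#' the next trial.  Exactly one stimulus per trial is the target, at a
#' position drawn uniformly from `1:seq_len`.
#'
#' @param rate_hz Presentation rate in Hz (the calibration uses 1 or 4).
#' @param n_trials Number of trials (sequences); the calibration uses 100.
#' @param seq_len Stimuli per sequence; the calibration uses 10.
#' @param seed Integer seed for the target-position draw.
#' @param prompt_ms,fixation_ms,inter_sequence_ms Segment durations (ms).
#'
#' @return An object of class `rsvp_schedule`: a list with the timing
#'   parameters and `events`, a data frame with one row per stimulus and
#'   columns `onset_ms`, `class` (`"target"`/`"nontarget"`), `trial`,
#'   `position`.
#' @export
make_schedule <- function(rate_hz, n_trials, seq_len, seed = 1L,
                          prompt_ms = 1000, fixation_ms = 500,
                          inter_sequence_ms = 750) {
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("`rate_hz` must be a positive scalar")
  if (!is.numeric(seq_len) || seq_len < 1)
    stop("`seq_len` must be >= 1")
  if (!is.numeric(n_trials) || n_trials < 0)
    stop("`n_trials` must be >= 0")
  n_trials <- as.integer(n_trials)
  sl <- as.integer(seq_len)
  soa_ms <- 1000 / rate_hz

  if (n_trials == 0L) {
    events <- data.frame(onset_ms = numeric(0), class = character(0),
                         trial = integer(0), position = integer(0))
  } else {
    set.seed(as.integer(seed))
    target_pos <- sample.int(sl, n_trials, replace = TRUE)
    trial_dur <- prompt_ms + fixation_ms + sl * soa_ms + inter_sequence_ms
    trial_start <- (seq_len(n_trials) - 1L) * trial_dur
    onset <- rep(trial_start, each = sl) + prompt_ms + fixation_ms +
      (rep(seq_len(sl), n_trials) - 1L) * soa_ms
    pos <- rep(seq_len(sl), n_trials)
    trial <- rep(seq_len(n_trials), each = sl)
    cls <- ifelse(pos == target_pos[trial], "target", "nontarget")
    events <- data.frame(onset_ms = onset, class = cls,
                         trial = trial, position = pos)
  }

  structure(list(rate_hz = rate_hz, n_trials = n_trials, seq_len = sl,
                 prompt_ms = prompt_ms, fixation_ms = fixation_ms,
                 inter_sequence_ms = inter_sequence_ms, soa_ms = soa_ms,
                 seed = as.integer(seed), events = events),
            class = "rsvp_schedule")
}

#' @export
print.rsvp_schedule <- function(x, ...) {
  cat(sprintf("RSVP schedule: %d trials x %d stimuli at %g Hz (%d events)\n",
              x$n_trials, x$seq_len, x$rate_hz, nrow(x$events)))
  invisible(x)
}
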