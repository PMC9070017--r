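# Minimal EDF (European Data Format) I/O for continuous recordings:
# 16-bit samples, identical sampling rate across signals, 1 s data
# records.  Event markers travel in a sidecar CSV (see
# write_events_csv()), as annotations are out of scope for classic EDF.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Stores the voltage matrix as classic EDF with 16-bit samples in
#' physical units of uV and a record duration of 1 s.  The final partial
#' record is zero-padded; [read_edf()] restores the original length via
#' the `n_samples` entry echoed in the reserved header field.
#'
#' @param recording An `rsvp_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "rsvp_recording"))
  data <- recording$data
  fs <- recording$fs
  ns <- nrow(data)
  n <- ncol(data)
  n_rec <- ceiling(n / fs)
  # round the physical range up to the 2-decimal header precision so the
  # writer's scale and the reader's reconstructed gain agree exactly
  pmax_ <- ceiling(max(abs(range(data)), 1) * 100) / 100
  dig_max <- 32767L
  scale <- dig_max / pmax_

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256 + 256 * ns
  writeChar(paste0(
    pad_field("0", 8), pad_field("synthetic RSVP-EEG", 80),
    pad_field("rsvpalpha simulation", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(hdr_bytes, 8), pad_field(paste0("n_samples=", n), 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4)),
    con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, pad_field, "", width = width),
                    collapse = ""), con, eos = NULL)
  field(recording$channels, 16)
  field(rep("simulated", ns), 80)
  field(rep("uV", ns), 8)
  field(rep(sprintf("%.2f", -pmax_), ns), 8)
  field(rep(sprintf("%.2f", pmax_), ns), 8)
  # symmetric digital range so the affine reconstruction has no offset
  field(rep(-dig_max, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("BP:1-45Hz sim", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  padded <- matrix(0, ns, n_rec * fs)
  padded[, seq_len(n)] <- data
  dig <- matrix(as.integer(round(padded * scale)), ns)
  for (r in seq_len(n_rec)) {
    block <- dig[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Parses a classic EDF header (equal per-signal sampling rates
#' required) and reconstructs the physical-unit voltage matrix.
#'
#' @param path EDF file path.
#' @return An `rsvp_recording` (without events; see
#'   [read_events_csv()]).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                             # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  sig <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- sig(16); sig(80); sig(8)
  pmin_ <- as.numeric(sig(8)); pmax_ <- as.numeric(sig(8))
  dmin <- as.numeric(sig(8)); dmax <- as.numeric(sig(8))
  sig(80)
  spr <- as.integer(sig(8))
  sig(32)
  if (length(unique(spr)) != 1)
    stop("read_edf supports equal sampling rates only")
  fs <- spr[1] / dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, integer(), n = ns * spr[1], size = 2,
                     endian = "little")
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      matrix(block, nrow = spr[1])[, seq_len(ns)] |> t()
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- data * gain + (pmin_ - dmin * gain)
  n_true <- suppressWarnings(
    as.integer(sub("n_samples=", "", reserved)))
  if (!is.na(n_true) && n_true <= ncol(data))
    data <- data[, seq_len(n_true), drop = FALSE]
  new_recording(data, fs, labels,
                data.frame(sample = integer(0), onset_ms = numeric(0),
                           class = character(0), trial = integer(0),
                           position = integer(0)))
}

#' Write the stimulus event table as CSV
#'
#' Columns: `onset_sample`, `onset_ms`, `class`, `trial`, `position`.
#'
#' @param recording An `rsvp_recording` with events.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(recording, path) {
  ev <- recording$events
  out <- data.frame(onset_sample = ev$sample, onset_ms = ev$onset_ms,
                    class = ev$class, trial = ev$trial,
                    position = ev$position)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a stimulus event CSV into a recording
#'
#' @param recording An `rsvp_recording` (e.g. from [read_edf()]).
#' @param path CSV path written by [write_events_csv()].
#' @return The recording with its `events` table populated.
#' @export
read_events_csv <- function(recording, path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  recording$events <- data.frame(sample = as.integer(ev$onset_sample),
                                 onset_ms = ev$onset_ms, class = ev$class,
                                 trial = ev$trial, position = ev$position)
  recording
}
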