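# Minimal EDF/EDF+ reader and writer (16-bit integer samples, continuous
# recordings, annotations ignored). Covers the subset of the format used by
# public resting-state EEG repositories; written here because no EDF reader
# is available among the package's dependencies.

edf_pad <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are scaled to the 16-bit integer range per channel; quantization
#' error is bounded by (physical range)/2^16.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @param record_seconds duration of one EDF data record (the recording is
#'   truncated to a whole number of records).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_seconds = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  spr <- round(record_seconds * rec$fs) # samples per record per channel
  n_rec <- ncol(rec$data) %/% spr
  if (n_rec < 1) stop_invalid_argument("recording shorter than one EDF record")
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad(rec$condition_label, 80),
    "01.01.0001.01.01", # start date/time (unused)
    edf_pad(256 + ns * 256, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(format(record_seconds), 8),
    edf_pad(ns, 4)
  ), con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""), con, eos = NULL)
  }
  field(rec$channel_labels, 16)
  field(rep("", ns), 80) # transducer
  field(rep("uV", ns), 8)
  field(formatC(phys_min, format = "g", digits = 6), 8)
  field(formatC(phys_max, format = "g", digits = 6), 8)
  field(rep(-32768, ns), 8)
  field(rep(32767, ns), 8)
  field(rep("", ns), 80) # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32) # reserved
  scale <- (phys_max - phys_min) / 65535
  for (r in seq_len(n_rec)) {
    block <- rec$data[, ((r - 1) * spr + 1):(r * spr), drop = FALSE]
    dig <- round((block - phys_min) / scale) - 32768
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF/EDF+ file
#'
#' Reads header and signal data, rescaling digital samples to physical units.
#' All channels must share one sampling rate; annotation channels are
#' dropped. A file whose data section is shorter than the header promises is
#' rejected rather than returned partially.
#'
#' @param path path to an EDF file.
#' @param subject_id,condition_label optional overrides for the recording
#'   metadata (defaults taken from the header).
#' @return an `eeg_recording` with `domain = "sensor"`.
#' @export
read_edf <- function(path, subject_id = NULL, condition_label = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path), "format_error")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    x <- readChar(con, n, useBytes = TRUE)
    if (length(x) == 0 || nchar(x, type = "bytes") < n) {
      abort("truncated EDF header", "format_error")
    }
    trimws(x)
  }
  rd(8) # version
  patient <- rd(80)
  recording_field <- rd(80)
  rd(16) # start date/time
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(header_bytes, n_rec, rec_dur, ns)) || ns < 1 || n_rec < 0) {
    abort("malformed EDF header", "format_error")
  }
  fields <- function(width, cast = identity) {
    vapply(seq_len(ns), function(i) cast(rd(width)), cast(""))
  }
  labels <- fields(16)
  fields(80)
  fields(8) # units
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr))) {
    abort("malformed EDF signal headers", "format_error")
  }
  keep <- !grepl("EDF Annotations", labels, fixed = TRUE)
  if (length(unique(spr[keep])) != 1) {
    abort("channels with differing sampling rates are not supported", "format_error")
  }
  total_int16 <- sum(spr) * n_rec
  raw <- readBin(con, integer(), n = total_int16, size = 2, endian = "little")
  if (length(raw) < total_int16) {
    abort("EDF data section shorter than header promises", "format_error")
  }
  data <- matrix(0, sum(keep), spr[keep][1] * n_rec)
  offs <- c(0, cumsum(spr))
  row <- 0L
  for (i in seq_len(ns)) {
    if (!keep[i]) next
    row <- row + 1L
    idx <- as.vector(outer(seq_len(spr[i]), (seq_len(n_rec) - 1) * sum(spr), `+`)) + offs[i]
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    data[row, ] <- (raw[idx] - dig_min[i]) * gain + phys_min[i]
  }
  fs <- spr[keep][1] / rec_dur
  new_recording(data, fs,
    channel_labels = labels[keep],
    subject_id = if (is.null(subject_id)) patient else subject_id,
    condition_label = if (is.null(condition_label)) recording_field else condition_label,
    domain = "sensor"
  )
}
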