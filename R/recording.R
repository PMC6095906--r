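# Recording and epoch-set containers shared by every stage of the pipeline.

#' Construct a multichannel recording
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling frequency in Hz.
#' @param channel_labels character vector, one per channel.
#' @param subject_id subject identifier.
#' @param condition_label condition tag (e.g. `"EC"`, `"EO"`).
#' @param domain one of `"sensor"`, `"source"`, `"roi"`.
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, channel_labels = NULL, subject_id = "S001",
                          condition_label = "EC",
                          domain = c("sensor", "source", "roi")) {
  domain <- match.arg(domain)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_invalid_argument("`data` must be a numeric channels x samples matrix")
  }
  check_finite(data, "data")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_invalid_argument("`fs` must be a positive sampling rate in Hz")
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("%s_%03d", switch(domain,
      sensor = "ch", source = "src", roi = "roi"
    ), seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop_invalid_argument("channel_labels length must match channel count")
  }
  structure(
    list(
      data = data, fs = fs, channel_labels = as.character(channel_labels),
      subject_id = subject_id, condition_label = condition_label, domain = domain
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s/%s [%s] %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$condition_label, x$domain, nrow(x$data), ncol(x$data),
    x$fs, ncol(x$data) / x$fs
  ))
  invisible(x)
}

# epochs are stored channels x samples x epoch so that one epoch is a
# contiguous slice
new_epoch_set <- function(epochs, fs, band = NULL, domain = "sensor",
                          channel_labels = NULL, subject_id = "S001",
                          condition_label = "EC") {
  stopifnot(is.array(epochs), length(dim(epochs)) == 3L)
  structure(
    list(
      epochs = epochs, fs = fs, band = band, domain = domain,
      channel_labels = channel_labels, subject_id = subject_id,
      condition_label = condition_label
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  band <- if (is.null(x$band)) "broadband" else sprintf("%g-%g Hz", x$band[1], x$band[2])
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples [%s, %s] @ %g Hz\n",
    d[3], d[1], d[2], x$domain, band, x$fs
  ))
  invisible(x)
}

# Extract epoch e as a channels x samples matrix (contiguous slice).
epoch_matrix <- function(es, e) {
  es$epochs[, , e]
}

n_epochs <- function(es) dim(es$epochs)[3L]
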