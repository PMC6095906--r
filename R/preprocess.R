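# Preprocessing applied identically to sensor and source/ROI series:
# common average reference, zero-phase FIR filtering, epoch segmentation.

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so the
#' channel mean is zero at each sample. Source- and ROI-domain recordings pass
#' through unchanged (re-referencing is a sensor-space concept).
#'
#' @param rec an `eeg_recording`.
#' @return the re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$domain != "sensor") return(rec)
  check_finite(rec$data, "data")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

# Windowed-sinc (Hamming) FIR coefficients for band-pass or band-stop. Order
# follows the common EEG-toolbox rule 3 * fs / low_edge, rounded up to even so
# the kernel has odd length and an integer group delay.
design_fir <- function(fs, low, high, type = c("pass", "stop"), order = NULL) {
  type <- match.arg(type)
  if (!(0 < low && low < high && high < fs / 2)) {
    stop_invalid_argument("band edges must satisfy 0 < low < high < fs/2")
  }
  if (is.null(order)) order <- 2 * ceiling(3 * fs / low / 2)
  w <- c(low, high) / (fs / 2)
  signal::fir1(order, w, type = type)
}

#' Zero-phase FIR band-pass (and optional notch) filter
#'
#' Windowed-sinc Hamming FIR filtering applied without phase distortion:
#' forward-backward application is folded into a single centred convolution
#' with the autocorrelation of the FIR kernel (identical impulse response,
#' exactly linear, output length equals input length; edges are zero-padded).
#' Undistorted phase matters because the phase-based connectivity metrics
#' (PLV, PLI) consume the filtered signal's instantaneous phase.
#'
#' @param rec an `eeg_recording`.
#' @param low,high band edges in Hz (`0 < low < high < fs/2`).
#' @param notch optional line frequency in Hz; a band-stop of
#'   `notch_halfwidth` Hz half-width is applied after the band-pass.
#' @param order band-pass FIR order; defaults to `3 * fs / low` rounded up to
#'   even.
#' @param notch_halfwidth half-width of the notch stop band (Hz).
#' @return the filtered recording, with the band stored as attribute `"band"`.
#' @export
bandpass_filter <- function(rec, low, high, notch = NULL, order = NULL,
                            notch_halfwidth = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  b <- design_fir(rec$fs, low, high, "pass", order)
  rec$data <- zero_phase_apply(rec$data, b)
  if (!is.null(notch)) {
    if (!(notch - notch_halfwidth > 0 && notch + notch_halfwidth < rec$fs / 2)) {
      stop_invalid_argument("notch band must lie inside (0, fs/2)")
    }
    bn <- design_fir(rec$fs, notch - notch_halfwidth, notch + notch_halfwidth,
      "stop",
      order = 2 * ceiling(0.75 * rec$fs)
    )
    rec$data <- zero_phase_apply(rec$data, bn)
  }
  attr(rec, "band") <- c(low, high)
  rec
}

# Forward-backward FIR == centred convolution with g = conv(b, rev(b)), a
# symmetric (zero-phase) kernel, evaluated by FFT convolution with zero-padded
# edges (identical to direct convolution of the zero-padded signal).
zero_phase_apply <- function(x, b) {
  g <- stats::convolve(b, b, type = "open") # b * rev(b), length 2L-1, symmetric
  fir_zero_phase(x, g)
}

#' Segment a recording into fixed-length non-overlapping epochs
#'
#' Cuts `floor(duration / epoch_seconds)` contiguous epochs from the start of
#' the recording; any trailing remainder is discarded.
#'
#' @param rec an `eeg_recording`.
#' @param epoch_seconds epoch length in seconds.
#' @return an `epoch_set` (epochs x channels x samples).
#' @export
segment_epochs <- function(rec, epoch_seconds = 12) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(epoch_seconds * rec$fs)
  n_samp <- ncol(rec$data)
  if (len > n_samp) stop_invalid_argument("epoch longer than the recording")
  n_ep <- n_samp %/% len
  epochs <- rec$data[, seq_len(n_ep * len), drop = FALSE]
  dim(epochs) <- c(nrow(rec$data), len, n_ep)
  new_epoch_set(epochs, rec$fs,
    band = attr(rec, "band"), domain = rec$domain,
    channel_labels = rec$channel_labels, subject_id = rec$subject_id,
    condition_label = rec$condition_label
  )
}
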