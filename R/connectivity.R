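# Functional connectivity estimators on band-limited multichannel epochs.
#
# Four metrics spanning the two coupling families and the two sensitivities
# to instantaneous mixing:
#   PLV  - phase locking value, sensitive to zero-lag (volume-conducted) phase
#          consistency.
#   PLI  - phase lag index, blind to symmetric / zero-lag phase differences.
#   AEC  - amplitude envelope correlation (raw envelopes).
#   AEC_corrected - AEC after multivariate symmetric orthogonalization, which
#          removes shared zero-lag components (signal leakage) first.

#' Analytic signal decomposition (Hilbert transform)
#'
#' Per channel, the FFT-based analytic signal: `envelope` is its magnitude and
#' `phase` its angle. Channels that are identically zero carry no phase and
#' are flagged rather than propagated as NaN.
#'
#' @param epoch numeric matrix, channels x samples, already band-limited.
#' @param fs sampling frequency in Hz.
#' @return object of class `analytic_decomposition` with fields `phase`
#'   (radians in (-pi, pi]), `envelope` (>= 0), `flagged` (logical per
#'   channel), `fs`.
#' @export
analytic_signal <- function(epoch, fs) {
  if (!is.matrix(epoch)) epoch <- rbind(epoch)
  check_finite(epoch, "epoch")
  z <- t(analytic_cols(epoch))
  flagged <- apply(epoch, 1, function(r) all(r == 0))
  structure(
    list(phase = Arg(z), envelope = Mod(z), flagged = flagged, fs = fs),
    class = "analytic_decomposition"
  )
}

check_pair <- function(a, b) {
  if (length(a) != length(b)) stop_invalid_argument("series must have equal length")
  if (length(a) < 2) stop_invalid_argument("series too short")
}

#' Phase locking value of two phase series
#'
#' Modulus of the sample mean unit phasor of the phase difference; 1 for a
#' perfectly consistent (including zero-lag) phase relation.
#'
#' @param phase_a,phase_b instantaneous phase series in radians.
#' @return PLV in [0, 1].
#' @export
plv <- function(phase_a, phase_b) {
  check_pair(phase_a, phase_b)
  Mod(mean(exp(1i * (phase_a - phase_b))))
}

#' Phase lag index of two phase series
#'
#' Absolute mean sign of `sin(phase_a - phase_b)`: the asymmetry of the
#' phase-difference distribution around zero. Exactly zero-lag (and exactly
#' anti-phase) samples contribute 0 to the sign sum, so purely instantaneous
#' mixing yields PLI 0.
#'
#' @inheritParams plv
#' @return PLI in [0, 1].
#' @export
pli <- function(phase_a, phase_b) {
  check_pair(phase_a, phase_b)
  abs(mean(sign(sin(phase_a - phase_b))))
}

#' Amplitude envelope correlation of two envelope series
#'
#' Absolute Pearson correlation of the envelopes (rectified so the value lies
#' in [0, 1], keeping the MST weight inversion `1 - FC` well defined).
#'
#' @param env_a,env_b amplitude envelope series.
#' @return AEC in [0, 1].
#' @export
aec <- function(env_a, env_b) {
  check_pair(env_a, env_b)
  if (sd(env_a) == 0 || sd(env_b) == 0) {
    abort("envelope with zero variance: correlation undefined", "undefined_pair")
  }
  abs(cor(env_a, env_b))
}

#' Multivariate symmetric orthogonalization (closest orthogonal matrix)
#'
#' Finds the set of mutually orthogonal row vectors closest (in Frobenius
#' norm) to the input rows, treating all channels symmetrically: permuting
#' input rows permutes output rows identically. This removes all zero-lag
#' (instantaneous) correlations among channels while perturbing each series
#' as little as possible. The solution is computed by alternating between the
#' orthonormal-frame Procrustes step (via SVD) and per-row magnitude
#' rescaling.
#'
#' Rank-deficient inputs (fewer independent dimensions than channels) cannot
#' host a full set of orthogonal rows inside their own row space. By default
#' this is an error; with `on_deficient = "complete"` the orthonormal basis is
#' completed deterministically from the SVD so the extra orthogonal directions
#' come from outside the row space — the behaviour needed for
#' average-referenced sensor data (codimension 1) and rank-limited
#' source-reconstructed data, where the deficiency is structural.
#'
#' @param epoch numeric matrix, channels x samples, with `samples >= channels`.
#' @param tol relative convergence tolerance on the residual.
#' @param max_iter maximum number of alternating iterations.
#' @param on_deficient `"error"` to reject (numerically) rank-deficient input,
#'   `"complete"` to orthogonalize through the completed SVD basis.
#' @return matrix of the same shape with mutually orthogonal rows.
#' @export
symmetric_orthogonalize <- function(epoch, tol = 1e-8, max_iter = 60L,
                                    on_deficient = c("error", "complete")) {
  on_deficient <- match.arg(on_deficient)
  x <- if (is.matrix(epoch)) epoch else rbind(epoch)
  n <- nrow(x)
  if (ncol(x) < n) stop_invalid_argument("need at least as many samples as channels")
  check_finite(x, "epoch")
  # Full factorization X = B Qf with Qf an orthonormal n-frame (LAPACK
  # completes the frame for null singular values) and B = U diag(s) square;
  # all alternating iterations then run on the small n x n factor B.
  eg <- eigen(tcrossprod(x), symmetric = TRUE)
  s <- sqrt(pmax(eg$values, 0))
  r <- sum(s > 1e-6 * s[1]) # singular-value ratio; 1e-12 on the Gram spectrum
  if (r < n && on_deficient == "error") {
    abort("input rows are (numerically) linearly dependent", "rank_deficient")
  }
  u0 <- eg$vectors
  qf <- (t(u0[, seq_len(r), drop = FALSE]) %*% x) / s[seq_len(r)]
  if (r < n) qf <- rbind(qf, complement_frame(qf, n - r))
  b <- u0 * rep(s, each = n) # U diag(s); X = B Qf
  d0 <- sqrt(rowSums(x^2))
  total <- sum(s^2)
  cw <- com_weights(b, d0, total, tol, as.integer(max_iter))
  sv <- svd(cw$d * b)
  out <- ((cw$d * sv$u) %*% t(sv$v)) %*% qf # diag(d) U W' Qf
  dimnames(out) <- dimnames(x)
  out
}

# Deterministic orthonormal completion of a frame: low-order DCT vectors
# (starting from the constant) projected out of the existing rows and
# Gram-Schmidt orthonormalized. Low-frequency vectors are nearly orthogonal
# to band-limited data already, keeping the completion well conditioned.
complement_frame <- function(q, k) {
  n_samp <- ncol(q)
  t_idx <- seq_len(n_samp) - 0.5
  out <- matrix(0, 0, n_samp)
  j <- 0
  while (nrow(out) < k) {
    v <- cos(pi * j * t_idx / n_samp)
    j <- j + 1
    v <- v - as.vector(crossprod(q %*% v, q)) # project out the data frame
    if (nrow(out) > 0) v <- v - as.vector(crossprod(out %*% v, out))
    nv <- sqrt(sum(v^2))
    if (nv < 1e-6 * sqrt(n_samp)) next # lies (almost) inside the span
    out <- rbind(out, v / nv)
    if (j > n_samp) abort("cannot complete orthonormal frame", "rank_deficient")
  }
  out
}

#' Leakage-corrected amplitude envelope correlation matrix
#'
#' Symmetric orthogonalization of the raw epoch, then the analytic envelope,
#' then pairwise (absolute) envelope correlations.
#'
#' @param epoch numeric matrix, channels x samples, band-limited.
#' @param fs sampling frequency in Hz.
#' @param edge_trim seconds discarded from each end of the envelope before
#'   correlating (analytic-signal edge artifacts).
#' @param on_deficient passed to [symmetric_orthogonalize()]; the pipeline
#'   uses `"complete"` because referencing and inversion make its epochs
#'   structurally rank-deficient.
#' @return symmetric matrix of AEC_corrected values, zero diagonal.
#' @export
aec_corrected <- function(epoch, fs, edge_trim = 0.25,
                          on_deficient = c("error", "complete")) {
  if (!is.matrix(epoch)) epoch <- rbind(epoch)
  xo <- symmetric_orthogonalize(epoch, on_deficient = match.arg(on_deficient))
  core <- conn_all(xo, round(edge_trim * fs), FALSE, TRUE)
  flag_na(core$aec, core$flagged)
}

# Mark all pairs touching a flagged (all-zero) channel as undefined.
flag_na <- function(m, flagged) {
  if (any(flagged)) {
    m[flagged, ] <- NA_real_
    m[, flagged] <- NA_real_
    diag(m) <- 0
  }
  m
}

# Drop edge_trim seconds of rows (samples) from both ends.
trim_rows <- function(x, fs, edge_trim) {
  k <- round(edge_trim * fs)
  n <- nrow(x)
  if (n - 2 * k < 2) stop_invalid_argument("edge_trim leaves fewer than 2 samples")
  x[(k + 1):(n - k), , drop = FALSE]
}

trim_samples <- function(x, fs, edge_trim) {
  k <- round(edge_trim * fs)
  n <- ncol(x)
  if (n - 2 * k < 2) stop_invalid_argument("edge_trim leaves fewer than 2 samples")
  x[, (k + 1):(n - k), drop = FALSE]
}

hilbert_weights <- function(n_samp) {
  h <- numeric(n_samp)
  h[1] <- 1
  if (n_samp %% 2 == 0) {
    h[n_samp / 2 + 1] <- 1
    h[2:(n_samp / 2)] <- 2
  } else {
    h[2:((n_samp + 1) / 2)] <- 2
  }
  h
}

# Complex analytic signal of a channels x samples epoch, returned as a
# samples x channels matrix (each channel contiguous); with mod_only the
# envelope is returned instead.
analytic_cols <- function(epoch, mod_only = FALSE) {
  z <- mvfft(mvfft(t(epoch)) * hilbert_weights(ncol(epoch)), inverse = TRUE) / ncol(epoch)
  if (mod_only) Mod(z) else z
}

# One epoch -> the requested metric matrices, sharing the analytic
# decomposition across metrics. Phase factors are taken as z/|z| directly,
# avoiding the angle round trip.
conn_epoch <- function(x, fs, metrics, edge_trim) {
  core <- conn_all(
    x, round(edge_trim * fs),
    any(c("plv", "pli") %in% metrics), "aec" %in% metrics
  )
  out <- list()
  for (nm in intersect(metrics, c("plv", "pli", "aec"))) {
    out[[nm]] <- flag_na(core[[nm]], core$flagged)
  }
  if ("aec_corrected" %in% metrics) {
    out$aec_corrected <- aec_corrected(x, fs, edge_trim, on_deficient = "complete")
  }
  out
}

CONN_METRICS <- c("plv", "pli", "aec", "aec_corrected")

#' Per-epoch connectivity matrices
#'
#' Computes one symmetric node x node connectivity matrix per epoch (no
#' cross-epoch pooling). The first and last `edge_trim` seconds of each
#' epoch's phase/envelope are excluded from the metric computation to
#' suppress analytic-signal edge artifacts.
#'
#' @param epochs an `epoch_set`, already filtered to the analysis band.
#' @param metric one of `"plv"`, `"pli"`, `"aec"`, `"aec_corrected"`.
#' @param edge_trim seconds trimmed from each epoch end.
#' @return list of symmetric matrices (one per epoch) with attributes
#'   `metric`, `domain`, `band`, `subject`, `condition`, `epoch`.
#' @export
connectivity_matrix <- function(epochs, metric = CONN_METRICS, edge_trim = 0.25) {
  metric <- match.arg(metric)
  stopifnot(inherits(epochs, "epoch_set"))
  lapply(seq_len(n_epochs(epochs)), function(e) {
    m <- conn_epoch(epoch_matrix(epochs, e), epochs$fs, metric, edge_trim)[[metric]]
    dimnames(m) <- list(epochs$channel_labels, epochs$channel_labels)
    structure(m,
      metric = metric, domain = epochs$domain, band = epochs$band,
      subject = epochs$subject_id, condition = epochs$condition_label, epoch = e
    )
  })
}

#' Global connectivity of a connectivity matrix
#'
#' Mean of the off-diagonal entries (equivalently, the mean upper triangle of
#' a symmetric matrix).
#'
#' @param m symmetric connectivity matrix.
#' @return scalar mean connectivity.
#' @export
global_connectivity <- function(m) {
  if (nrow(m) < 2) stop_invalid_argument("global connectivity undefined for a single node")
  mean(m[upper.tri(m)])
}
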