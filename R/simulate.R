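# Forward simulation: coupled stochastic oscillators -> volume-conducted
# sensor recordings. This module provides the ground truth that the empirical
# study design lacks: phase- and amplitude-coupling graphs whose topology is
# known exactly, so scalp- and source-level network estimates can both be
# compared against the truth and against each other.

KURAMOTO_GAIN <- 20 # rad/s of phase pull at coupling strength 1

#' Simulate coupled oscillatory source activity
#'
#' Integrates stochastic phase oscillators on the spec's coupling graph
#' (Euler-Maruyama, step `1/fs`): each source advances at its natural alpha
#' frequency, coupled pairs pull towards the per-edge phase lag, and phase
#' noise diffuses the uncoupled pairs. Amplitude coupling is realised through
#' slow (< 1 Hz) shared log-normal envelope modulators: each edge of the
#' amplitude graph owns an Ornstein-Uhlenbeck modulator whose weight in the
#' two endpoint envelopes equals the edge strength, so the envelope
#' correlation of an amplitude-coupled pair approaches its edge strength.
#'
#' @param spec a [ground_truth_spec()].
#' @param duration recording length in seconds (>= 2).
#' @param fs sampling frequency in Hz.
#' @param coupling_gain phase pull in rad/s exerted by a strength-1 edge.
#' @param envelope_log_sd log-scale SD of the envelope modulation.
#' @return an `eeg_recording` with `domain = "source"`; the integrated phase
#'   matrix is attached as attribute `"phase"` and the envelope as
#'   `"envelope"` for ground-truth checks.
#' @export
simulate_sources <- function(spec, duration = 60, fs = 160,
                             coupling_gain = KURAMOTO_GAIN,
                             envelope_log_sd = 0.7) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  if (duration < 2) stop_invalid_argument("duration must be at least 2 seconds")
  n <- spec$n_sources
  steps <- round(duration * fs)
  dt <- 1 / fs
  with_seed(spec$seed, {
    omega <- 2 * pi * (spec$center_frequency + rnorm(n, sd = spec$freq_jitter_sd))
    phi0 <- runif(n, 0, 2 * pi)
    up <- which(upper.tri(spec$coupling_graph) & spec$coupling_graph > 0, arr.ind = TRUE)
    noise <- matrix(rnorm(n * steps, sd = spec$phase_noise_sd * sqrt(dt)), nrow = n)
    envelope <- exp(envelope_log_sd * envelope_modulators(spec$amplitude_coupling_graph, steps, fs))
    sim <- kuramoto_phases(
      phi0, omega,
      as.integer(up[, 1]) - 1L, as.integer(up[, 2]) - 1L,
      coupling_gain * spec$coupling_graph[up], spec$lag[up],
      noise, dt, envelope
    )
    phases <- sim$phases
    rec <- new_recording(sim$data, fs,
      subject_id = "sim", condition_label = spec$condition_label,
      domain = "source"
    )
    attr(rec, "phase") <- phases
    attr(rec, "envelope") <- envelope
    rec
  })
}

# Slow standardized modulators: one OU process per amplitude-coupled edge plus
# one private process per source, mixed so Var(z_i) = 1 and
# cor(z_i, z_j) = strength(i, j) for amplitude-coupled pairs. The modulators
# live far below the signal band, so they are generated on a coarse time grid
# (mod_fs) and linearly interpolated to the sampling rate.
envelope_modulators <- function(amp_graph, steps, fs, cutoff_hz = 0.9, mod_fs = 8) {
  n <- nrow(amp_graph)
  up <- which(upper.tri(amp_graph) & amp_graph > 0, arr.ind = TRUE)
  m <- nrow(up)
  ratio <- fs / mod_fs
  steps_low <- ceiling((steps - 1) / ratio) + 2L
  burn <- 48L
  a <- exp(-2 * pi * cutoff_hz / mod_fs) # AR(1) pole at ~cutoff_hz
  ou <- function(k) {
    # columns are independent unit-variance OU traces at the coarse rate
    e <- matrix(rnorm(k * (steps_low + burn), sd = sqrt(1 - a^2)), nrow = steps_low + burn)
    z <- stats::filter(e, a, method = "recursive")
    matrix(z[(burn + 1):(burn + steps_low), ], ncol = k)
  }
  edge_mod <- if (m > 0) ou(m) else NULL
  own_mod <- ou(n)
  z_low <- matrix(0, steps_low, n)
  for (i in seq_len(n)) {
    e_idx <- which(up[, 1] == i | up[, 2] == i)
    w <- amp_graph[cbind(up[e_idx, 1], up[e_idx, 2])]
    tot <- sum(w)
    if (tot > 0.95) {
      w <- w * 0.95 / tot
      tot <- 0.95
    }
    zi <- sqrt(1 - tot) * own_mod[, i]
    if (length(e_idx) > 0) {
      zi <- zi + edge_mod[, e_idx, drop = FALSE] %*% sqrt(w)
    }
    z_low[, i] <- zi
  }
  pos <- (seq_len(steps) - 1) / ratio + 1
  i0 <- pmin(floor(pos), steps_low - 1L)
  frac <- pos - i0
  t(z_low[i0, , drop = FALSE] * (1 - frac) + z_low[i0 + 1L, , drop = FALSE] * frac)
}

#' Project source activity to the scalp through a leadfield
#'
#' Applies the instantaneous forward model `sensor = gain %*% source` and adds
#' white sensor noise scaled so the empirical signal-to-noise power ratio
#' equals `sensor_snr`.
#'
#' @param sources an `eeg_recording` with one channel per leadfield source.
#' @param lf a `leadfield`.
#' @param sensor_snr signal-to-noise power ratio; `Inf` for noiseless.
#' @param seed integer seed for the noise realization.
#' @param signal_scale multiplier applied to the projected signal but not the
#'   noise; values other than 1 emulate between-subject differences in rhythm
#'   amplitude against a fixed sensor noise floor.
#' @return an `eeg_recording` with `domain = "sensor"`.
#' @export
project_to_sensors <- function(sources, lf, sensor_snr = 4, seed = 1L,
                               signal_scale = 1) {
  stopifnot(inherits(sources, "eeg_recording"), inherits(lf, "leadfield"))
  if (ncol(lf$gain) != nrow(sources$data)) {
    stop_invalid_argument(sprintf(
      "leadfield expects %d sources, recording has %d channels",
      ncol(lf$gain), nrow(sources$data)
    ))
  }
  clean <- lf$gain %*% sources$data
  if (is.finite(sensor_snr)) {
    if (sensor_snr <= 0) stop_invalid_argument("sensor_snr must be positive")
    # noise floor referenced to the UNSCALED signal power: with
    # signal_scale != 1 the realized SNR is signal_scale^2 * sensor_snr,
    # emulating subjects whose rhythm amplitude differs against a fixed
    # amplifier/environment noise level
    p_signal <- mean(clean^2)
    noise <- with_seed(seed, matrix(
      rnorm(length(clean), sd = sqrt(p_signal / sensor_snr)),
      nrow(clean)
    ))
    data <- signal_scale * clean + noise
  } else {
    data <- signal_scale * clean
  }
  new_recording(data, sources$fs,
    subject_id = sources$subject_id,
    condition_label = sources$condition_label, domain = "sensor"
  )
}

#' Default experimental condition templates
#'
#' Two resting-state conditions with distinct ground-truth topology and
#' coupling strength: eyes-closed (`EC`, more hub-dominated backbone and
#' stronger alpha coupling) versus eyes-open (`EO`, more line-like backbone,
#' weaker coupling).
#'
#' @return named list of per-condition parameter lists consumed by
#'   [make_cohort()].
#' @export
default_conditions <- function() {
  list(
    EC = list(
      condition_label = "EC", target_leaf_fraction = 0.65, strength = 0.7,
      amp_strength = 0.5, power = 1.15
    ),
    EO = list(
      condition_label = "EO", target_leaf_fraction = 0.45, strength = 0.6,
      amp_strength = 0.45, power = 0.85
    )
  )
}

#' Simulate a whole cohort of sensor recordings
#'
#' For every subject and condition, draws a ground-truth coupling graph
#' (tree backbone with condition-specific target leaf fraction, jittered per
#' subject), integrates the source model, and projects it through one shared
#' spherical-head leadfield (all subjects share the montage and template
#' anatomy). Everything is reproducible from the master seed, and subject
#' `i`'s data depend only on `(seed, i)`.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param conditions named list of condition templates; see
#'   [default_conditions()].
#' @param seed master integer seed.
#' @param n_sensors,n_sources geometry size (64 sensors / 68 sources by
#'   default, one source per ROI).
#' @param duration,fs recording length (s) and sampling rate (Hz).
#' @param sensor_snr sensor-level signal-to-noise power ratio.
#' @param jitter logical; disable to give every subject the identical
#'   condition-template coupling graph (degenerate cohort for testing).
#' @param leaf_jitter half-width of the per-subject uniform jitter on the
#'   target leaf fraction.
#' @param strength_range range of the per-subject multiplicative coupling
#'   strength scale (drives between-subject global-connectivity variation).
#' @param source_radius radius of the source shell, passed to
#'   [make_geometry()].
#' @param phase_noise_sd oscillator phase diffusion, passed to
#'   [ground_truth_spec()].
#' @param anatomy_jitter SD (radians) of the per-subject azimuthal rotation of
#'   the true source lattice relative to the template geometry used for
#'   inversion; emulates template-anatomy source reconstruction of
#'   anatomically distinct heads.
#' @return object of class `eeg_cohort`: `leadfield`, and `records`, a list
#'   with one entry per subject x condition holding `sensor` and `source`
#'   recordings plus the `spec` ground truth.
#' @export
make_cohort <- function(n_subjects, conditions = default_conditions(), seed = 1L,
                        n_sensors = 64, n_sources = 68, duration = 60, fs = 160,
                        sensor_snr = 4, jitter = TRUE, leaf_jitter = 0.2,
                        strength_range = c(0.85, 1), source_radius = 0.8,
                        phase_noise_sd = 1, anatomy_jitter = 0.4) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  if (length(conditions) < 1L) stop_invalid_argument("need at least one condition template")
  if (is.null(names(conditions))) names(conditions) <- vapply(conditions, `[[`, "", "condition_label")
  n_cond <- length(conditions)
  draws <- with_seed(seed, list(
    geom_seed = sample.int(.Machine$integer.max - 1L, 1L),
    scale = runif(n_subjects, strength_range[1], strength_range[2]),
    power = exp(rnorm(n_subjects, sd = 0.25)),
    anatomy = rnorm(n_subjects, sd = anatomy_jitter),
    leaf_shift = runif(n_subjects, -leaf_jitter, leaf_jitter),
    sim_seeds = matrix(
      sample.int(.Machine$integer.max - 1L, n_subjects * n_cond * 3L),
      nrow = n_subjects
    )
  ))
  lf <- make_geometry(n_sensors, n_sources, seed = draws$geom_seed, source_radius = source_radius)
  records <- vector("list", n_subjects * n_cond)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    # per-subject anatomy: the true forward geometry deviates from the shared
    # template that the inverse operator will assume, as when all subjects are
    # source-reconstructed with one template head model
    lf_subj <- if (jitter && anatomy_jitter > 0) {
      make_geometry(n_sensors, n_sources,
        seed = draws$geom_seed, source_radius = source_radius,
        azimuth = lf$azimuth + draws$anatomy[s]
      )
    } else {
      lf
    }
    for (ci in seq_len(n_cond)) {
      k <- k + 1L
      tmpl <- conditions[[ci]]
      leaf <- tmpl$target_leaf_fraction
      strength <- tmpl$strength
      graph_seed <- draws$sim_seeds[s, 3L * ci - 2L]
      amp_seed <- draws$sim_seeds[s, 3L * ci - 1L]
      sim_seed <- draws$sim_seeds[s, 3L * ci]
      if (jitter) {
        leaf <- min(0.9, max(0.25, leaf + draws$leaf_shift[s]))
        strength <- strength * draws$scale[s]
      } else {
        # degenerate cohort: one shared graph per condition
        graph_seed <- draws$sim_seeds[1L, 3L * ci - 2L]
        amp_seed <- draws$sim_seeds[1L, 3L * ci - 1L]
      }
      graph <- sample_coupling_graph(
        n_sources,
        target_leaf_fraction = leaf, strength = strength,
        strength_jitter = min(0.1, strength / 4), seed = graph_seed
      )
      # the amplitude-coupling network shares the condition topology target
      # but is an independently sampled backbone: genuine envelope coupling
      # between regions need not coincide with phase-locked pairs, and only
      # non-phase-locked envelope coupling survives leakage correction
      # amplitude coupling shares the phase backbone by default: phase-locked
      # pairs also share their envelope modulation, as alpha sources do
      amp_graph <- if (isTRUE(tmpl$amp_separate)) {
        amp_strength <- if (is.null(tmpl$amp_strength)) 0.5 else tmpl$amp_strength
        if (jitter) amp_strength <- amp_strength * (0.7 + 0.3 * draws$scale[s])
        sample_coupling_graph(
          n_sources,
          target_leaf_fraction = leaf, strength = amp_strength,
          strength_jitter = 0.05, max_degree = 3, seed = amp_seed
        )
      } else {
        graph
      }
      spec <- ground_truth_spec(
        n_sources,
        coupling_graph = graph,
        amplitude_coupling_graph = amp_graph,
        phase_noise_sd = phase_noise_sd,
        condition_label = tmpl$condition_label,
        target_leaf_fraction = leaf,
        seed = sim_seed
      )
      src <- simulate_sources(spec, duration = duration, fs = fs)
      src$subject_id <- sprintf("S%03d", s)
      power <- if (is.null(tmpl$power)) 1 else tmpl$power
      if (jitter) power <- power * draws$power[s]
      sen <- project_to_sensors(src, lf_subj,
        sensor_snr = sensor_snr, seed = sim_seed, signal_scale = power
      )
      attr(src, "phase") <- NULL # keep cohort objects lean
      attr(src, "envelope") <- NULL
      records[[k]] <- list(
        subject = sprintf("S%03d", s),
        condition = tmpl$condition_label,
        sensor = sen, source = src, spec = spec
      )
    }
  }
  structure(
    list(
      leadfield = lf, records = records, n_subjects = n_subjects,
      conditions = names(conditions), fs = fs, duration = duration, seed = seed
    ),
    class = "eeg_cohort"
  )
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf(
    "<eeg_cohort> %d subjects x %d conditions = %d recordings (%g s @ %g Hz)\n",
    x$n_subjects, length(x$conditions), length(x$records), x$duration, x$fs
  ))
  invisible(x)
}
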