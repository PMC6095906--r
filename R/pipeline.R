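# End-to-end orchestration: simulate -> preprocess -> (scalp | inverse)
# branches -> connectivity -> MST descriptors -> domain comparison.

BAND_PRESETS <- list(alpha = c(8, 13), theta = c(4, 8), beta = c(13, 30))

#' Assemble and validate a pipeline configuration
#'
#' @param n_subjects cohort size.
#' @param conditions condition templates, see [default_conditions()].
#' @param seed master seed for the whole run.
#' @param band analysis band: a preset name (`"alpha"`, `"theta"`, `"beta"`)
#'   or a numeric `c(low, high)` in Hz.
#' @param broadband optional sensor-level broadband filter `c(low, high)`
#'   applied before the analysis band (off by default for simulated cohorts,
#'   whose signals are generated in-band).
#' @param notch optional notch frequency in Hz (applied with `broadband`).
#' @param epoch_seconds epoch length in seconds.
#' @param edge_trim per-epoch edge trim in seconds for the analytic signal.
#' @param inverse_method `"wmne"` or `"sloreta"`.
#' @param inverse_snr,inverse_depth inverse regularization SNR and depth
#'   exponent (depth applies to wMNE only).
#' @param metrics connectivity metrics to compute.
#' @param node_subset optional character vector of source/ROI labels to KEEP
#'   in source-domain matrices (network-size sensitivity check).
#' @param n_boot bootstrap replicates for the correlation comparisons.
#' @param n_sensors,n_sources,duration,fs,sensor_snr cohort geometry and
#'   recording parameters, passed to [make_cohort()].
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 40, conditions = default_conditions(),
                            seed = 1L, band = "alpha", broadband = NULL,
                            notch = NULL, epoch_seconds = 12, edge_trim = 0.25,
                            inverse_method = c("wmne", "sloreta"),
                            inverse_snr = 3, inverse_depth = 0.5,
                            metrics = CONN_METRICS, node_subset = NULL,
                            n_boot = 500L, n_sensors = 64, n_sources = 68,
                            duration = 60, fs = 160, sensor_snr = 4) {
  inverse_method <- match.arg(inverse_method)
  if (is.character(band)) {
    if (!band %in% names(BAND_PRESETS)) {
      stop_invalid_argument(sprintf("unknown band preset '%s'", band))
    }
    band_name <- band
    band <- BAND_PRESETS[[band]]
  } else {
    band_name <- sprintf("%g-%g Hz", band[1], band[2])
  }
  if (!(length(band) == 2 && 0 < band[1] && band[1] < band[2] && band[2] < fs / 2)) {
    stop_invalid_argument("band must satisfy 0 < low < high < fs/2")
  }
  metrics <- match.arg(metrics, CONN_METRICS, several.ok = TRUE)
  if (epoch_seconds > duration) stop_invalid_argument("epoch_seconds exceeds duration")
  structure(
    list(
      n_subjects = check_count(n_subjects, "n_subjects"), conditions = conditions,
      seed = as.integer(seed), band = band, band_name = band_name,
      broadband = broadband, notch = notch, epoch_seconds = epoch_seconds,
      edge_trim = edge_trim, inverse_method = inverse_method,
      inverse_snr = inverse_snr, inverse_depth = inverse_depth,
      metrics = metrics, node_subset = node_subset,
      n_boot = as.integer(n_boot), n_sensors = n_sensors,
      n_sources = n_sources, duration = duration, fs = fs,
      sensor_snr = sensor_snr
    ),
    class = "pipeline_config"
  )
}

#' Restrict a connectivity matrix to a subset of labelled nodes
#'
#' Returns the principal submatrix on the kept labels, preserving their
#' original order (used for the 68-to-64-node network-size check, where the
#' bilateral parahippocampal and lingual parcels are dropped).
#'
#' @param m square matrix with row/column names.
#' @param keep character vector of labels to keep.
#' @return the submatrix, attributes preserved.
#' @export
subset_nodes <- function(m, keep) {
  if (is.null(rownames(m))) stop_invalid_argument("matrix has no node labels")
  unknown <- setdiff(keep, rownames(m))
  if (length(unknown)) {
    stop_invalid_argument(paste("unknown node labels:", paste(unknown, collapse = ", ")))
  }
  idx <- which(rownames(m) %in% keep)
  out <- m[idx, idx, drop = FALSE]
  for (at in c("metric", "domain", "band", "subject", "condition", "epoch")) {
    attr(out, at) <- attr(m, at)
  }
  out
}

# Preprocess one sensor recording: CAR, optional broadband+notch, analysis
# band; then epoch.
preprocess_sensor <- function(rec, cfg) {
  rec <- common_average_reference(rec)
  if (!is.null(cfg$broadband)) {
    rec <- bandpass_filter(rec, cfg$broadband[1], cfg$broadband[2], notch = cfg$notch)
  }
  rec <- bandpass_filter(rec, cfg$band[1], cfg$band[2])
  segment_epochs(rec, cfg$epoch_seconds)
}

measure_values <- function(m) {
  tm <- tree_metrics(m)
  c(
    global = global_connectivity(m), leaf_fraction = tm$leaf_fraction,
    diameter = tm$diameter, kappa = tm$kappa, hierarchy = tm$hierarchy
  )
}

#' Paired scalp/source network measures for a cohort
#'
#' Runs both analysis branches on every recording of a cohort — the scalp
#' branch directly on the preprocessed sensor epochs, the source branch on
#' the same epochs after inverse modelling and ROI aggregation — and tabulates
#' global connectivity plus the four MST descriptors for every metric and
#' epoch.
#'
#' @param cohort an `eeg_cohort` from [make_cohort()].
#' @param cfg a `pipeline_config` (geometry fields are taken from the cohort).
#' @return a paired measure table: data.frame (subject, condition, epoch,
#'   metric, measure, scalp, source).
#' @export
network_measures <- function(cohort, cfg = pipeline_config(n_subjects = cohort$n_subjects)) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  lf <- cohort$leadfield
  op <- if (cfg$inverse_method == "sloreta") {
    sloreta_operator(lf, snr = cfg$inverse_snr)
  } else {
    wmne_operator(lf, snr = cfg$inverse_snr, depth_exponent = cfg$inverse_depth)
  }
  rows <- vector("list", length(cohort$records))
  n_meas <- length(MEASURE_NAMES)
  for (k in seq_along(cohort$records)) {
    rec <- cohort$records[[k]]
    ep_sen <- preprocess_sensor(rec$sensor, cfg)
    ep_roi <- aggregate_rois(apply_inverse(ep_sen, op), lf)
    n_ep <- n_epochs(ep_sen)
    n_met <- length(cfg$metrics)
    scalp_v <- numeric(n_ep * n_met * n_meas)
    source_v <- numeric(n_ep * n_met * n_meas)
    pos <- 0L
    for (e in seq_len(n_ep)) {
      cs <- conn_epoch(epoch_matrix(ep_sen, e), cfg$fs, cfg$metrics, cfg$edge_trim)
      cr <- conn_epoch(epoch_matrix(ep_roi, e), cfg$fs, cfg$metrics, cfg$edge_trim)
      for (met in cfg$metrics) {
        src <- cr[[met]]
        if (!is.null(cfg$node_subset)) {
          dimnames(src) <- list(ep_roi$channel_labels, ep_roi$channel_labels)
          src <- subset_nodes(src, cfg$node_subset)
        }
        scalp_v[pos + seq_len(n_meas)] <- measure_values(cs[[met]])
        source_v[pos + seq_len(n_meas)] <- measure_values(src)
        pos <- pos + n_meas
      }
    }
    rows[[k]] <- data.frame(
      subject = rec$subject, condition = rec$condition,
      epoch = rep(seq_len(n_ep), each = n_met * n_meas),
      metric = rep(rep(cfg$metrics, each = n_meas), times = n_ep),
      measure = rep(MEASURE_NAMES, times = n_ep * n_met),
      scalp = scalp_v, source = source_v
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full scalp-versus-source comparison pipeline
#'
#' Simulates a cohort, computes the paired measure table, the epoch- and
#' subject-level Spearman correlation grids, the percentile-bootstrap
#' comparisons between leakage-insensitive and leakage-sensitive metrics
#' (PLI vs PLV, AEC_corrected vs AEC) for every MST measure, and the
#' condition-shift direction report. Fully deterministic for a fixed config.
#'
#' @param cfg a `pipeline_config`.
#' @param out optional directory; when given, tidy CSV tables and a JSON
#'   report are written there together with the resolved configuration.
#' @param cohort optionally, a pre-built `eeg_cohort` to analyse instead of
#'   simulating one from the config.
#' @return list with elements `measures`, `correlations` (epoch + subject
#'   level), `bootstrap` (list of `correlation_comparison` per measure and
#'   metric pair), `shifts`, `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out = NULL, cohort = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  if (is.null(cohort)) {
    cohort <- make_cohort(
      cfg$n_subjects,
      conditions = cfg$conditions, seed = cfg$seed,
      n_sensors = cfg$n_sensors, n_sources = cfg$n_sources,
      duration = cfg$duration, fs = cfg$fs, sensor_snr = cfg$sensor_snr
    )
  }
  message(sprintf("[simulate] %d recordings (%.1f s)", length(cohort$records),
    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  measures <- network_measures(cohort, cfg)
  message(sprintf("[measures] %d rows (%.1f s)", nrow(measures),
    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  correlations <- rbind(
    correlate_domains(measures, "epoch"),
    correlate_domains(measures, "subject")
  )
  pairs_of_interest <- list(
    c("pli", "plv"), c("aec_corrected", "aec")
  )
  bootstrap <- list()
  boot_seeds <- derive_seeds(cfg$seed + 1L, length(pairs_of_interest) * length(MEASURE_NAMES))
  bs <- 0L
  for (pair in pairs_of_interest) {
    if (!all(pair %in% cfg$metrics)) next
    for (meas in setdiff(MEASURE_NAMES, "global")) {
      bs <- bs + 1L
      sub_a <- measures[measures$metric == pair[1] & measures$measure == meas, ]
      sub_b <- measures[measures$metric == pair[2] & measures$measure == meas, ]
      key <- sprintf("%s_vs_%s.%s", pair[1], pair[2], meas)
      bootstrap[[key]] <- bootstrap_compare(
        sub_a[, c("scalp", "source")], sub_b[, c("scalp", "source")],
        n_boot = cfg$n_boot, seed = boot_seeds[bs]
      )
    }
  }
  shifts <- if (length(cohort$conditions) >= 2) {
    do.call(rbind, lapply(MEASURE_NAMES, function(ms) condition_shift(measures, ms)))
  } else {
    NULL
  }
  result <- list(
    measures = measures, correlations = correlations, bootstrap = bootstrap,
    shifts = shifts, config = cfg
  )
  if (!is.null(out)) write_pipeline_results(result, out)
  message(sprintf("[done] total %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  result
}

write_pipeline_results <- function(result, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$measures, file.path(out, "measures.csv"), row.names = FALSE)
  write.csv(result$correlations, file.path(out, "correlations.csv"), row.names = FALSE)
  if (!is.null(result$shifts)) {
    write.csv(result$shifts, file.path(out, "condition_shifts.csv"), row.names = FALSE)
  }
  boot <- lapply(result$bootstrap, function(b) {
    list(
      rho_a = b$rho_a, rho_b = b$rho_b, difference = b$difference,
      ci = b$ci, n_boot = b$n_boot, n_skipped = b$n_skipped
    )
  })
  jsonlite::write_json(boot, file.path(out, "bootstrap_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  cfg <- result$config
  cfg$conditions <- lapply(cfg$conditions, as.list)
  jsonlite::write_json(unclass(cfg), file.path(out, "config.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(out)
}
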