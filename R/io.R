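# Serialization: cohort directory layout and connectivity matrix exports.

#' Save a simulated cohort to a directory
#'
#' One binary array file (little-endian doubles, channels x samples in
#' column-major order) per sensor recording, plus a JSON sidecar with the
#' sampling metadata, condition, seed, and the ground-truth coupling edge
#' list.
#'
#' @param cohort an `eeg_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$records) {
    stem <- file.path(dir, sprintf("%s_%s", rec$subject, rec$condition))
    con <- file(paste0(stem, ".bin"), "wb")
    writeBin(as.vector(rec$sensor$data), con, size = 8, endian = "little")
    close(con)
    g <- rec$spec$coupling_graph
    ed <- which(upper.tri(g) & g > 0, arr.ind = TRUE)
    jsonlite::write_json(
      list(
        subject = rec$subject, condition = rec$condition,
        fs = rec$sensor$fs, n_channels = nrow(rec$sensor$data),
        n_samples = ncol(rec$sensor$data),
        channel_labels = rec$sensor$channel_labels,
        seed = rec$spec$seed,
        target_leaf_fraction = rec$spec$target_leaf_fraction,
        coupling_edges = data.frame(i = ed[, 1], j = ed[, 2], strength = g[ed])
      ),
      paste0(stem, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}

#' Load sensor recordings saved by [save_cohort()]
#'
#' @param dir directory written by [save_cohort()].
#' @return list of `eeg_recording` objects (sensor domain), one per sidecar,
#'   each carrying its ground-truth coupling edge list as attribute
#'   `"coupling_edges"`.
#' @export
load_cohort <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (!length(sidecars)) abort(sprintf("no cohort sidecars in %s", dir), "format_error")
  lapply(sidecars, function(path) {
    meta <- jsonlite::read_json(path, simplifyVector = TRUE)
    bin <- sub("\\.json$", ".bin", path)
    n <- meta$n_channels * meta$n_samples
    con <- file(bin, "rb")
    on.exit(close(con))
    vals <- readBin(con, numeric(), n = n, size = 8, endian = "little")
    if (length(vals) < n) abort(sprintf("truncated array file %s", bin), "format_error")
    rec <- new_recording(
      matrix(vals, meta$n_channels, meta$n_samples), meta$fs,
      channel_labels = meta$channel_labels, subject_id = meta$subject,
      condition_label = meta$condition, domain = "sensor"
    )
    attr(rec, "coupling_edges") <- meta$coupling_edges
    rec
  })
}

#' Export a connectivity matrix as plain text
#'
#' @param m symmetric connectivity matrix (typically from
#'   [connectivity_matrix()]).
#' @param path output file.
#' @param format `"matrix"` for a whitespace-separated square table,
#'   `"long"` for tidy CSV rows (node_i, node_j, metric, epoch, domain,
#'   value) over the upper triangle.
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(m, path, format = c("matrix", "long")) {
  format <- match.arg(format)
  if (format == "matrix") {
    utils::write.table(unclass(m), path,
      row.names = !is.null(rownames(m)),
      col.names = !is.null(colnames(m)), quote = FALSE
    )
  } else {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    lab <- rownames(m)
    if (is.null(lab)) lab <- as.character(seq_len(nrow(m)))
    df <- data.frame(
      node_i = lab[idx[, 1]], node_j = lab[idx[, 2]],
      metric = attr(m, "metric") %||% NA, epoch = attr(m, "epoch") %||% NA,
      domain = attr(m, "domain") %||% NA, value = m[idx]
    )
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
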