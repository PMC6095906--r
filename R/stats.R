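# Scalp-vs-source statistical comparison: Spearman correlations between
# domains, percentile bootstrap for non-overlapping correlations, subject
# aggregation, and condition-shift direction analysis.

MEASURE_NAMES <- c("global", "leaf_fraction", "diameter", "kappa", "hierarchy")

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties share their average
#' rank).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_invalid_argument("x and y must have equal length")
  if (length(x) < 3) stop_invalid_argument("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant input", "undefined_correlation")
  }
  cor(x, y, method = "spearman")
}

#' Percentile bootstrap comparison of two non-overlapping correlations
#'
#' Compares the Spearman correlation of group A with that of group B (two
#' independent sets of paired observations): for each replicate, pairs are
#' resampled with replacement independently within each group, and the
#' replicate difference `rho_a* - rho_b*` is recorded. The 2.5th and 97.5th
#' percentiles of the replicate distribution form the 95% confidence interval
#' of the observed difference. Replicates in which either resample has
#' constant ranks are skipped and counted; more than 20% skipped is an error.
#'
#' @param pairs_a,pairs_b two-column matrices (or data.frames) of (x, y)
#'   pairs, at least 3 rows each.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param conf confidence level of the percentile interval.
#' @return object of class `correlation_comparison`: `rho_a`, `rho_b`,
#'   `difference`, `ci` (length-2), `n_boot`, `n_skipped`, `boot_differences`,
#'   `seed`.
#' @export
bootstrap_compare <- function(pairs_a, pairs_b, n_boot = 500L, seed = 1L,
                              conf = 0.95) {
  pairs_a <- as.matrix(pairs_a)
  pairs_b <- as.matrix(pairs_b)
  if (nrow(pairs_a) < 3 || nrow(pairs_b) < 3) {
    stop_invalid_argument("each group needs at least 3 pairs")
  }
  rho_a <- spearman_rho(pairs_a[, 1], pairs_a[, 2])
  rho_b <- spearman_rho(pairs_b[, 1], pairs_b[, 2])
  na <- nrow(pairs_a)
  nb <- nrow(pairs_b)
  diffs <- rep(NA_real_, n_boot)
  n_skipped <- 0L
  with_seed(seed, {
    for (k in seq_len(n_boot)) {
      ia <- sample.int(na, na, replace = TRUE)
      ib <- sample.int(nb, nb, replace = TRUE)
      a <- pairs_a[ia, , drop = FALSE]
      b <- pairs_b[ib, , drop = FALSE]
      if (sd(a[, 1]) == 0 || sd(a[, 2]) == 0 || sd(b[, 1]) == 0 || sd(b[, 2]) == 0) {
        n_skipped <- n_skipped + 1L
        next
      }
      diffs[k] <- cor(a[, 1], a[, 2], method = "spearman") -
        cor(b[, 1], b[, 2], method = "spearman")
    }
  })
  if (n_skipped > 0.2 * n_boot) {
    abort(sprintf(
      "%d of %d bootstrap replicates degenerate (constant ranks)", n_skipped, n_boot
    ), "degenerate_bootstrap")
  }
  ok <- diffs[!is.na(diffs)]
  alpha <- (1 - conf) / 2
  structure(
    list(
      rho_a = rho_a, rho_b = rho_b, difference = rho_a - rho_b,
      ci = unname(quantile(ok, c(alpha, 1 - alpha), type = 7)),
      n_boot = as.integer(n_boot), n_skipped = n_skipped,
      boot_differences = diffs, seed = as.integer(seed)
    ),
    class = "correlation_comparison"
  )
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf(
    "<correlation_comparison> rho_a = %.3f, rho_b = %.3f, difference = %.3f, 95%% CI [%.3f, %.3f] (%d reps, %d skipped)\n",
    x$rho_a, x$rho_b, x$difference, x$ci[1], x$ci[2], x$n_boot, x$n_skipped
  ))
  invisible(x)
}

check_measure_table <- function(table) {
  needed <- c("subject", "condition", "epoch", "metric", "measure", "scalp", "source")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop_invalid_argument(paste("paired measure table lacks columns:", paste(missing, collapse = ", ")))
  }
  table
}

#' Average epochs within subject
#'
#' Arithmetic mean over epochs within each subject x condition x metric x
#' measure cell, separately per domain, producing the subject-level table
#' (one row per cell, `epoch = NA`).
#'
#' @param table a paired measure table (see [paired_measure_table()]).
#' @return table of the same shape with epochs averaged out.
#' @export
subject_average <- function(table) {
  check_measure_table(table)
  agg <- aggregate(
    cbind(scalp, source) ~ subject + condition + metric + measure,
    data = table, FUN = mean
  )
  agg$epoch <- NA_integer_
  agg[, c("subject", "condition", "epoch", "metric", "measure", "scalp", "source")]
}

#' Spearman correlation between scalp and source measures
#'
#' For every metric x measure cell, the Spearman correlation between the
#' scalp- and source-level values across rows. At `level = "epoch"` all
#' (subject, condition, epoch) rows are pooled; at `level = "subject"` epochs
#' are first averaged within subject via [subject_average()].
#'
#' @param table a paired measure table.
#' @param level `"epoch"` or `"subject"`.
#' @return data.frame (metric, measure, level, n, rho).
#' @export
correlate_domains <- function(table, level = c("epoch", "subject")) {
  level <- match.arg(level)
  check_measure_table(table)
  if (level == "subject") table <- subject_average(table)
  cells <- unique(table[, c("metric", "measure")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    rows <- table$metric == cells$metric[k] & table$measure == cells$measure[k]
    data.frame(
      metric = cells$metric[k], measure = cells$measure[k], level = level,
      n = sum(rows),
      rho = spearman_rho(table$scalp[rows], table$source[rows])
    )
  }))
  rownames(out) <- NULL
  out
}

#' Direction of the condition effect at scalp versus source level
#'
#' For each metric and domain, computes the sign of
#' `mean(condition_1) - mean(condition_2)` for the chosen measure and reports
#' whether the scalp- and source-level shifts point in the same direction.
#'
#' @param table a paired measure table containing both conditions.
#' @param measure measure name (default `"leaf_fraction"`).
#' @param conditions length-2 character vector naming the conditions to
#'   contrast; defaults to the first two present in the table.
#' @return data.frame (metric, shift_scalp, shift_source, direction) where
#'   `direction` is `"same"`, `"opposite"`, or `"none"` when either domain
#'   shows no shift.
#' @export
condition_shift <- function(table, measure = "leaf_fraction", conditions = NULL) {
  check_measure_table(table)
  table <- table[table$measure == measure, ]
  if (is.null(conditions)) conditions <- unique(table$condition)[1:2]
  if (length(conditions) != 2 || any(is.na(conditions)) ||
      !all(conditions %in% table$condition)) {
    abort("both conditions must be present in the table", "invalid_input")
  }
  out <- do.call(rbind, lapply(unique(table$metric), function(met) {
    rows <- table[table$metric == met, ]
    d <- vapply(c("scalp", "source"), function(dom) {
      mean(rows[[dom]][rows$condition == conditions[1]]) -
        mean(rows[[dom]][rows$condition == conditions[2]])
    }, numeric(1))
    dir <- if (any(d == 0)) {
      "none"
    } else if (sign(d[1]) == sign(d[2])) "same" else "opposite"
    data.frame(
      metric = met, measure = measure,
      shift_scalp = d[["scalp"]], shift_source = d[["source"]], direction = dir
    )
  }))
  rownames(out) <- NULL
  out
}
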