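# Internal helpers: classed errors and small numeric utilities.

abort <- function(message, class) {
  stop(structure(
    list(message = message, call = sys.call(-1)),
    class = c(class, "eegnetcomp_error", "error", "condition")
  ))
}

stop_invalid_argument <- function(message) abort(message, "invalid_argument")
stop_invalid_data <- function(message) abort(message, "invalid_data")

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != round(x)) {
    stop_invalid_argument(sprintf("`%s` must be a positive integer, got %s", name, deparse(x)))
  }
  as.integer(x)
}

check_finite <- function(x, name) {
  if (!all(is.finite(x))) stop_invalid_data(sprintf("`%s` contains non-finite values", name))
  invisible(x)
}

# Derive a stream of reproducible sub-seeds from one master seed, keeping each
# below .Machine$integer.max so they remain valid R seeds.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never disturbs user simulations.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}
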