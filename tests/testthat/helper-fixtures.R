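# Shared fixtures and independent oracles used across the test files.

# Connectivity matrix whose MST is a star centred on node 1.
star_matrix <- function(m, hub_fc = 0.9, bg = 0.1) {
  x <- matrix(bg, m, m)
  x[1, -1] <- x[-1, 1] <- hub_fc
  diag(x) <- 0
  x
}

# Connectivity matrix whose MST is the path 1-2-...-m.
path_matrix <- function(m, edge_fc = 0.9, bg = 0.05) {
  x <- matrix(bg, m, m)
  for (i in seq_len(m - 1)) x[i, i + 1] <- x[i + 1, i] <- edge_fc
  diag(x) <- 0
  x
}

# Exhaustive minimum-spanning-tree oracle: enumerate all labelled spanning
# trees of the complete graph on m nodes through their Pruefer sequences
# (m^(m-2) trees) and return the minimum total weight.
brute_force_mst_weight <- function(w) {
  m <- nrow(w)
  if (m == 2) return(w[1, 2])
  decode <- function(code) {
    # code: integer vector length m-2 with entries in 1..m
    remaining <- rep(1L, m)
    for (v in code) remaining[v] <- remaining[v] + 1L
    total <- 0
    for (v in code) {
      leaf <- which(remaining == 1L)[1L]
      total <- total + w[leaf, v]
      remaining[leaf] <- 0L
      remaining[v] <- remaining[v] - 1L
    }
    last <- which(remaining == 1L)
    total + w[last[1], last[2]]
  }
  codes <- as.matrix(expand.grid(rep(list(seq_len(m)), m - 2)))
  min(apply(codes, 1, decode))
}

# Independent Spearman oracle: average ranks, then plain Pearson.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# A tiny ground-truth spec: 3 sources with one coupled pair (1, 2).
pair_spec <- function(strength = 0.9, lag = pi / 2, seed = 1L, n = 3L,
                      leaf = 2 / 3, ...) {
  g <- matrix(0, n, n)
  g[1, 2] <- g[2, 1] <- strength
  ground_truth_spec(n, g, lag = lag, target_leaf_fraction = leaf, seed = seed, ...)
}

# Leadfield stub with a prescribed gain (singleton ROIs, dummy geometry).
leadfield_stub <- function(gain, roi_labels = sprintf("roi_%03d", seq_len(ncol(gain))),
                           orientations = NULL) {
  n_src <- ncol(gain)
  if (is.null(orientations)) orientations <- cbind(0, 0, rep(1, n_src))
  structure(
    list(
      gain = gain,
      sensor_positions = cbind(0, 0, rep(1, nrow(gain))),
      source_positions = cbind(0, 0, rep(0.8, n_src)),
      source_orientations = orientations,
      roi_labels = roi_labels
    ),
    class = "leadfield"
  )
}

# Epoch set wrapper around a single channels x samples matrix.
single_epoch_set <- function(x, fs = 160, domain = "sensor", labels = NULL) {
  eegnetcomp:::new_epoch_set(
    array(x, dim = c(nrow(x), ncol(x), 1)), fs,
    domain = domain, channel_labels = labels
  )
}
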