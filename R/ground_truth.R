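# Ground-truth coupling structure for the simulator.
#
# The simulator needs a controllable "true" network whose topology (summarised
# by the MST leaf fraction) can be dialled: trees with a prescribed number of
# leaves are sampled through their Pruefer sequence, whose support determines
# exactly which nodes are internal.

#' Sample a random labelled tree with a target leaf fraction
#'
#' A labelled tree on `n` nodes corresponds one-to-one to a Pruefer sequence of
#' length `n - 2`; the leaves of the tree are precisely the labels absent from
#' the sequence. Choosing which nodes appear (each internal node at least
#' once) therefore fixes the leaf count exactly.
#'
#' @param n number of nodes (>= 3).
#' @param target_leaf_fraction desired fraction of degree-1 nodes; the achieved
#'   leaf count is `clamp(round(f * n), 2, n - 1)`, further reduced when a
#'   degree bound makes the requested leaf count infeasible.
#' @param max_degree optional cap on node degree (>= 3). A tree with degree
#'   bound `d` admits at most `(n (d - 2) + 2) / (d - 1)` leaves.
#' @return 2-column integer matrix of edges (node_i < node_j per row).
#' @export
sample_leaf_tree <- function(n, target_leaf_fraction, max_degree = Inf) {
  n <- check_count(n, "n")
  if (n < 3L) stop_invalid_argument("need n >= 3 nodes to control leaf fraction")
  if (!is.numeric(target_leaf_fraction) || target_leaf_fraction <= 0 ||
      target_leaf_fraction > 1) {
    stop_invalid_argument("target_leaf_fraction must lie in (0, 1]")
  }
  if (max_degree < 3) stop_invalid_argument("max_degree must be at least 3")
  n_leaves <- max(2L, min(n - 1L, as.integer(round(target_leaf_fraction * n))))
  if (is.finite(max_degree)) {
    # a node of degree k appears k - 1 times in the Pruefer sequence; with
    # per-node multiplicity <= d - 1 the n - 2 slots bound the leaf count
    n_leaves <- min(n_leaves, as.integer(floor(
      (n * (max_degree - 2) + 2) / (max_degree - 1)
    )))
  }
  internal <- sample.int(n, n - n_leaves)
  # one slot per internal node; the remaining L - 2 slots are spread with at
  # most max_degree - 2 extras per node so degrees stay within the bound
  pool <- if (is.finite(max_degree)) {
    rep(internal, max_degree - 2L)
  } else {
    sample(internal, n_leaves - 2L, replace = TRUE)
  }
  extra <- if (is.finite(max_degree)) {
    if (n_leaves > 2L) sample(pool, n_leaves - 2L) else integer(0)
  } else {
    pool
  }
  pruefer <- sample(c(internal, extra))
  pruefer_to_tree(pruefer, n)
}

# Decode a Pruefer sequence into the edge list of the labelled tree:
# repeatedly join the smallest unconsumed leaf to the next sequence entry.
pruefer_to_tree <- function(pruefer, n) {
  remaining <- rep(1L, n)
  for (v in pruefer) remaining[v] <- remaining[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_along(pruefer)) {
    v <- pruefer[k]
    leaf <- which(remaining == 1L)[1L]
    edges[k, ] <- c(min(leaf, v), max(leaf, v))
    remaining[leaf] <- 0L
    remaining[v] <- remaining[v] - 1L
  }
  edges[n - 1L, ] <- range(which(remaining == 1L))
  edges
}

#' Sample a ground-truth coupling graph
#'
#' Builds a symmetric coupling adjacency over the sources: a random tree with
#' the requested leaf fraction, optional extra non-tree edges, and per-edge
#' strengths in [0, 1].
#'
#' @param n_sources number of sources (>= 3).
#' @param target_leaf_fraction leaf fraction of the backbone tree.
#' @param strength mean edge strength in [0, 1].
#' @param strength_jitter half-width of the uniform jitter on strengths.
#' @param extra_edges number of additional random edges beyond the tree.
#' @param max_degree optional degree bound for the backbone tree.
#' @param seed integer seed.
#' @return symmetric `n_sources x n_sources` matrix of strengths, zero diagonal.
#' @export
sample_coupling_graph <- function(n_sources, target_leaf_fraction = 0.5,
                                  strength = 0.7, strength_jitter = 0.1,
                                  extra_edges = 0L, max_degree = Inf,
                                  seed = NULL) {
  run <- function() {
    edges <- sample_leaf_tree(n_sources, target_leaf_fraction, max_degree)
    if (extra_edges > 0L) {
      all_pairs <- which(upper.tri(matrix(0, n_sources, n_sources)), arr.ind = TRUE)
      key <- paste(edges[, 1], edges[, 2])
      free <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% key), , drop = FALSE]
      pick <- free[sample.int(nrow(free), min(extra_edges, nrow(free))), , drop = FALSE]
      edges <- rbind(edges, pick)
    }
    g <- matrix(0, n_sources, n_sources)
    s <- pmin(1, pmax(0, strength + runif(nrow(edges), -strength_jitter, strength_jitter)))
    g[edges] <- s
    g[edges[, c(2, 1), drop = FALSE]] <- s
    g
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Specify the ground truth of one simulated recording
#'
#' Bundles everything `simulate_sources()` needs: the phase-coupling graph with
#' per-edge strengths and lags, the amplitude-coupling graph, the oscillator
#' band parameters, and the condition tag.
#'
#' @param n_sources number of sources.
#' @param coupling_graph symmetric matrix of phase-coupling strengths in
#'   [0, 1], zero diagonal.
#' @param lag per-edge phase lag in radians: either a scalar applied to every
#'   edge (i < j locks at `phase_j - phase_i = lag`) or a full antisymmetric
#'   matrix.
#' @param center_frequency oscillator center frequency in Hz.
#' @param amplitude_coupling_graph symmetric matrix of envelope-coupling
#'   strengths; defaults to `coupling_graph`.
#' @param phase_noise_sd phase diffusion (radians per sqrt-second).
#' @param freq_jitter_sd per-source natural-frequency spread (Hz).
#' @param condition_label condition tag, e.g. `"EC"` or `"EO"`.
#' @param target_leaf_fraction leaf fraction the coupling backbone was built
#'   with (book-keeping; used for cohort jitter and recoverability checks).
#' @param seed integer seed consumed by `simulate_sources()`.
#' @return object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(n_sources,
                              coupling_graph,
                              lag = pi / 4,
                              center_frequency = 10,
                              amplitude_coupling_graph = coupling_graph,
                              phase_noise_sd = 2,
                              freq_jitter_sd = 0.5,
                              condition_label = "EC",
                              target_leaf_fraction = 0.5,
                              seed = 1L) {
  n_sources <- check_count(n_sources, "n_sources")
  validate_coupling <- function(g, name) {
    if (!is.matrix(g) || !all(dim(g) == n_sources)) {
      stop_invalid_argument(sprintf("`%s` must be %d x %d", name, n_sources, n_sources))
    }
    check_finite(g, name)
    if (max(abs(g - t(g))) > 1e-12) stop_invalid_argument(sprintf("`%s` must be symmetric", name))
    if (any(diag(g) != 0)) stop_invalid_argument(sprintf("`%s` must have zero diagonal", name))
    if (any(g < 0 | g > 1)) stop_invalid_argument(sprintf("`%s` strengths must lie in [0, 1]", name))
    g
  }
  coupling_graph <- validate_coupling(coupling_graph, "coupling_graph")
  amplitude_coupling_graph <- validate_coupling(amplitude_coupling_graph, "amplitude_coupling_graph")
  if (length(lag) == 1L) {
    lag_mat <- matrix(0, n_sources, n_sources)
    lag_mat[upper.tri(lag_mat)] <- lag
    lag_mat <- lag_mat - t(lag_mat)
  } else {
    lag_mat <- lag
    if (!is.matrix(lag_mat) || !all(dim(lag_mat) == n_sources) ||
        max(abs(lag_mat + t(lag_mat))) > 1e-12) {
      stop_invalid_argument("`lag` must be a scalar or an antisymmetric matrix")
    }
  }
  if (n_sources >= 3 &&
      (target_leaf_fraction < 2 / n_sources || target_leaf_fraction > (n_sources - 1) / n_sources)) {
    stop_invalid_argument("target_leaf_fraction outside [2/M, (M-1)/M]")
  }
  structure(
    list(
      n_sources = n_sources,
      coupling_graph = coupling_graph,
      lag = lag_mat,
      center_frequency = center_frequency,
      amplitude_coupling_graph = amplitude_coupling_graph,
      phase_noise_sd = phase_noise_sd,
      freq_jitter_sd = freq_jitter_sd,
      condition_label = condition_label,
      target_leaf_fraction = target_leaf_fraction,
      seed = as.integer(seed)
    ),
    class = "ground_truth_spec"
  )
}

#' @export
print.ground_truth_spec <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_spec> %d sources, %d coupled pairs, f0 = %g Hz, condition %s\n",
    x$n_sources, sum(x$coupling_graph[upper.tri(x$coupling_graph)] > 0),
    x$center_frequency, x$condition_label
  ))
  invisible(x)
}
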