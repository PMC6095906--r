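# Minimum spanning tree backbone and global topology descriptors.
#
# Connectivity values live in [0, 1] with high = strongly coupled, so weights
# are inverted (1 - FC) before the MST: the tree keeps the strongest
# connections. Ties are broken deterministically by (weight, smaller node
# index, larger node index).

#' Minimum spanning tree of a connectivity matrix
#'
#' Builds the spanning tree minimizing the total inverted weight
#' `sum(1 - FC)` over its edges (equivalently maximizing total FC) with
#' Kruskal's algorithm and a deterministic lexicographic tie-break.
#'
#' @param m symmetric connectivity matrix with values in [0, 1] (the usual
#'   output of [connectivity_matrix()]).
#' @return object of class `spanning_tree`: `n_nodes`, `edges` (`(M-1) x 2`
#'   node-index matrix), `edge_weights` (original FC values), `degree`,
#'   `node_labels`.
#' @export
build_mst <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2) {
    stop_invalid_argument("`m` must be a square matrix with >= 2 nodes")
  }
  if (!all(is.finite(m[upper.tri(m)]))) {
    abort("connectivity matrix has non-finite weights", "invalid_matrix")
  }
  n <- nrow(m)
  edges <- kruskal_mst(1 - m)
  degree <- tabulate(edges, nbins = n)
  structure(
    list(
      n_nodes = n,
      edges = edges,
      edge_weights = m[edges],
      degree = degree,
      node_labels = rownames(m)
    ),
    class = "spanning_tree"
  )
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf(
    "<spanning_tree> %d nodes, %d edges, leaf fraction %.3f\n",
    x$n_nodes, nrow(x$edges), leaf_fraction(x)
  ))
  invisible(x)
}

check_tree <- function(t, min_nodes = 2L) {
  stopifnot(inherits(t, "spanning_tree"))
  if (t$n_nodes < min_nodes) {
    stop_invalid_argument(sprintf("descriptor requires at least %d nodes", min_nodes))
  }
  t
}

#' Leaf fraction of a spanning tree
#'
#' Number of degree-1 nodes divided by the total number of nodes; high values
#' indicate a star-like, hub-dominated backbone.
#'
#' @param t a `spanning_tree`.
#' @return fraction in `[2/M, (M-1)/M]`.
#' @export
leaf_fraction <- function(t) {
  check_tree(t)
  sum(t$degree == 1L) / t$n_nodes
}

#' Diameter of a spanning tree
#'
#' Largest hop distance between any two nodes (unweighted shortest paths),
#' computed with the two-sweep breadth-first search that is exact on trees.
#'
#' @param t a `spanning_tree`.
#' @return diameter in hops.
#' @export
tree_diameter <- function(t) {
  check_tree(t)
  tree_stats(t$edges, t$n_nodes)$diameter
}

#' Degree divergence (kappa) of a spanning tree
#'
#' Broadness of the degree distribution, `<k^2> / <k>`; large for
#' hub-dominated trees (star: `(M^2 - M + ...)`), minimal for paths.
#'
#' @param t a `spanning_tree`.
#' @return kappa >= 1.
#' @export
tree_kappa <- function(t) {
  check_tree(t)
  sum(t$degree^2) / sum(t$degree)
}

#' Tree hierarchy of a spanning tree
#'
#' `L / (2 m BC_max)` with `L` the leaf count, `m = M - 1` edges and `BC_max`
#' the maximum normalized betweenness centrality (pair counts divided by
#' `(M-1)(M-2)/2`). Balances network integration against hub overload.
#'
#' @param t a `spanning_tree` with at least 3 nodes.
#' @return hierarchy in [0, 1].
#' @export
tree_hierarchy <- function(t) {
  check_tree(t, min_nodes = 3L)
  st <- tree_stats(t$edges, t$n_nodes)
  bc_max <- st$bc_max_raw / choose(t$n_nodes - 1, 2) # normalized pair counts
  sum(t$degree == 1L) / (2 * (t$n_nodes - 1) * bc_max)
}

#' All global MST descriptors of a connectivity matrix or tree
#'
#' @param x a `spanning_tree` or a symmetric connectivity matrix (which is
#'   first passed through [build_mst()]).
#' @return named list: `leaf_fraction`, `diameter`, `diameter_normalized`
#'   (`diameter / (M - 1)`), `kappa`, `hierarchy`.
#' @export
tree_metrics <- function(x) {
  t <- if (inherits(x, "spanning_tree")) x else build_mst(x)
  st <- tree_stats(t$edges, t$n_nodes)
  m <- t$n_nodes
  list(
    leaf_fraction = sum(t$degree == 1L) / m,
    diameter = st$diameter,
    diameter_normalized = st$diameter / (m - 1),
    kappa = sum(t$degree^2) / sum(t$degree),
    hierarchy = if (m >= 3) {
      sum(t$degree == 1L) / (2 * (m - 1) * (st$bc_max_raw / choose(m - 1, 2)))
    } else {
      NA_real_
    }
  )
}

#' Write a spanning tree as a plain-text edge list
#'
#' @param t a `spanning_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree_edges <- function(t, path) {
  stopifnot(inherits(t, "spanning_tree"))
  lab <- if (is.null(t$node_labels)) as.character(seq_len(t$n_nodes)) else t$node_labels
  df <- data.frame(
    node_i = lab[t$edges[, 1]], node_j = lab[t$edges[, 2]],
    fc_weight = t$edge_weights
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
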