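## Order-d adjacency projections -------------------------------------------

#' Node-by-hyperedge incidence matrix of one snapshot at one order
#'
#' Builds `E` with one column per order-`d` hyperedge of the snapshot
#' (columns in lexicographic order of the sorted node tuples); entry
#' `(i, alpha)` is 1 iff node `i` belongs to hyperedge `alpha`.
#'
#' @param snapshot list of hyperedges (integer vectors).
#' @param d order to select.
#' @param num_nodes number of nodes `N`.
#' @return an `N x m` binary matrix (possibly zero columns).
#' @export
build_incidence <- function(snapshot, d, num_nodes) {
  if (!is_count(d, min = 2L)) hm_input_error("order d must be an integer >= 2")
  snapshot <- canonical_snapshot(snapshot)
  sel <- snapshot[vapply(snapshot, length, integer(1)) == d]
  for (e in sel) {
    if (any(e < 1L) || any(e > num_nodes)) {
      hm_input_error(sprintf(
        "hyperedge {%s} uses node ids outside 1..%d", edge_key(e), num_nodes
      ))
    }
  }
  E <- matrix(0L, nrow = num_nodes, ncol = length(sel))
  for (a in seq_along(sel)) E[sel[[a]], a] <- 1L
  E
}

#' Project one snapshot's order-d hyperedges onto a node adjacency matrix
#'
#' Returns `A = E E^T` with the diagonal zeroed, so the off-diagonal entry
#' `(i, j)` counts the order-`d` hyperedges containing both `i` and `j`.
#'
#' @inheritParams build_incidence
#' @return symmetric `N x N` integer matrix with zero diagonal.
#' @export
project_adjacency <- function(snapshot, d, num_nodes) {
  E <- build_incidence(snapshot, d, num_nodes)
  A <- E %*% t(E)
  diag(A) <- 0L
  storage.mode(A) <- "integer"
  A
}

#' Adjacency sequence of one order, with its annealed average
#'
#' Applies [project_adjacency()] to every snapshot and stores the result in
#' flattened form (one row per time step, `N^2` columns in column-major
#' order) together with the annealed matrix `mu`, the element-wise
#' time-average over the full sequence. The flattened layout is an internal
#' convenience; use [adjacency_at()] for the `N x N` matrix at one step.
#'
#' @param th a `temporal_hypergraph`.
#' @param d order, `2 <= d <= max_order`.
#' @return an object of class `adjacency_sequence` with fields `order`, `n`,
#'   `t_len`, `flat` (`T x N^2` integer matrix) and `annealed` (`N x N`).
#' @export
adjacency_sequence <- function(th, d) {
  stopifnot(inherits(th, "temporal_hypergraph"))
  if (!is_count(d, min = 2L) || d > th$max_order) {
    hm_input_error(sprintf("order d must lie in 2..%d", th$max_order))
  }
  n <- th$num_nodes
  t_len <- num_steps(th)
  # pair-position templates: for a sorted d-tuple v, the co-membership pairs
  tpl <- utils::combn(d, 2L)
  flat <- matrix(0L, nrow = t_len, ncol = n * n)
  for (t in seq_len(t_len)) {
    snap <- th$snapshots[[t]]
    for (e in snap) {
      if (length(e) != d) next
      i <- e[tpl[1L, ]]
      j <- e[tpl[2L, ]]
      cols <- c((j - 1L) * n + i, (i - 1L) * n + j)
      flat[t, cols] <- flat[t, cols] + 1L
    }
  }
  structure(
    list(order = as.integer(d), n = n, t_len = t_len,
         flat = flat, annealed = matrix(colMeans(flat), n, n)),
    class = "adjacency_sequence"
  )
}

#' Adjacency matrix of an adjacency sequence at one time step
#' @param seq an `adjacency_sequence`.
#' @param t time index in `1..T`.
#' @return `N x N` integer matrix.
#' @export
adjacency_at <- function(seq, t) {
  stopifnot(inherits(seq, "adjacency_sequence"))
  if (!is_count(t) || t > seq$t_len) hm_input_error("t out of range")
  matrix(seq$flat[t, ], seq$n, seq$n)
}

#' @export
print.adjacency_sequence <- function(x, ...) {
  cat(sprintf("<adjacency_sequence> order %d, N = %d, T = %d, mean link weight %.4f\n",
              x$order, x$n, x$t_len, mean(x$annealed)))
  invisible(x)
}
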