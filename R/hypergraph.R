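## Temporal hypergraphs ----------------------------------------------------

#' Canonicalize a hyperedge
#'
#' A hyperedge is a set of two or more distinct nodes interacting
#' simultaneously; its order is the number of nodes involved. Hyperedges are
#' stored as sorted integer vectors, so two hyperedges compare equal iff their
#' node sets are equal.
#'
#' @param nodes integer vector of node identifiers (1-based).
#' @return sorted integer vector of class-free canonical form.
#' @export
hyperedge <- function(nodes) {
  nodes <- as.integer(nodes)
  if (anyNA(nodes)) hm_input_error("hyperedge nodes must be integers")
  if (anyDuplicated(nodes)) {
    hm_input_error(sprintf(
      "hyperedge {%s} has repeated nodes", paste(nodes, collapse = ",")
    ))
  }
  if (length(nodes) < 2L) {
    hm_input_error("a hyperedge needs at least two nodes (order >= 2)")
  }
  sort(nodes)
}

edge_key <- function(nodes) paste(nodes, collapse = ",")

# Canonicalize one snapshot: a deduplicated, lexicographically ordered list
# of canonical hyperedges.
canonical_snapshot <- function(edges) {
  if (length(edges) == 0L) return(list())
  edges <- lapply(edges, hyperedge)
  keys <- vapply(edges, edge_key, character(1))
  edges <- edges[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  ord <- order(vapply(edges, length, integer(1)),
               vapply(edges, function(e) paste(sprintf("%09d", e), collapse = ","),
                      character(1)))
  edges[ord]
}

#' Construct a temporal hypergraph
#'
#' A temporal hypergraph is a set of `N` nodes together with a length-`T`
#' sequence of snapshots, each snapshot a set of hyperedges (node subsets of
#' size 2..`D`). Empty snapshots are allowed and are meaningful: the lag
#' `tau` of every correlation estimator counts time steps, not events.
#'
#' @param snapshots list of length `T`; each element a list of hyperedges
#'   (integer vectors). Duplicated hyperedges within a snapshot are collapsed.
#' @param num_nodes number of nodes `N`; node ids must lie in `1..N`.
#' @param max_order maximum order `D`; defaults to the largest order present
#'   (at least 2).
#' @param labels optional character vector of length `N` with external node
#'   labels (kept for file round-trips).
#' @param times optional numeric vector of length `T` with the original
#'   timestamps of the snapshots.
#' @return an object of class `temporal_hypergraph`.
#' @export
temporal_hypergraph <- function(snapshots, num_nodes, max_order = NULL,
                                labels = NULL, times = NULL) {
  if (!is.list(snapshots) || length(snapshots) < 1L) {
    hm_input_error("snapshots must be a non-empty list (T >= 1)")
  }
  if (!is_count(num_nodes)) hm_input_error("num_nodes must be a positive integer")
  num_nodes <- as.integer(num_nodes)
  snapshots <- lapply(snapshots, canonical_snapshot)
  orders <- unlist(lapply(snapshots, function(s) vapply(s, length, integer(1))))
  obs_max <- if (length(orders)) max(orders) else 2L
  if (is.null(max_order)) max_order <- max(2L, obs_max)
  if (!is_count(max_order, min = 2L)) {
    hm_input_error("max_order must be an integer >= 2")
  }
  max_order <- as.integer(max_order)
  if (length(orders) && obs_max > max_order) {
    hm_input_error(sprintf(
      "hyperedge of order %d exceeds max_order %d", obs_max, max_order
    ))
  }
  for (s in snapshots) {
    for (e in s) {
      if (any(e < 1L) || any(e > num_nodes)) {
        hm_input_error(sprintf(
          "hyperedge {%s} uses node ids outside 1..%d",
          edge_key(e), num_nodes
        ))
      }
    }
  }
  if (!is.null(labels) && length(labels) != num_nodes) {
    hm_input_error("labels must have length num_nodes")
  }
  if (!is.null(times) && length(times) != length(snapshots)) {
    hm_input_error("times must have length T")
  }
  structure(
    list(num_nodes = num_nodes, max_order = max_order,
         snapshots = snapshots, labels = labels, times = times),
    class = "temporal_hypergraph"
  )
}

#' @export
print.temporal_hypergraph <- function(x, ...) {
  m <- vapply(x$snapshots, length, integer(1))
  cat(sprintf(
    "<temporal_hypergraph> N = %d nodes, D = %d, T = %d snapshots\n",
    x$num_nodes, x$max_order, length(x$snapshots)
  ))
  cat(sprintf("  hyperedges per snapshot: mean %.2f, max %d\n",
              mean(m), if (length(m)) max(m) else 0L))
  tab <- order_counts(x)
  for (d in names(tab)) {
    cat(sprintf("  order %s: %d hyperedge events\n", d, tab[[d]]))
  }
  invisible(x)
}

#' Number of time steps of a temporal hypergraph
#' @param th a `temporal_hypergraph`.
#' @return integer `T`.
#' @export
num_steps <- function(th) {
  stopifnot(inherits(th, "temporal_hypergraph"))
  length(th$snapshots)
}

# Total hyperedge events per order across all snapshots (named by order).
order_counts <- function(th) {
  orders <- unlist(lapply(th$snapshots, function(s) vapply(s, length, integer(1))))
  if (!length(orders)) return(integer(0))
  tab <- table(orders)
  stats::setNames(as.integer(tab), names(tab))
}

## Hyperedge event files ---------------------------------------------------

#' Read a hyperedge event file
#'
#' One line per (time, hyperedge): `t<TAB>n1,n2,...,nk` with nodes
#' comma-separated; any whitespace is accepted between the two fields and
#' `#` starts a comment. Node labels are mapped to dense integer ids 1..N
#' (numeric labels are sorted numerically, otherwise lexicographically);
#' the original labels are preserved in the returned object.
#'
#' @param path path to the event file.
#' @param fill_gaps materialize missing timestamps as empty snapshots
#'   (default `TRUE`), so that a lag of `tau` means `tau` time steps on the
#'   original grid rather than `tau` recorded events.
#' @param max_order optional cap `D`; defaults to the largest order present.
#' @return a [temporal_hypergraph()].
#' @export
read_hyperedge_events <- function(path, fill_gaps = TRUE, max_order = NULL) {
  if (is.null(path) || !length(path)) hm_input_error("no input path given")
  if (!file.exists(path)) hm_input_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) hm_input_error(sprintf("no events in file: %s", path))
  ts <- numeric(length(keep))
  nodes_raw <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    parts <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(parts) != 2L) {
      hm_input_error(sprintf("line %d of %s: expected 't n1,n2,...'", ln, path))
    }
    tval <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(tval)) {
      hm_input_error(sprintf("line %d of %s: bad timestamp '%s'", ln, path, parts[1]))
    }
    ts[k] <- tval
    nodes_raw[[k]] <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
  }
  all_labels <- unique(unlist(nodes_raw))
  num_lab <- suppressWarnings(as.numeric(all_labels))
  labels <- if (!anyNA(num_lab)) all_labels[order(num_lab)] else sort(all_labels)
  ids <- lapply(nodes_raw, function(v) match(v, labels))
  grid <- densify_times(ts, fill_gaps)
  snapshots <- rep(list(list()), length(grid$times))
  slot <- grid$index
  for (k in seq_along(ids)) {
    snapshots[[slot[k]]] <- c(snapshots[[slot[k]]], list(ids[[k]]))
  }
  temporal_hypergraph(snapshots, num_nodes = length(labels),
                      max_order = max_order, labels = labels,
                      times = grid$times)
}

# Map raw timestamps onto a dense 1..T index. With fill_gaps the grid is the
# arithmetic sequence from min(t) to max(t) with step = gcd of the observed
# differences; otherwise only observed timestamps become snapshots.
densify_times <- function(ts, fill_gaps) {
  ut <- sort(unique(ts))
  if (!fill_gaps || length(ut) == 1L) {
    return(list(times = ut, index = match(ts, ut)))
  }
  d <- diff(ut)
  step <- Reduce(gcd_int, d)
  times <- seq(ut[1], ut[length(ut)], by = step)
  list(times = times, index = as.integer(round((ts - ut[1]) / step)) + 1L)
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 1e-9) { r <- a %% b; a <- b; b <- r }
  a
}

#' Write a hyperedge event file
#'
#' Inverse of [read_hyperedge_events()]: writes `t<TAB>n1,n2,...` lines,
#' using the stored labels and original timestamps when present. Empty
#' snapshots produce no lines (their timestamps are recovered on re-read
#' via gap filling).
#'
#' @param th a `temporal_hypergraph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hyperedge_events <- function(th, path) {
  stopifnot(inherits(th, "temporal_hypergraph"))
  times <- if (!is.null(th$times)) th$times else seq_along(th$snapshots) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_along(th$snapshots)) {
    for (e in th$snapshots[[t]]) {
      lab <- if (!is.null(th$labels)) th$labels[e] else as.character(e)
      writeLines(sprintf("%s\t%s", format(times[t], scientific = FALSE),
                         paste(lab, collapse = ",")), con)
    }
  }
  invisible(path)
}
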