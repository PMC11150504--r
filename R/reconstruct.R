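## Clique promotion: pairwise contact streams -> temporal hypergraphs ------

#' Read a pairwise contact stream
#'
#' Parses SocioPatterns-style event lists: one record `t i j` per line
#' (whitespace, tab or comma separated; extra columns ignored; `#` starts a
#' comment). Records are undirected -- `(t, i, j)` and `(t, j, i)` collapse
#' to one contact -- and exact duplicates are dropped. Node labels are
#' mapped to dense integer ids (numeric labels sorted numerically).
#'
#' @param path input file.
#' @param resolution nominal step between frames in timestamp units
#'   (e.g. 20 for 20-second proximity data); raw timestamps are regularized
#'   by integer division.
#' @return an object of class `contact_stream` with fields `records`
#'   (data frame `time, i, j` on the regularized grid, `i < j`), `labels`,
#'   and `resolution`.
#' @export
read_contact_stream <- function(path, resolution = 1L) {
  if (is.null(path) || !length(path)) hm_input_error("no input path given")
  if (!file.exists(path)) hm_input_error(sprintf("file not found: %s", path))
  if (!is_count(resolution)) hm_input_error("resolution must be a positive integer")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) hm_input_error(sprintf("no contacts in file: %s", path))
  ts <- numeric(length(keep))
  ni <- nj <- character(length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    parts <- strsplit(trimws(lines[ln]), "[[:space:],;]+")[[1]]
    if (length(parts) < 3L) {
      hm_input_error(sprintf("line %d of %s: expected 't i j'", ln, path))
    }
    tval <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(tval)) {
      hm_input_error(sprintf("line %d of %s: bad timestamp '%s'", ln, path, parts[1]))
    }
    if (parts[2] == parts[3]) {
      hm_input_error(sprintf("line %d of %s: self-contact %s-%s",
                             ln, path, parts[2], parts[3]))
    }
    ts[k] <- tval
    ni[k] <- parts[2]
    nj[k] <- parts[3]
  }
  all_labels <- unique(c(ni, nj))
  num_lab <- suppressWarnings(as.numeric(all_labels))
  labels <- if (!anyNA(num_lab)) all_labels[order(num_lab)] else sort(all_labels)
  i <- match(ni, labels)
  j <- match(nj, labels)
  lo <- pmin(i, j); hi <- pmax(i, j)
  treg <- floor(ts / resolution)
  df <- unique(data.frame(time = treg, i = lo, j = hi))
  df <- df[order(df$time, df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(records = df, labels = labels,
                 resolution = as.integer(resolution)),
            class = "contact_stream")
}

#' @export
print.contact_stream <- function(x, ...) {
  cat(sprintf("<contact_stream> %d contacts, %d nodes, %d frames\n",
              nrow(x$records), length(x$labels), length(unique(x$records$time))))
  invisible(x)
}

#' Promote the cliques of one contact frame to hyperedges
#'
#' If `d` nodes are pairwise in contact at one time (a clique of the frame
#' graph), they are assumed to interact as one group of size `d`. Only
#' MAXIMAL cliques are promoted: an edge inside a triangle is part of the
#' triad, not additionally a dyad -- promoting every sub-clique would make
#' each group imply all its subgroups and trivialize cross-order structure.
#' Set `all_cliques = TRUE` to promote every clique of size >= 2 instead
#' (sensitivity analysis only).
#'
#' @param edges two-column matrix (or data frame) of undirected node pairs.
#' @param max_order optional cap `D`: maximal cliques larger than `D` are
#'   skipped with a warning, or -- with `split_large = TRUE` -- emitted as
#'   all their size-`D` subsets. `NULL` (default) promotes every maximal
#'   clique whatever its size.
#' @param split_large replace an over-sized clique by its size-`D` subsets.
#' @param all_cliques promote all cliques, not only maximal ones.
#' @param clique_guard abort if one frame yields more than this many
#'   cliques (protection against pathological dense frames).
#' @return list of hyperedges (sorted integer vectors).
#' @export
promote_cliques <- function(edges, max_order = NULL, split_large = FALSE,
                            all_cliques = FALSE, clique_guard = 1e5) {
  edges <- as.matrix(edges)
  if (nrow(edges) == 0L) return(list())
  storage.mode(edges) <- "integer"
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  cl <- if (all_cliques) {
    igraph::cliques(g, min = 2L)
  } else {
    igraph::max_cliques(g, min = 2L)
  }
  if (length(cl) > clique_guard) {
    hm_input_error(sprintf(
      "frame produced %d cliques (> guard %g); refusing to promote",
      length(cl), clique_guard
    ))
  }
  out <- list()
  for (v in cl) {
    nodes <- sort(as.integer(v))
    if (!is.null(max_order) && length(nodes) > max_order) {
      if (split_large) {
        cmb <- utils::combn(nodes, max_order)
        out <- c(out, lapply(seq_len(ncol(cmb)), function(k) cmb[, k]))
      } else {
        warning(sprintf(
          "maximal clique of size %d exceeds max_order %d; skipped (use split_large)",
          length(nodes), max_order
        ))
      }
    } else {
      out <- c(out, list(nodes))
    }
  }
  canonical_snapshot(out)
}

#' Reconstruct a temporal hypergraph from a contact stream
#'
#' Applies [promote_cliques()] frame by frame, densifies the frame
#' timestamps to consecutive snapshot indices and (by default) inserts empty
#' snapshots for frames with no contacts, so that lags count time steps on
#' the original recording grid.
#'
#' @param stream a `contact_stream`.
#' @param max_order,split_large,all_cliques passed to [promote_cliques()].
#' @param fill_gaps insert empty snapshots for missing frames (default
#'   `TRUE`).
#' @return a `temporal_hypergraph` carrying the stream's node labels.
#' @export
reconstruct_hypergraph <- function(stream, max_order = NULL,
                                   split_large = FALSE, all_cliques = FALSE,
                                   fill_gaps = TRUE) {
  stopifnot(inherits(stream, "contact_stream"))
  rec <- stream$records
  grid <- densify_times(rec$time, fill_gaps)
  snaps <- rep(list(list()), length(grid$times))
  for (ft in unique(rec$time)) {
    sel <- rec$time == ft
    slot <- grid$index[which(sel)[1]]
    snaps[[slot]] <- promote_cliques(cbind(rec$i[sel], rec$j[sel]),
                                     max_order = max_order,
                                     split_large = split_large,
                                     all_cliques = all_cliques)
  }
  temporal_hypergraph(snaps, num_nodes = length(stream$labels),
                      max_order = max_order, labels = stream$labels,
                      times = grid$times * stream$resolution)
}
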