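## Synthetic fixtures with planted ground truth ----------------------------

#' Generate a synthetic test input with known ground truth
#'
#' Four kinds of fixture cover the analysis surface without any external
#' data:
#' * `iid_bernoulli` -- every candidate hyperedge active i.i.d. in time with
#'   its order's density: no correlation at any positive lag.
#' * `planted_periodic` -- i.i.d. background plus one chosen hyperedge
#'   active exactly every `period` steps: intra-order autocorrelation peaks
#'   at multiples of the period.
#' * `planted_cross_lag` -- a 2-hyperedge flips a fair coin each step and
#'   its state is copied into a covering 3-hyperedge `lag` steps later, on
#'   top of i.i.d. background: `c^(2,3)(lag)` is large while `c^(3,2)` is
#'   flat, so `delta^(2,3)` peaks exactly at the planted lag.
#' * `contact_stream_toy` -- a pairwise contact stream whose every frame is
#'   a union of vertex-disjoint cliques, with the promoted hypergraph known
#'   by construction.
#'
#' The planted objects are attached as attribute `"truth"` for assertions.
#'
#' @param kind fixture kind (see above).
#' @param num_nodes,max_order,horizon dimensions `N`, `D`, `T`.
#' @param density per-order activity probability of the background (scalar
#'   or one value per order).
#' @param lag planted cross-order lag `L` (planted_cross_lag).
#' @param period planted period `P` (planted_periodic).
#' @param seed integer seed; every fixture is reproducible from its
#'   arguments plus the seed.
#' @return a `temporal_hypergraph`, or a `contact_stream` for
#'   `contact_stream_toy`, with attribute `"truth"`.
#' @export
make_fixture <- function(kind = c("iid_bernoulli", "planted_periodic",
                                  "planted_cross_lag", "contact_stream_toy"),
                         num_nodes = 8L, max_order = 3L, horizon = 200L,
                         density = 0.1, lag = 5L, period = 10L, seed = 1L) {
  kind <- match.arg(kind)
  if (!is_count(num_nodes) || !is_count(max_order, 2L) ||
      num_nodes < max_order || !is_count(horizon)) {
    hm_config_error("need integer N >= D >= 2 and T >= 1")
  }
  orders <- seq(2L, max_order)
  dens <- per_order_param(density, orders, "density")
  switch(kind,
    iid_bernoulli = fixture_iid(num_nodes, max_order, horizon, dens, seed),
    planted_periodic = fixture_periodic(num_nodes, max_order, horizon, dens,
                                        period, seed),
    planted_cross_lag = fixture_cross_lag(num_nodes, max_order, horizon,
                                          dens, lag, seed),
    contact_stream_toy = fixture_contacts(num_nodes, max_order, horizon, seed)
  )
}

# i.i.d. state matrix over all candidate hyperedges
iid_states <- function(edges, dens, horizon) {
  n_e <- length(edges)
  yv <- unname(dens[as.character(vapply(edges, length, integer(1)))])
  matrix(stats::rbinom(horizon * n_e, 1L, rep(yv, each = horizon)),
         nrow = horizon, ncol = n_e)
}

states_to_th <- function(S, edges, num_nodes, max_order) {
  snaps <- lapply(seq_len(nrow(S)), function(t) edges[S[t, ] == 1L])
  temporal_hypergraph(snaps, num_nodes, max_order)
}

fixture_iid <- function(n, d_max, t_len, dens, seed) {
  with_opt_seed(seed, {
    edges <- enumerate_hyperedges(n, d_max)
    th <- states_to_th(iid_states(edges, dens, t_len), edges, n, d_max)
    attr(th, "truth") <- list(kind = "iid_bernoulli", density = dens)
    th
  })
}

fixture_periodic <- function(n, d_max, t_len, dens, period, seed) {
  if (!is_count(period)) hm_config_error("period must be a positive integer")
  with_opt_seed(seed, {
    edges <- enumerate_hyperedges(n, d_max)
    S <- iid_states(edges, dens, t_len)
    planted <- seq_len(d_max)               # the first nodes, order D
    key <- edge_key(planted)
    idx <- which(vapply(edges, edge_key, character(1)) == key)
    S[, idx] <- 0L
    S[seq(1L, t_len, by = period), idx] <- 1L
    th <- states_to_th(S, edges, n, d_max)
    attr(th, "truth") <- list(kind = "planted_periodic", period = period,
                              hyperedge = planted)
    th
  })
}

fixture_cross_lag <- function(n, d_max, t_len, dens, lag, seed) {
  if (d_max < 3L) hm_config_error("planted_cross_lag needs D >= 3")
  if (!is_count(lag) || lag >= t_len) {
    hm_config_error("planted lag must satisfy 1 <= L < T")
  }
  with_opt_seed(seed, {
    edges <- enumerate_hyperedges(n, d_max)
    keys <- vapply(edges, edge_key, character(1))
    S <- iid_states(edges, dens, t_len)
    pair <- c(1L, 2L)
    triple <- c(1L, 2L, 3L)
    i2 <- which(keys == edge_key(pair))
    i3 <- which(keys == edge_key(triple))
    driver <- stats::rbinom(t_len, 1L, 0.5)
    S[, i2] <- driver
    S[, i3] <- 0L
    S[(lag + 1L):t_len, i3] <- driver[seq_len(t_len - lag)]
    th <- states_to_th(S, edges, n, d_max)
    attr(th, "truth") <- list(kind = "planted_cross_lag", lag = lag,
                              pair = pair, triple = triple)
    th
  })
}

fixture_contacts <- function(n, d_max, t_len, seed) {
  with_opt_seed(seed, {
    snaps <- vector("list", t_len)
    contacts <- list()
    for (t in seq_len(t_len)) {
      nodes <- sample.int(n)
      cliques <- list()
      pos <- 1L
      while (pos <= n - 1L) {
        size <- sample(2:d_max, 1L)
        if (pos + size - 1L > n) break
        # leave some frames sparse: each clique kept with prob 0.7
        if (stats::runif(1) < 0.7) {
          cliques <- c(cliques, list(sort(nodes[pos:(pos + size - 1L)])))
        }
        pos <- pos + size
      }
      # anchor the first and last frame so the reconstructed time range
      # matches the ground truth exactly
      if (!length(cliques) && (t == 1L || t == t_len)) {
        cliques <- list(sort(nodes[1:2]))
      }
      snaps[[t]] <- cliques
      for (cq in cliques) {
        prs <- utils::combn(cq, 2L)
        for (k in seq_len(ncol(prs))) {
          contacts <- c(contacts, list(c(t - 1L, prs[1, k], prs[2, k])))
        }
      }
    }
    rec <- if (length(contacts)) {
      as.data.frame(do.call(rbind, contacts)) |> stats::setNames(c("time", "i", "j"))
    } else {
      data.frame(time = integer(), i = integer(), j = integer())
    }
    rec <- rec[order(rec$time, rec$i, rec$j), , drop = FALSE]
    rownames(rec) <- NULL
    stream <- structure(
      list(records = rec, labels = as.character(seq_len(n)), resolution = 1L),
      class = "contact_stream"
    )
    truth_th <- temporal_hypergraph(snaps, n, d_max)
    attr(stream, "truth") <- list(kind = "contact_stream_toy",
                                  hypergraph = truth_th)
    stream
  })
}
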