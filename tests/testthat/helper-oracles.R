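# Independent brute-force oracles. These deliberately avoid the package's
# fast paths (incidence products, flattened elementwise sums): adjacency is
# counted pair by pair, correlations entry by entry from the definition.

oracle_project <- function(snapshot, d, n) {
  A <- matrix(0L, n, n)
  for (e in snapshot) {
    if (length(e) != d) next
    for (a in seq_along(e)) {
      for (b in seq_along(e)) {
        if (a != b) A[e[a], e[b]] <- A[e[a], e[b]] + 1L
      }
    }
  }
  A
}

oracle_adjacency_array <- function(th, d) {
  n <- th$num_nodes
  t_len <- length(th$snapshots)
  arr <- array(0L, c(n, n, t_len))
  for (t in seq_len(t_len)) arr[, , t] <- oracle_project(th$snapshots[[t]], d, n)
  arr
}

# C^(d1,d2)(tau)_ij = sum_t sum_k x1[i,k,t] x2[j,k,t+tau] /
#                     ((T-tau) (d1-1)! (d2-1)!)  with x = A - mu
oracle_cross_matrix <- function(th, d1, d2, tau) {
  a1 <- oracle_adjacency_array(th, d1)
  a2 <- oracle_adjacency_array(th, d2)
  n <- th$num_nodes
  t_len <- dim(a1)[3]
  mu1 <- apply(a1, c(1, 2), mean)
  mu2 <- apply(a2, c(1, 2), mean)
  x1 <- sweep(a1, c(1, 2), mu1)
  x2 <- sweep(a2, c(1, 2), mu2)
  out <- matrix(0, n, n)
  tt <- seq_len(t_len - tau)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (k in seq_len(n)) {
        s <- s + sum(x1[i, k, tt] * x2[j, k, tt + tau])
      }
      out[i, j] <- s
    }
  }
  out / ((t_len - tau) * factorial(d1 - 1) * factorial(d2 - 1))
}

oracle_cross_trace <- function(th, d1, d2, tau) {
  sum(diag(oracle_cross_matrix(th, d1, d2, tau)))
}

oracle_gap <- function(th, d1, d2, tau) {
  s1 <- oracle_cross_trace(th, d1, d1, 0)
  s2 <- oracle_cross_trace(th, d2, d2, 0)
  (oracle_cross_trace(th, d1, d2, tau) - oracle_cross_trace(th, d2, d1, tau)) /
    (2 * sqrt(s1 * s2))
}

oracle_binned <- function(lags, vals, num_bins, scale = "log") {
  keep <- if (scale == "log") lags >= 1 else rep(TRUE, length(lags))
  lags <- lags[keep]; vals <- vals[keep]
  edges <- if (scale == "log") {
    exp(seq(0, log(max(lags)), length.out = num_bins + 1))
  } else {
    seq(min(lags), max(lags), length.out = num_bins + 1)
  }
  res <- NULL
  for (b in seq_len(num_bins)) {
    # the last bin is closed above at the true max lag (exp/log round trips
    # can land edges a hair below it)
    inb <- if (b < num_bins) lags >= edges[b] & lags < edges[b + 1]
           else lags >= edges[b]
    if (!any(inb)) next
    v <- vals[inb]
    res <- rbind(res, data.frame(
      bin_center = if (scale == "log") sqrt(edges[b] * edges[b + 1])
                   else (edges[b] + edges[b + 1]) / 2,
      mean = mean(v),
      std = sqrt(sum((v - mean(v))^2) / length(v)),
      count = sum(inb)
    ))
  }
  res
}

# sample() expands a scalar first argument to 1:x; this never does.
sample1 <- function(x) x[sample.int(length(x), 1L)]

# Random temporal hypergraph: every candidate hyperedge of orders 2..D
# active i.i.d. Bernoulli(dens) per step.
random_th <- function(n = 6, d_max = 3, t_len = 10, dens = 0.2) {
  cand <- enumerate_hyperedges(n, d_max)
  snaps <- lapply(seq_len(t_len), function(t) {
    cand[stats::runif(length(cand)) < dens]
  })
  temporal_hypergraph(snaps, n, d_max)
}

# Per-hyperedge binary state series recovered from snapshots (independent of
# the simulator's keep_states attribute).
states_from_th <- function(th, edges) {
  keys <- vapply(edges, function(e) paste(e, collapse = ","), character(1))
  t(vapply(th$snapshots, function(s) {
    sk <- vapply(s, function(e) paste(e, collapse = ","), character(1))
    as.integer(keys %in% sk)
  }, integer(length(keys))))
}
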