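## DARH / cDARH: discrete autoregressive hypergraph models -----------------
##
## Every candidate hyperedge of order d in {2..D} over N nodes carries a
## binary present/absent state updated each step: with probability 1-q^(d)
## the state is redrawn Bernoulli(y^(d)); with probability q^(d) it is
## copied from memory. In the DARH model memory is the hyperedge's own past
## (a uniformly chosen one of its m_s most recent states). The cross-memory
## variant (cDARH) lets the copy source, with probability p^(d), be the
## recent past of a uniformly chosen OVERLAPPING hyperedge of another order
## d' ~ rho^(d), read back up to m_c^(d',d) steps.

#' Enumerate all candidate hyperedges of orders 2..D over N nodes
#'
#' @param num_nodes number of nodes `N` (>= `max_order`).
#' @param max_order maximum order `D` (>= 2).
#' @return list of sorted integer vectors, ordered by order then
#'   lexicographically; `choose(N, d)` entries per order.
#' @export
enumerate_hyperedges <- function(num_nodes, max_order) {
  if (!is_count(num_nodes) || !is_count(max_order, 2L) || num_nodes < max_order) {
    hm_input_error("need integer N >= D >= 2")
  }
  out <- list()
  for (d in 2:max_order) {
    cmb <- utils::combn(num_nodes, d)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(k) cmb[, k]))
  }
  out
}

#' Overlapping hyperedges of another order
#'
#' The candidates a hyperedge may copy cross-order memory from: for
#' `d_prime < d`, all size-`d_prime` subsets of its nodes
#' (`choose(d, d_prime)` of them); for `d_prime > d`, all size-`d_prime`
#' supersets within the `N` nodes (`choose(N - d, d_prime - d)`).
#'
#' @param alpha a hyperedge (integer vector).
#' @param d_prime target order, different from `length(alpha)`.
#' @param num_nodes number of nodes `N`.
#' @return list of hyperedges (sorted integer vectors).
#' @export
overlapping_candidates <- function(alpha, d_prime, num_nodes) {
  alpha <- hyperedge(alpha)
  d <- length(alpha)
  if (!is_count(d_prime, 2L)) hm_input_error("d_prime must be an integer >= 2")
  if (d_prime == d) hm_input_error("d_prime must differ from the hyperedge's order")
  if (d_prime < d) {
    cmb <- utils::combn(alpha, d_prime)
    lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
  } else {
    others <- setdiff(seq_len(num_nodes), alpha)
    extra <- d_prime - d
    if (length(others) < extra) {
      hm_input_error(sprintf(
        "no order-%d supersets of {%s} exist with N = %d",
        d_prime, edge_key(alpha), num_nodes
      ))
    }
    # combn(x, m) expands a scalar x to 1:x; guard the single-candidate case
    cmb <- if (length(others) == extra) matrix(others, ncol = 1L)
           else utils::combn(others, extra)
    lapply(seq_len(ncol(cmb)), function(k) sort(c(alpha, cmb[, k])))
  }
}

#' Per-hyperedge intra-order memory lengths
#'
#' Independent draws from the discrete Uniform{1, ..., m_s_max}, one per
#' hyperedge, fixed for the whole simulation. Heterogeneous memory lengths
#' turn the single-scale exponential correlation decay of a fixed `m_s` into
#' the slow multi-scale decay seen in empirical contact data.
#'
#' @param m_s_max maximum memory length (>= 1).
#' @param count number of hyperedges.
#' @param seed optional seed (same seed, same lengths).
#' @return integer vector of length `count`.
#' @export
sample_memory_lengths <- function(m_s_max, count, seed = NULL) {
  if (!is_count(m_s_max)) hm_config_error("m_s_max must be an integer >= 1")
  with_opt_seed(seed, runif_int(count, m_s_max))
}

# Expand a scalar or per-order parameter to a named vector over orders 2..D.
per_order_param <- function(x, orders, name, prob = TRUE) {
  if (is.null(x)) return(NULL)
  if (length(x) == 1L && is.null(names(x))) {
    x <- stats::setNames(rep(as.numeric(x), length(orders)), orders)
  } else if (!is.null(names(x))) {
    full <- stats::setNames(rep(NA_real_, length(orders)), orders)
    bad <- setdiff(names(x), as.character(orders))
    if (length(bad)) hm_config_error(sprintf("%s has unknown order(s) %s",
                                             name, paste(bad, collapse = ",")))
    full[names(x)] <- as.numeric(x)
    if (anyNA(full)) hm_config_error(sprintf("%s missing for some order", name))
    x <- full
  } else if (length(x) == length(orders)) {
    x <- stats::setNames(as.numeric(x), orders)
  } else {
    hm_config_error(sprintf("%s must be scalar or one value per order", name))
  }
  if (prob && !all(is_prob(x))) {
    hm_config_error(sprintf("%s must lie in [0, 1]", name))
  }
  if (!prob && !all(x == as.integer(x) & x >= 1)) {
    hm_config_error(sprintf("%s must be positive integers", name))
  }
  x
}

#' Configuration of a DARH / cDARH simulation
#'
#' @param num_nodes number of nodes `N`.
#' @param max_order maximum hyperedge order `D` (`N >= D >= 2`).
#' @param horizon number of output time steps `T`.
#' @param q per-order memory-copy probability `q^(d)` (scalar recycled, or
#'   one value per order 2..D, optionally named by order).
#' @param y per-order Bernoulli activity `y^(d)` -- the stationary
#'   probability that a candidate hyperedge is present.
#' @param p per-order cross-copy probability `p^(d)` (only used by cDARH).
#' @param m_s fixed intra-order memory length per order; mutually exclusive
#'   with `m_s_max`.
#' @param m_s_max per-order maximum for per-hyperedge memory lengths drawn
#'   Uniform{1..m_s_max} once at the start of the simulation.
#' @param m_c cross-order memory lengths: scalar, or a `(D-1) x (D-1)`
#'   matrix with `m_c[d_from, d_to]` = how far order `d_to` reads into the
#'   past of an overlapping order-`d_from` hyperedge (dimnames = orders).
#' @param rho order-selection distribution: named list, one entry per order
#'   `d` with `p^(d) > 0`, each a named probability vector over the source
#'   orders `d' != d`. Default: uniform over `{2..D} \ {d}`.
#' @param seed integer seed (`NULL`: use the session RNG).
#' @param burn_in steps discarded before recording; default 10x the largest
#'   memory length, enough to forget the synthetic i.i.d. history the
#'   buffers are initialised with.
#' @return an object of class `memory_model_config`.
#' @export
memory_model_config <- function(num_nodes, max_order, horizon,
                                q, y, p = 0, m_s = NULL, m_s_max = NULL,
                                m_c = 1L, rho = NULL, seed = NULL,
                                burn_in = NULL) {
  if (!is_count(num_nodes) || !is_count(max_order, 2L) ||
      num_nodes < max_order) {
    hm_config_error("need integer N >= D >= 2")
  }
  if (!is_count(horizon)) hm_config_error("horizon T must be a positive integer")
  orders <- seq(2L, max_order)
  q <- per_order_param(q, orders, "q")
  y <- per_order_param(y, orders, "y")
  p <- per_order_param(p, orders, "p")
  if (!is.null(m_s) && !is.null(m_s_max)) {
    hm_config_error("give either m_s (fixed) or m_s_max (sampled), not both")
  }
  if (is.null(m_s) && is.null(m_s_max)) m_s <- 1L
  m_s <- per_order_param(m_s, orders, "m_s", prob = FALSE)
  m_s_max <- per_order_param(m_s_max, orders, "m_s_max", prob = FALSE)
  if (length(m_c) == 1L) {
    m_c <- matrix(as.integer(m_c), length(orders), length(orders),
                  dimnames = list(orders, orders))
  }
  if (!is.matrix(m_c) || any(dim(m_c) != length(orders)) ||
      is.null(dimnames(m_c))) {
    hm_config_error("m_c must be a scalar or (D-1)x(D-1) matrix with order dimnames")
  }
  if (any(m_c != round(m_c) | m_c < 1)) {
    hm_config_error("m_c entries must be positive integers")
  }
  if (is.null(rho)) {
    rho <- lapply(orders, function(d) {
      others <- setdiff(orders, d)
      if (!length(others)) return(NULL)
      stats::setNames(rep(1 / length(others), length(others)), others)
    })
    names(rho) <- orders
  }
  for (d in orders) {
    if (p[[as.character(d)]] > 0) {
      r <- rho[[as.character(d)]]
      if (is.null(r) || !length(r)) {
        hm_config_error(sprintf(
          "p^(%d) > 0 but no other order exists to copy from (D = %d)",
          d, max_order
        ))
      }
      sup <- as.integer(names(r))
      if (any(sup == d) || any(!sup %in% orders)) {
        hm_config_error(sprintf("rho^(%d) support must be within {2..D} \\ {%d}", d, d))
      }
      if (abs(sum(r) - 1) > 1e-8) {
        hm_config_error(sprintf("rho^(%d) must sum to 1", d))
      }
    }
  }
  n_cand <- sum(choose(num_nodes, orders))
  if (n_cand > 1e5) {
    warning(sprintf(
      "%d candidate hyperedge processes; simulation will be slow and heavy",
      n_cand
    ))
  }
  max_mem <- max(c(m_s, m_s_max, if (any(p > 0)) m_c else 1L), na.rm = TRUE)
  if (is.null(burn_in)) burn_in <- 10L * max_mem
  if (!is_count(burn_in, min = 0L)) hm_config_error("burn_in must be >= 0")
  structure(
    list(num_nodes = as.integer(num_nodes), max_order = as.integer(max_order),
         horizon = as.integer(horizon), q = q, y = y, p = p,
         m_s = m_s, m_s_max = m_s_max, m_c = m_c, rho = rho,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         burn_in = as.integer(burn_in), max_mem = as.integer(max_mem)),
    class = "memory_model_config"
  )
}

#' @export
print.memory_model_config <- function(x, ...) {
  cat(sprintf("<memory_model_config> N = %d, D = %d, T = %d, burn_in = %d\n",
              x$num_nodes, x$max_order, x$horizon, x$burn_in))
  cat("  q:", paste(sprintf("%s=%.3g", names(x$q), x$q), collapse = " "), "\n")
  cat("  y:", paste(sprintf("%s=%.3g", names(x$y), x$y), collapse = " "), "\n")
  cat("  p:", paste(sprintf("%s=%.3g", names(x$p), x$p), collapse = " "), "\n")
  if (!is.null(x$m_s)) cat("  m_s (fixed):",
    paste(sprintf("%s=%d", names(x$m_s), x$m_s), collapse = " "), "\n")
  if (!is.null(x$m_s_max)) cat("  m_s_max (sampled per hyperedge):",
    paste(sprintf("%s=%d", names(x$m_s_max), x$m_s_max), collapse = " "), "\n")
  invisible(x)
}

#' Read a simulation configuration from JSON
#'
#' Keys: `N, D, T, seed, burn_in`; `q, y, p` scalars or maps keyed by order;
#' `m_s` or `m_s_max` likewise; `m_c` a scalar or a map keyed
#' `"d_from,d_to"`; `rho` a map of maps.
#'
#' @param path JSON file.
#' @return a [memory_model_config()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) hm_input_error(sprintf("config not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("N", "D", "T", "q", "y")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    hm_config_error(sprintf("config missing key(s): %s", paste(miss, collapse = ",")))
  }
  orders <- seq(2L, cfg$D)
  m_c <- 1L
  if (!is.null(cfg[["m_c"]])) {
    mc_raw <- cfg[["m_c"]]
    if (length(mc_raw) == 1L && is.null(names(mc_raw))) {
      m_c <- as.integer(mc_raw)
    } else {
      m_c <- matrix(1L, length(orders), length(orders),
                    dimnames = list(orders, orders))
      for (k in names(mc_raw)) {
        dd <- strsplit(k, ",", fixed = TRUE)[[1]]
        m_c[dd[1], dd[2]] <- as.integer(mc_raw[[k]])
      }
    }
  }
  to_named <- function(x) {
    if (is.null(x) || is.null(names(x))) x else unlist(x)
  }
  # [[ ]] throughout: $ would partial-match m_s to m_s_max
  rho <- if (is.null(cfg[["rho"]])) NULL else lapply(cfg[["rho"]], unlist)
  memory_model_config(
    num_nodes = cfg[["N"]], max_order = cfg[["D"]], horizon = cfg[["T"]],
    q = to_named(cfg[["q"]]), y = to_named(cfg[["y"]]),
    p = if (is.null(cfg[["p"]])) 0 else to_named(cfg[["p"]]),
    m_s = to_named(cfg[["m_s"]]), m_s_max = to_named(cfg[["m_s_max"]]),
    m_c = m_c, rho = rho, seed = cfg[["seed"]], burn_in = cfg[["burn_in"]]
  )
}

#' Reference cDARH demonstration configuration
#'
#' The parameter set used throughout the package to demonstrate cross-order
#' memory: `N = 10` nodes, orders up to `D = 3`, `T = 30000` steps;
#' 2-hyperedges evolve independently (`p^(2) = 0`) while 3-hyperedges copy,
#' on 60% of their memory updates, from the past 60 states of an overlapping
#' 2-hyperedge (`p^(3) = 0.6`, `m_c^(2,3) = 60`); intra-order memory lengths
#' are drawn per hyperedge uniformly up to 40 (order 2) and 10 (order 3).
#' The memory strength `q^(d) = 0.8` and activity `y^(d) = 0.2` put the
#' model in the strongly correlated, sparse regime. In this setting the
#' cross-order gap `delta^(2,3)(tau)` is positive across the probed lag
#' range: pairs lead triads, as in empirical face-to-face data.
#'
#' @param seed integer seed.
#' @param horizon number of steps (default 30000).
#' @return a [memory_model_config()].
#' @export
cdarh_reference_config <- function(seed = 1L, horizon = 30000L) {
  memory_model_config(
    num_nodes = 10L, max_order = 3L, horizon = horizon,
    q = 0.8, y = 0.2,
    p = c(`2` = 0, `3` = 0.6),
    m_s_max = c(`2` = 40L, `3` = 10L),
    m_c = matrix(c(1L, 1L, 60L, 1L), 2, 2, dimnames = list(2:3, 2:3)),
    seed = seed
  )
}

## Simulation engine --------------------------------------------------------

# Shared synchronous engine. All hyperedges update at step t from the
# histories as of the end of step t-1; copies always read lags >= 1, i.e.
# strictly past states. Histories start with max_mem i.i.d. Bernoulli(y)
# rows, and `burn_in` further steps are simulated and discarded.
simulate_engine <- function(config, cross, keep_states = FALSE) {
  stopifnot(inherits(config, "memory_model_config"))
  with_opt_seed(config$seed, {
    n_nodes <- config$num_nodes
    orders <- seq(2L, config$max_order)
    edges <- enumerate_hyperedges(n_nodes, config$max_order)
    n_e <- length(edges)
    ord <- vapply(edges, length, integer(1))
    och <- as.character(ord)
    qv <- unname(config$q[och])
    yv <- unname(config$y[och])
    pv <- if (cross) unname(config$p[och]) else rep(0, n_e)
    # intra-order memory length per hyperedge
    msv <- if (!is.null(config$m_s)) {
      unname(config$m_s[och])
    } else {
      mx <- unname(config$m_s_max[och])
      runif_int(n_e, mx)
    }
    # cross-memory plumbing
    use_cross <- which(pv > 0)
    cand <- NULL
    if (length(use_cross)) {
      key_of <- vapply(edges, edge_key, character(1))
      gidx <- stats::setNames(seq_len(n_e), key_of)
      cand <- list()
      for (d in unique(ord[use_cross])) {
        ii <- which(ord == d)
        sup <- as.integer(names(config$rho[[as.character(d)]]))
        for (d2 in sup) {
          cnt <- choose(if (d2 < d) d else n_nodes - d,
                        if (d2 < d) d2 else d2 - d)
          raw <- vapply(ii, function(a) {
            cc <- overlapping_candidates(edges[[a]], d2, n_nodes)
            unname(gidx[vapply(cc, edge_key, character(1))])
          }, integer(cnt))
          cand[[paste(d, d2)]] <- if (cnt == 1L) matrix(raw, ncol = 1L) else t(raw)
        }
      }
      row_in_order <- integer(n_e)
      for (d in orders) row_in_order[ord == d] <- seq_len(sum(ord == d))
    }
    buf <- config$max_mem
    total <- buf + config$burn_in + config$horizon
    H <- matrix(0L, nrow = total, ncol = n_e)
    H[seq_len(buf), ] <- stats::rbinom(buf * n_e, 1L, rep(yv, each = buf))
    for (t in (buf + 1L):total) {
      h <- integer(n_e)
      memory <- stats::runif(n_e) < qv
      rnd <- which(!memory)
      if (length(rnd)) h[rnd] <- stats::rbinom(length(rnd), 1L, yv[rnd])
      mem <- which(memory)
      if (length(mem)) {
        go_cross <- mem[stats::runif(length(mem)) < pv[mem]]
        intra <- setdiff(mem, go_cross)
        if (length(intra)) {
          lag <- runif_int(length(intra), msv[intra])
          h[intra] <- H[cbind(t - lag, intra)]
        }
        if (length(go_cross)) {
          for (d in unique(ord[go_cross])) {
            ii <- go_cross[ord[go_cross] == d]
            r <- config$rho[[as.character(d)]]
            sup <- as.integer(names(r))
            dprime <- if (length(sup) == 1L) rep(sup, length(ii)) else
              sample(sup, length(ii), replace = TRUE, prob = r)
            for (d2 in unique(dprime)) {
              jj <- ii[dprime == d2]
              cm <- cand[[paste(d, d2)]]
              beta <- cm[cbind(row_in_order[jj],
                               runif_int(length(jj), ncol(cm)))]
              lag <- runif_int(length(jj), config$m_c[as.character(d2),
                                                      as.character(d)])
              h[jj] <- H[cbind(t - lag, beta)]
            }
          }
        }
      }
      H[t, ] <- h
    }
    keep <- (buf + config$burn_in + 1L):total
    S <- H[keep, , drop = FALSE]
    snaps <- lapply(seq_len(nrow(S)), function(t) edges[S[t, ] == 1L])
    th <- temporal_hypergraph(snaps, n_nodes, config$max_order)
    if (keep_states) {
      attr(th, "states") <- S
      attr(th, "edges") <- edges
    }
    th
  })
}

#' Simulate the DARH model
#'
#' Every candidate hyperedge evolves as an independent discrete
#' autoregressive binary process: `h_t = Q_t h_{t-lag} + (1 - Q_t) Y_t` with
#' `Q_t ~ Bernoulli(q^(d))`, `Y_t ~ Bernoulli(y^(d))` and
#' `lag ~ Uniform{1..m_s^(d)}`. The stationary activity of each hyperedge is
#' `y^(d)` for any `q < 1`; with `m_s = 1` the autocorrelation at lag `tau`
#' is exactly `q^tau` (a DAR(1) process). Cross-copy parameters in the
#' config are ignored.
#'
#' @param config a [memory_model_config()].
#' @param keep_states attach the `T x n_hyperedges` binary state matrix and
#'   the hyperedge list as attributes `"states"` / `"edges"`.
#' @return a `temporal_hypergraph` of `horizon` snapshots.
#' @export
darh_simulate <- function(config, keep_states = FALSE) {
  simulate_engine(config, cross = FALSE, keep_states = keep_states)
}

#' Simulate the cDARH model
#'
#' Extends [darh_simulate()] with cross-order memory: on a memory update
#' (probability `q^(d)`), with probability `p^(d)` the hyperedge copies one
#' of the `m_c^(d',d)` most recent past states of a uniformly chosen
#' overlapping hyperedge of order `d' ~ rho^(d)` instead of its own past.
#' All hyperedges update synchronously from end-of-previous-step histories.
#' With `p = 0` the model is distributionally identical to DARH.
#'
#' @inheritParams darh_simulate
#' @return a `temporal_hypergraph` of `horizon` snapshots.
#' @export
cdarh_simulate <- function(config, keep_states = FALSE) {
  simulate_engine(config, cross = TRUE, keep_states = keep_states)
}
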