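## Time-shuffled null model -------------------------------------------------

#' Reshuffle the time steps of a temporal hypergraph
#'
#' Applies ONE uniformly random permutation to the snapshot sequence: each
#' snapshot moves as a block, so instantaneous co-occurrence across orders is
#' preserved while every temporal correlation is destroyed. The multiset of
#' snapshots -- hence every annealed matrix `mu^(d)` and every variance
#' `sigma^(d)` -- is exactly invariant.
#'
#' @param th a `temporal_hypergraph` with `T >= 2`.
#' @param seed optional integer seed; the same seed always yields the same
#'   permutation. `NULL` uses (and advances) the session RNG.
#' @param per_order if `TRUE`, shuffle each order's sub-sequence with an
#'   independent permutation instead (exploratory variant; breaks
#'   cross-sectional co-occurrence and is NOT the reference null).
#' @return a `temporal_hypergraph`.
#' @export
time_shuffle <- function(th, seed = NULL, per_order = FALSE) {
  stopifnot(inherits(th, "temporal_hypergraph"))
  t_len <- num_steps(th)
  if (t_len < 2L) hm_input_error("time_shuffle needs T >= 2")
  snaps <- with_opt_seed(seed, {
    if (!per_order) {
      th$snapshots[sample.int(t_len)]
    } else {
      orders_of <- function(s) vapply(s, length, integer(1))
      ds <- sort(unique(unlist(lapply(th$snapshots, orders_of))))
      out <- rep(list(list()), t_len)
      for (d in ds) {
        perm <- sample.int(t_len)
        for (t in seq_len(t_len)) {
          part <- th$snapshots[[perm[t]]]
          out[[t]] <- c(out[[t]], part[orders_of(part) == d])
        }
      }
      out
    }
  })
  temporal_hypergraph(snaps, th$num_nodes, th$max_order,
                      labels = th$labels, times = th$times)
}

#' Null-ensemble summary of a correlation statistic
#'
#' Repeats [time_shuffle()] with seeds `seed, seed+1, ..., seed+R-1`,
#' recomputes the requested statistic on each randomized realization, and
#' returns its per-lag mean and standard deviation -- the "null band" against
#' which the observed curve is judged.
#'
#' @param th a `temporal_hypergraph`.
#' @param statistic one of `"intra"`, `"cross"`, `"gap"`.
#' @param orders one order for `"intra"`, a pair `(d1, d2)` otherwise.
#' @param lags integer lags (`tau >= 1` is the interesting range; `tau = 0`
#'   statistics are shuffle-invariant).
#' @param realizations ensemble size `R >= 1`.
#' @param seed base seed for the ensemble.
#' @return an object of class `null_ensemble_summary` with fields `lags`,
#'   `mean`, `std` (population), `realizations`, `seed`, `statistic`,
#'   `orders`, and the `R x length(lags)` matrix `draws`.
#' @export
null_ensemble <- function(th, statistic = c("intra", "cross", "gap"),
                          orders, lags, realizations = 20L, seed = 1L) {
  statistic <- match.arg(statistic)
  if (!is_count(realizations)) hm_input_error("realizations must be >= 1")
  if (statistic == "intra" && length(orders) == 1L) orders <- rep(orders, 2L)
  if (length(orders) != 2L) hm_input_error("orders must give (d1, d2)")
  draws <- matrix(NA_real_, nrow = realizations, ncol = length(lags))
  for (r in seq_len(realizations)) {
    sh <- time_shuffle(th, seed = seed + r - 1L)
    s1 <- adjacency_sequence(sh, orders[1])
    s2 <- if (orders[2] == orders[1]) s1 else adjacency_sequence(sh, orders[2])
    series <- switch(statistic,
      intra = intra_order_function(s1, lags),
      cross = cross_order_function(s1, s2, lags),
      gap   = cross_order_gap(s1, s2, lags)
    )
    draws[r, ] <- series$values
  }
  structure(
    list(lags = as.integer(lags),
         mean = colMeans(draws),
         std = sqrt(colMeans(sweep(draws, 2, colMeans(draws))^2)),
         realizations = as.integer(realizations),
         seed = as.integer(seed), statistic = statistic,
         orders = as.integer(orders), draws = draws),
    class = "null_ensemble_summary"
  )
}

#' @export
print.null_ensemble_summary <- function(x, ...) {
  cat(sprintf(
    "<null_ensemble_summary> %s(%s), R = %d, seed = %d, %d lags\n",
    x$statistic, paste(x$orders, collapse = ","), x$realizations,
    x$seed, length(x$lags)
  ))
  invisible(x)
}

#' Write a null-ensemble summary to CSV (`tau,null_mean,null_std`)
#' @param ns a `null_ensemble_summary`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_null_csv <- function(ns, path) {
  utils::write.csv(
    data.frame(tau = ns$lags, null_mean = ns$mean, null_std = ns$std),
    path, row.names = FALSE
  )
  invisible(path)
}
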