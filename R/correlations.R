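## Intra- and cross-order correlation estimators ---------------------------
##
## All estimators centre each order-d adjacency sequence by its annealed
## matrix mu^(d) (time-average over the FULL sequence -- no per-window
## re-centering) and carry the combinatorial weight 1/(d-1)! per order, so
## that orders of different sizes are comparable: a single d-hyperedge
## contributes (d-1)(d-2)...  pair co-memberships per node row.

# Centred, 1/(d-1)!-scaled flattened sequence (double T x N^2 matrix).
centered_flat <- function(seq) {
  stopifnot(inherits(seq, "adjacency_sequence"))
  x <- seq$flat - matrix(as.vector(seq$annealed), nrow = seq$t_len,
                         ncol = seq$n^2, byrow = TRUE)
  x / factorial(seq$order - 1L)
}

check_lags <- function(lags, t_len, min_lag = 0L) {
  if (!length(lags)) hm_input_error("at least one lag is required")
  if (any(lags != as.integer(lags)) || any(lags < min_lag)) {
    hm_input_error(sprintf("lags must be integers >= %d", min_lag))
  }
  if (any(lags >= t_len)) {
    hm_input_error(sprintf("lag %d out of range (T = %d)", max(lags), t_len))
  }
  if (is.unsorted(lags, strictly = TRUE)) {
    hm_input_error("lags must be strictly increasing")
  }
  as.integer(lags)
}

check_pair <- function(seq1, seq2) {
  if (seq1$n != seq2$n || seq1$t_len != seq2$t_len) {
    hm_input_error("the two adjacency sequences must share N and T")
  }
}

#' Cross-order correlation matrix at one lag
#'
#' The lag-`tau` cross-covariance between the centred adjacency sequences of
#' orders `d1` and `d2`:
#' `sum_t [A1(t)-mu1] [A2(t+tau)-mu2]^T / ((T-tau) (d1-1)! (d2-1)!)`.
#' With `seq1 = seq2` this is the intra-order correlation matrix.
#'
#' @param seq1,seq2 [adjacency_sequence()] objects sharing `N` and `T`.
#' @param lag integer lag `tau`, `0 <= tau <= T-1`.
#' @return real `N x N` matrix.
#' @export
cross_order_matrix <- function(seq1, seq2, lag) {
  check_pair(seq1, seq2)
  lag <- check_lags(lag, seq1$t_len)
  x1 <- centered_flat(seq1)
  x2 <- centered_flat(seq2)
  n <- seq1$n
  t_eff <- seq1$t_len - lag
  acc <- matrix(0, n, n)
  for (t in seq_len(t_eff)) {
    acc <- acc + matrix(x1[t, ], n, n) %*% t(matrix(x2[t + lag, ], n, n))
  }
  acc / t_eff
}

#' Intra-order correlation matrix at one lag
#'
#' @param seq an [adjacency_sequence()].
#' @param lag integer lag `tau`.
#' @return real `N x N` matrix whose diagonal captures hyperedge
#'   autocorrelation and whose off-diagonal terms capture cross-node
#'   correlations within the order.
#' @export
intra_order_matrix <- function(seq, lag) {
  cross_order_matrix(seq, seq, lag)
}

# Scalar traces for a vector of lags, without materialising N x N products:
# tr(X Y^T) = sum_ij X_ij Y_ij, so the trace at lag tau is the mean over t of
# the elementwise product of time-shifted flattened rows.
trace_series <- function(seq1, seq2, lags) {
  x1 <- centered_flat(seq1)
  x2 <- centered_flat(seq2)
  t_len <- seq1$t_len
  vapply(lags, function(tau) {
    t_eff <- t_len - tau
    sum(x1[seq_len(t_eff), , drop = FALSE] *
        x2[seq_len(t_eff) + tau, , drop = FALSE]) / t_eff
  }, numeric(1))
}

new_correlation_series <- function(kind, orders, lags, values, binned = NULL) {
  structure(
    list(kind = kind, orders = as.integer(orders), lags = as.integer(lags),
         values = as.numeric(values), binned = binned),
    class = "correlation_series"
  )
}

#' @export
print.correlation_series <- function(x, ...) {
  lab <- switch(x$kind,
    intra = sprintf("c^(%d)", x$orders[1]),
    cross = sprintf("c^(%d,%d)", x$orders[1], x$orders[2]),
    gap   = sprintf("delta^(%d,%d)", x$orders[1], x$orders[2])
  )
  cat(sprintf("<correlation_series> %s over %d lags [%d..%d]%s\n",
              lab, length(x$lags), min(x$lags), max(x$lags),
              if (!is.null(x$binned)) sprintf(", %d bins", nrow(x$binned)) else ""))
  invisible(x)
}

#' @export
as.data.frame.correlation_series <- function(x, ...) {
  data.frame(tau = x$lags, value = x$values)
}

#' Intra-order correlation function
#'
#' The trace of the intra-order correlation matrix per lag: a scalar measure
#' of how hyperedges of order `d` are autocorrelated at lag `tau`. The value
#' at `tau = 0` is the order's variance `sigma^(d)`.
#'
#' @param seq an [adjacency_sequence()].
#' @param lags strictly increasing integer lags, each `< T`.
#' @return a `correlation_series` of kind `"intra"`.
#' @export
intra_order_function <- function(seq, lags) {
  lags <- check_lags(lags, seq$t_len)
  new_correlation_series("intra", c(seq$order, seq$order), lags,
                         trace_series(seq, seq, lags))
}

#' Cross-order correlation function
#'
#' The trace of [cross_order_matrix()] per lag: how interactions of order
#' `d1` at time `t` correlate with interactions of order `d2` at `t + tau`.
#' Asymmetric in its arguments for `tau > 0`.
#'
#' @inheritParams cross_order_matrix
#' @param lags strictly increasing integer lags, each `< T`.
#' @return a `correlation_series` of kind `"cross"` (or `"intra"` when both
#'   sequences have the same order).
#' @export
cross_order_function <- function(seq1, seq2, lags) {
  check_pair(seq1, seq2)
  lags <- check_lags(lags, seq1$t_len)
  kind <- if (seq1$order == seq2$order) "intra" else "cross"
  new_correlation_series(kind, c(seq1$order, seq2$order), lags,
                         trace_series(seq1, seq2, lags))
}

#' Order variance sigma^(d) = c^(d)(0)
#' @param seq an [adjacency_sequence()].
#' @return non-negative scalar.
#' @export
order_variance <- function(seq) {
  trace_series(seq, seq, 0L)
}

#' Cross-order gap function
#'
#' `delta^(d1,d2)(tau) = (c^(d1,d2)(tau) - c^(d2,d1)(tau)) /
#' (2 sqrt(sigma^(d1) sigma^(d2)))`. A positive value means groups of size
#' `d1` predict groups of size `d2` a lag `tau` later more than the other
#' way around -- a preferred temporal direction of group growth. If either
#' order has zero variance the series is NaN and a warning is raised (never
#' an error, so lag sweeps don't abort).
#'
#' @inheritParams cross_order_function
#' @return a `correlation_series` of kind `"gap"`, antisymmetric in the
#'   order pair and identically 0 at `tau = 0`.
#' @export
cross_order_gap <- function(seq1, seq2, lags) {
  check_pair(seq1, seq2)
  lags <- check_lags(lags, seq1$t_len)
  s1 <- order_variance(seq1)
  s2 <- order_variance(seq2)
  if (s1 <= 0 || s2 <= 0) {
    warning(sprintf(
      "zero variance for order %d or %d: gap is NaN",
      seq1$order, seq2$order
    ))
    return(new_correlation_series("gap", c(seq1$order, seq2$order), lags,
                                  rep(NaN, length(lags))))
  }
  c12 <- trace_series(seq1, seq2, lags)
  c21 <- trace_series(seq2, seq1, lags)
  new_correlation_series("gap", c(seq1$order, seq2$order), lags,
                         (c12 - c21) / (2 * sqrt(s1 * s2)))
}

#' Normalized interaction matrix K(tau)
#'
#' The `(D-1) x (D-1)` matrix with entries
#' `K[d1, d2] = c^(d1,d2)(tau) / (2 sqrt(sigma^(d1) sigma^(d2)))`,
#' summarising all intra- and cross-order correlations at one lag. Rows and
#' columns are labelled by order; entries involving an order with zero
#' variance are NaN (with a warning). At `tau = 0` every diagonal entry with
#' positive variance equals 1/2.
#'
#' @param th a `temporal_hypergraph`.
#' @param lag integer lag `tau < T`.
#' @param orders orders to include (default `2:max_order`).
#' @return an object of class `interaction_matrix` with fields `lag`,
#'   `orders`, `entries`, `variances`.
#' @export
interaction_matrix <- function(th, lag, orders = NULL) {
  stopifnot(inherits(th, "temporal_hypergraph"))
  if (is.null(orders)) orders <- seq(2L, th$max_order)
  lag <- check_lags(lag, num_steps(th))
  seqs <- lapply(orders, function(d) adjacency_sequence(th, d))
  sig <- vapply(seqs, order_variance, numeric(1))
  names(sig) <- orders
  if (any(sig <= 0)) {
    warning(sprintf(
      "zero variance for order(s) %s: NaN entries in K",
      paste(orders[sig <= 0], collapse = ", ")
    ))
  }
  k <- matrix(NaN, length(orders), length(orders),
              dimnames = list(orders, orders))
  for (a in seq_along(orders)) {
    for (b in seq_along(orders)) {
      if (sig[a] > 0 && sig[b] > 0) {
        cab <- trace_series(seqs[[a]], seqs[[b]], lag)
        k[a, b] <- cab / (2 * sqrt(sig[a] * sig[b]))
      }
    }
  }
  structure(
    list(lag = lag, orders = as.integer(orders), entries = k, variances = sig),
    class = "interaction_matrix"
  )
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> K(tau = %d), orders %s\n",
              x$lag, paste(range(x$orders), collapse = "..")))
  print(round(x$entries, 4))
  invisible(x)
}

## Binned averaging ---------------------------------------------------------

#' Bin-average a correlation series
#'
#' Partitions the lag axis into `num_bins` bins -- geometric (log-spaced)
#' edges over `[1, max lag]` by default, matching the double-logarithmic
#' presentation customary for slowly decaying correlation functions -- and
#' reports per bin the mean, the population (1/n) standard deviation and the
#' count of lags. Empty bins are omitted; for log bins the bin centre is the
#' geometric mean of the edges. Non-positive lags are excluded from log
#' binning.
#'
#' @param series a `correlation_series`.
#' @param num_bins number of bins (>= 1).
#' @param scale `"log"` (default) or `"linear"`.
#' @return the series with its `binned` field set to a data frame with
#'   columns `bin_center`, `mean`, `std`, `count`.
#' @export
binned_average <- function(series, num_bins = 10L, scale = c("log", "linear")) {
  stopifnot(inherits(series, "correlation_series"))
  scale <- match.arg(scale)
  if (!is_count(num_bins)) hm_input_error("num_bins must be a positive integer")
  lags <- series$lags
  vals <- series$values
  if (all(is.nan(vals))) hm_input_error("cannot bin an all-NaN series")
  keep <- !is.nan(vals) & (if (scale == "log") lags >= 1L else TRUE)
  lags <- lags[keep]; vals <- vals[keep]
  if (!length(lags)) hm_input_error("no usable lags to bin")
  if (scale == "log") {
    edges <- exp(seq(log(1), log(max(lags)), length.out = num_bins + 1L))
  } else {
    edges <- seq(min(lags), max(lags), length.out = num_bins + 1L)
  }
  # half-open bins [e_k, e_{k+1}), last bin closed
  bin <- findInterval(lags, edges, rightmost.closed = TRUE)
  bin[bin > num_bins] <- num_bins
  rows <- lapply(sort(unique(bin)), function(b) {
    v <- vals[bin == b]
    ctr <- if (scale == "log") sqrt(edges[b] * edges[b + 1L])
           else (edges[b] + edges[b + 1L]) / 2
    data.frame(bin_center = ctr, mean = mean(v),
               std = sqrt(mean((v - mean(v))^2)), count = length(v))
  })
  series$binned <- do.call(rbind, rows)
  series
}

## CSV round-trips ----------------------------------------------------------

#' Write a correlation series to CSV
#'
#' Raw values go to `path` with columns `tau,value`; if the series carries
#' binned averages they go to `binned_path` (default: `path` with a
#' `_binned` suffix) with columns `bin_center,mean,std,count`.
#'
#' @param series a `correlation_series`.
#' @param path output CSV path for the raw series.
#' @param binned_path optional path for the binned CSV.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path, binned_path = NULL) {
  # na = "NaN" so degenerate (zero-variance) series round-trip as NaN
  utils::write.csv(as.data.frame(series), path, row.names = FALSE, na = "NaN")
  if (!is.null(series$binned)) {
    if (is.null(binned_path)) {
      binned_path <- sub("(\\.[^.]+)?$", "_binned\\1", path)
    }
    utils::write.csv(series$binned, binned_path, row.names = FALSE, na = "NaN")
  }
  invisible(path)
}

#' Read a correlation series back from CSV
#' @param path CSV with columns `tau,value`.
#' @param kind,orders metadata to attach (`kind` one of intra/cross/gap).
#' @param binned_path optional binned CSV to attach.
#' @return a `correlation_series`.
#' @export
read_series_csv <- function(path, kind = "intra", orders = c(2L, 2L),
                            binned_path = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("tau", "value") %in% names(df))) {
    hm_input_error(sprintf("%s lacks tau,value columns", path))
  }
  binned <- if (!is.null(binned_path)) utils::read.csv(binned_path) else NULL
  new_correlation_series(kind, orders, df$tau, df$value, binned)
}

#' Write an interaction matrix to CSV (orders as header row and column)
#' @param im an `interaction_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_interaction_csv <- function(im, path) {
  stopifnot(inherits(im, "interaction_matrix"))
  utils::write.csv(im$entries, path, row.names = TRUE)
  invisible(path)
}

#' Read an interaction matrix written by [write_interaction_csv()]
#' @param path CSV path.
#' @param lag lag metadata to attach.
#' @return an `interaction_matrix` (variances unavailable, set to NA).
#' @export
read_interaction_csv <- function(path, lag = NA_integer_) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  orders <- as.integer(rownames(m))
  structure(
    list(lag = lag, orders = orders, entries = m,
         variances = stats::setNames(rep(NA_real_, length(orders)), orders)),
    class = "interaction_matrix"
  )
}
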