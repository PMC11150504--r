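# Frozen two-step instance: one dyad present at t=1, absent at t=2.
two_step_dyad <- function() {
  temporal_hypergraph(list(list(c(1, 2)), list()), 2)
}

test_that("intra-order matrix and function match hand-derived values", {
  s <- adjacency_sequence(two_step_dyad(), 2)
  expect_equal(intra_order_matrix(s, 1), diag(-0.25, 2))
  expect_equal(intra_order_matrix(s, 0), diag(0.25, 2))
  f <- intra_order_function(s, 0:1)
  expect_equal(f$values, c(0.5, -0.5))
  expect_equal(order_variance(s), 0.5)
  # single 3-hyperedge present then absent: the 1/((d-1)!)^2 factor bites
  th3 <- temporal_hypergraph(list(list(c(1, 2, 3)), list()), 3)
  s3 <- adjacency_sequence(th3, 3)
  expect_equal(intra_order_function(s3, 1)$values, -0.375)
  expect_error(intra_order_matrix(s, 2), "out of range")
  expect_error(intra_order_function(s, c(1, 1)), "strictly increasing")
})

test_that("constant sequences have zero correlation", {
  th <- temporal_hypergraph(rep(list(list(c(1, 2), c(1, 3))), 5), 3)
  s <- adjacency_sequence(th, 2)
  for (tau in 0:3) {
    expect_equal(intra_order_matrix(s, tau), matrix(0, 3, 3))
  }
})

test_that("cross-order matrix reduces to intra and vanishes for constant factors", {
  set.seed(21)
  th <- random_th(5, 3, 12, 0.3)
  s2 <- adjacency_sequence(th, 2)
  expect_identical(cross_order_matrix(s2, s2, 2), intra_order_matrix(s2, 2))
  # order-3 part constant in time -> centered factor vanishes
  thc <- temporal_hypergraph(
    lapply(1:6, function(t) {
      c(list(c(1, 2, 3)), if (t %% 2) list(c(1, 2)) else list())
    }), 4)
  sc2 <- adjacency_sequence(thc, 2)
  sc3 <- adjacency_sequence(thc, 3)
  expect_equal(cross_order_matrix(sc2, sc3, 1), matrix(0, 4, 4))
  expect_equal(cross_order_function(sc2, sc3, 1:3)$values, rep(0, 3))
  # mismatched dimensions are rejected
  other <- adjacency_sequence(random_th(4, 2, 12, 0.3), 2)
  expect_error(cross_order_matrix(s2, other, 1), "share N and T")
})

test_that("estimators match the nested-loop oracle on random instances", {
  set.seed(33)
  for (rep in 1:60) {
    n <- sample(3:6, 1)
    d_max <- sample1(2:min(4, n))
    t_len <- sample(4:15, 1)
    th <- random_th(n, d_max, t_len, stats::runif(1, 0.1, 0.5))
    d1 <- sample1(2:d_max)
    d2 <- sample1(2:d_max)
    tau <- sample1(0:(t_len - 2))
    s1 <- adjacency_sequence(th, d1)
    s2 <- adjacency_sequence(th, d2)
    expect_lt(max(abs(cross_order_matrix(s1, s2, tau) -
                      oracle_cross_matrix(th, d1, d2, tau))), 1e-10)
    expect_lt(abs(cross_order_function(s1, s2, tau)$values -
                  oracle_cross_trace(th, d1, d2, tau)), 1e-10)
  }
})

test_that("trace identity at lag zero and gap antisymmetry hold everywhere", {
  set.seed(44)
  for (rep in 1:20) {
    th <- random_th(5, 3, 10, 0.3)
    s2 <- adjacency_sequence(th, 2)
    s3 <- adjacency_sequence(th, 3)
    expect_equal(cross_order_function(s2, s3, 0L)$values,
                 cross_order_function(s3, s2, 0L)$values, tolerance = 1e-12)
    g23 <- cross_order_gap(s2, s3, 0:4)
    g32 <- cross_order_gap(s3, s2, 0:4)
    expect_lt(abs(g23$values[1]), 1e-12)
    expect_equal(g23$values, -g32$values, tolerance = 1e-12)
    expect_lt(abs(g23$values[3] - oracle_gap(th, 2, 3, 2)), 1e-10)
  }
})

test_that("interaction matrix normalizes correctly and flags absent orders", {
  set.seed(55)
  th <- random_th(5, 3, 12, 0.3)
  km <- interaction_matrix(th, 0)
  expect_equal(unname(diag(km$entries)), c(0.5, 0.5))
  km1 <- interaction_matrix(th, 1)
  for (d1 in 2:3) for (d2 in 2:3) {
    expect_equal(
      km1$entries[as.character(d1), as.character(d2)],
      oracle_cross_trace(th, d1, d2, 1) /
        (2 * sqrt(oracle_cross_trace(th, d1, d1, 0) *
                  oracle_cross_trace(th, d2, d2, 0))),
      tolerance = 1e-10
    )
  }
  # an order absent throughout gives a NaN row/column plus a warning
  th2 <- temporal_hypergraph(list(list(c(1, 2)), list()), 2, max_order = 3)
  expect_warning(km2 <- interaction_matrix(th2, 0), "zero variance")
  expect_true(all(is.nan(km2$entries["3", ])))
  expect_true(all(is.nan(km2$entries[, "3"])))
  expect_equal(km2$entries["2", "2"], 0.5)
})

test_that("zero-variance gap warns and returns NaN, never errors", {
  th <- temporal_hypergraph(list(list(c(1, 2)), list()), 2, max_order = 3)
  s2 <- adjacency_sequence(th, 2)
  s3 <- adjacency_sequence(th, 3)
  expect_warning(g <- cross_order_gap(s2, s3, 1L), "zero variance")
  expect_true(all(is.nan(g$values)))
})

test_that("variance is invariant under any permutation of time steps", {
  set.seed(66)
  th <- random_th(5, 3, 12, 0.3)
  s0 <- order_variance(adjacency_sequence(th, 2))
  for (k in 1:5) {
    perm <- sample(num_steps(th))
    thp <- temporal_hypergraph(th$snapshots[perm], th$num_nodes, th$max_order)
    expect_equal(order_variance(adjacency_sequence(thp, 2)), s0,
                 tolerance = 1e-12)
  }
})

test_that("binned averages match an independent recomputation", {
  set.seed(77)
  vals <- cumsum(stats::rnorm(1000))
  series <- hypermem:::new_correlation_series("intra", c(2, 2), 1:1000, vals)
  b1 <- binned_average(series, 1L)
  expect_equal(b1$binned$mean, mean(vals))
  expect_equal(b1$binned$std, stats::sd(vals) * sqrt(999 / 1000))
  expect_equal(b1$binned$count, 1000L)
  const <- hypermem:::new_correlation_series("intra", c(2, 2), 1:50, rep(2, 50))
  expect_equal(binned_average(const, 5L)$binned$std, rep(0, 5))
  b10 <- binned_average(series, 10L)
  expect_equal(b10$binned, oracle_binned(1:1000, vals, 10), tolerance = 1e-12)
  blin <- binned_average(series, 7L, scale = "linear")
  expect_equal(blin$binned, oracle_binned(1:1000, vals, 7, "linear"),
               tolerance = 1e-12)
  nan_series <- hypermem:::new_correlation_series("gap", c(2, 3), 1:5, rep(NaN, 5))
  expect_error(binned_average(nan_series, 2L), "all-NaN")
})

test_that("i.i.d. sequences show no correlation at positive lags", {
  set.seed(88)
  th <- random_th(6, 3, 400, 0.2)
  s <- adjacency_sequence(th, 2)
  f <- intra_order_function(s, 1:50)
  se <- stats::sd(f$values) / sqrt(50)
  expect_lt(abs(mean(f$values)), 3 * se)
})

test_that("series and interaction-matrix CSVs round-trip losslessly", {
  set.seed(99)
  th <- random_th(5, 3, 20, 0.3)
  s2 <- adjacency_sequence(th, 2)
  f <- binned_average(intra_order_function(s2, 1:10), 3L)
  dir <- withr::local_tempdir()
  raw <- file.path(dir, "c2.csv")
  write_series_csv(f, raw)
  binned <- file.path(dir, "c2_binned.csv")
  expect_true(file.exists(binned))
  back <- read_series_csv(raw, "intra", c(2, 2), binned_path = binned)
  expect_equal(back$lags, f$lags)
  expect_equal(back$values, f$values)
  expect_equal(back$binned$mean, f$binned$mean)
  km <- interaction_matrix(th, 1)
  kpath <- file.path(dir, "K.csv")
  write_interaction_csv(km, kpath)
  kback <- read_interaction_csv(kpath, lag = 1L)
  expect_equal(kback$entries, km$entries)
  expect_equal(kback$orders, km$orders)
})
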