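test_that("candidate hyperedge enumeration is complete and ordered", {
  expect_length(Filter(function(e) length(e) == 2, enumerate_hyperedges(10, 2)), 45L)
  expect_length(Filter(function(e) length(e) == 3, enumerate_hyperedges(10, 3)), 120L)
  all3 <- enumerate_hyperedges(3, 3)
  expect_identical(all3, list(c(1L, 2L), c(1L, 3L), c(2L, 3L), c(1L, 2L, 3L)))
  expect_error(enumerate_hyperedges(2, 3), "N >= D")
})

test_that("overlapping candidates are subsets or supersets as ordered", {
  expect_identical(overlapping_candidates(c(1, 2, 3), 2, 5),
                   list(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  sup <- overlapping_candidates(c(1, 2), 3, 10)
  expect_length(sup, 8L)                      # N - 2 triads contain the pair
  expect_true(all(vapply(sup, function(e) all(c(1L, 2L) %in% e), logical(1))))
  expect_identical(overlapping_candidates(c(1, 2), 3, 3), list(c(1L, 2L, 3L)))
  expect_error(overlapping_candidates(c(1, 2), 2, 5), "differ")
})

test_that("per-hyperedge memory lengths are uniform and reproducible", {
  expect_identical(sample_memory_lengths(1, 5, seed = 1), rep(1L, 5))
  x <- sample_memory_lengths(40, 1e4, seed = 2)
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 20.5), 3 * se)
  expect_true(all(x >= 1 & x <= 40))
  expect_identical(x, sample_memory_lengths(40, 1e4, seed = 2))
  expect_error(sample_memory_lengths(0, 5), "m_s_max")
})

test_that("config validation rejects inconsistent parameter sets", {
  expect_error(memory_model_config(5, 3, 10, q = 1.2, y = 0.1), "\\[0, 1\\]")
  expect_error(memory_model_config(5, 3, 10, q = 0.5, y = 0.1, m_s = 0),
               "positive integers")
  expect_error(memory_model_config(5, 3, 10, q = 0.5, y = 0.1,
                                   m_s = 2, m_s_max = 5), "not both")
  expect_error(memory_model_config(5, 2, 10, q = 0.5, y = 0.1, p = 0.5),
               "no other order")
  expect_error(memory_model_config(5, 3, 10, q = 0.5, y = 0.1, p = 0.5,
                                   rho = list(`2` = c(`3` = 0.5), `3` = c(`2` = 1))),
               "sum to 1")
  expect_error(memory_model_config(5, 4, 10, q = c(`2` = 0.1, `3` = 0.2)),
               "missing")
  cfg <- memory_model_config(5, 3, 10, q = 0.5, y = 0.1, p = 0.3,
                             m_s_max = 4, m_c = 6)
  expect_equal(cfg$burn_in, 60L)              # 10 x the largest memory length
  expect_equal(unname(cfg$rho[["2"]]), 1)     # only order 3 to copy from
})

test_that("JSON configs load into equivalent objects", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "N": 10, "D": 3, "T": 50, "seed": 4,
    "q": 0.8, "y": {"2": 0.2, "3": 0.1},
    "p": {"2": 0, "3": 0.6},
    "m_s_max": {"2": 40, "3": 10},
    "m_c": {"2,3": 60}
  }', path)
  cfg <- read_model_config(path)
  expect_equal(cfg$y[["3"]], 0.1)
  expect_equal(cfg$m_c["2", "3"], 60L)
  expect_equal(cfg$m_c["3", "2"], 1L)
  expect_null(cfg$m_s)
  expect_equal(cfg$m_s_max[["2"]], 40)
  th <- cdarh_simulate(cfg)
  expect_equal(num_steps(th), 50L)
  expect_error(read_model_config(withr::local_tempfile()), "not found")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"N": 5}', bad)
  expect_error(read_model_config(bad), "missing key")
})

test_that("DARH degenerate regimes behave as the update rule forces", {
  # q = 1, m_s = 1: every hyperedge frozen at its initial state
  cfg <- memory_model_config(5, 3, 40, q = 1, y = 0.4, m_s = 1, seed = 6)
  th <- darh_simulate(cfg, keep_states = TRUE)
  S <- attr(th, "states")
  expect_true(all(apply(S, 2, function(col) length(unique(col)) == 1L)))
  # q = 0: i.i.d. Bernoulli(y) activity (scaled-down check; the full
  # T = 1e4 marginal test lives in the acceptance suite)
  cfg0 <- memory_model_config(6, 3, 4000, q = 0, y = c(`2` = 0.3, `3` = 0.1),
                              seed = 7)
  th0 <- darh_simulate(cfg0, keep_states = TRUE)
  S0 <- attr(th0, "states")
  ord <- vapply(attr(th0, "edges"), length, integer(1))
  for (d in 2:3) {
    dens <- colMeans(S0[, ord == d, drop = FALSE])
    y_d <- c(`2` = 0.3, `3` = 0.1)[[as.character(d)]]
    se <- stats::sd(dens) / sqrt(length(dens))
    expect_lt(abs(mean(dens) - y_d), 3 * se)
  }
})

test_that("simulations are reproducible from config + seed", {
  cfg <- memory_model_config(6, 3, 100, q = 0.7, y = 0.2, p = 0.4,
                             m_s_max = 5, m_c = 8, seed = 9)
  expect_identical(cdarh_simulate(cfg)$snapshots, cdarh_simulate(cfg)$snapshots)
  expect_identical(darh_simulate(cfg)$snapshots, darh_simulate(cfg)$snapshots)
  cfg2 <- memory_model_config(6, 3, 100, q = 0.7, y = 0.2, p = 0.4,
                              m_s_max = 5, m_c = 8, seed = 10)
  expect_false(identical(cdarh_simulate(cfg)$snapshots,
                         cdarh_simulate(cfg2)$snapshots))
})

test_that("cDARH with p = 0 matches DARH distributionally", {
  dens_of <- function(fun, seed) {
    cfg <- memory_model_config(6, 3, 2000, q = 0.6, y = 0.25, p = 0,
                               m_s = 3, seed = seed)
    th <- fun(cfg, keep_states = TRUE)
    mean(attr(th, "states"))
  }
  da <- vapply(1:6, function(s) dens_of(darh_simulate, s), numeric(1))
  cd <- vapply(101:106, function(s) dens_of(cdarh_simulate, s), numeric(1))
  se <- sqrt(stats::var(da) / 6 + stats::var(cd) / 6)
  expect_lt(abs(mean(da) - mean(cd)), 3 * se + 1e-3)
})

test_that("fixed m_s produces a correlation plateau up to m_s", {
  cfg <- memory_model_config(7, 2, 6000, q = 0.85, y = 0.25, m_s = 10, seed = 12)
  th <- darh_simulate(cfg)
  f <- intra_order_function(adjacency_sequence(th, 2), 1:30)
  expect_gt(mean(f$values[1:10]), mean(f$values[11:30]))
})

test_that("cross-copy states are drawn from the strict past", {
  # m_c = 1, p = 1, q = 1: the 3-hyperedge's state at t is a copy of one of
  # its three 2-subsets' states at exactly t-1 (lag forced to 1).
  rho <- list(`2` = NULL, `3` = c(`2` = 1))
  cfg <- memory_model_config(3, 3, 50, q = c(`2` = 0, `3` = 1),
                             y = c(`2` = 0.5, `3` = 0.5),
                             p = c(`2` = 0, `3` = 1),
                             m_s = 1, m_c = 1, rho = rho, seed = 13,
                             burn_in = 5)
  th <- cdarh_simulate(cfg, keep_states = TRUE)
  S <- attr(th, "states")
  edges <- attr(th, "edges")
  ord <- vapply(edges, length, integer(1))
  i3 <- which(ord == 3)
  pairs <- which(ord == 2)
  for (t in 2:nrow(S)) {
    expect_true(S[t, i3] %in% S[t - 1, pairs])
  }
})
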