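# hypermem

Memory and cross-order correlations in temporal hypergraphs.

## What this is for

Systems whose units interact in *groups* — conversations, meetings, animal
aggregations, co-activating neural assemblies — are poorly served by
temporal-network tools, which only see pairs. `hypermem` represents such a
system as a **temporal hypergraph**: `N` nodes plus a sequence of `T`
snapshots, each a set of hyperedges (node subsets of size `d = 2..D`). It
answers two questions:

1. **How persistent are groups of each size?** Each order `d` is projected
   onto adjacency matrices `A^(d)(t)` (entry `(i,j)` counts the order-`d`
   hyperedges containing both nodes), and the intra-order correlation
   function

   `c^(d)(tau) = tr{ (1/(T-tau)) sum_t [A^(d)(t)-mu^(d)][A^(d)(t+tau)-mu^(d)]^T / ((d-1)!)^2 }`

   measures their autocorrelation at lag `tau`, with `mu^(d)` the
   time-averaged (annealed) matrix and `sigma^(d) = c^(d)(0)`.

2. **Do group sizes lead or follow each other?** The cross-order function
   `c^(d1,d2)(tau)` correlates order `d1` now with order `d2` a lag later;
   its normalized asymmetry, the **cross-order gap**

   `delta^(d1,d2)(tau) = [c^(d1,d2)(tau) - c^(d2,d1)(tau)] / (2 sqrt(sigma^(d1) sigma^(d2)))`,

   is positive when size-`d1` groups anticipate size-`d2` groups more than
   the reverse (e.g. pairs seeding triads). The `(D-1)x(D-1)` normalized
   interaction matrix `K(tau)` collects all order pairs at one lag.

The package also provides:

* **DARH / cDARH simulators** — discrete autoregressive binary processes on
  all candidate hyperedges, with per-order memory strength `q`, activity
  `y`, intra-order memory lengths `m_s` (fixed or per-hyperedge uniform)
  and, in cDARH, cross-order copying from *overlapping* hyperedges
  (probability `p`, reach `m_c`).
* A **time-shuffle null model** (block permutation of snapshots) and
  null-ensemble summaries.
* **Clique promotion**: reconstruction of group interactions from pairwise
  contact streams (`t i j` records, SocioPatterns dialect) by promoting
  maximal cliques of each frame to hyperedges.
* **Fixture generators** with planted ground truth, so everything is
  testable offline.

## Worked example

A fixture plants a 2-hyperedge whose coin-flip activity is copied into a
covering 3-hyperedge 5 steps later; the gap estimator must find that lag.

```r
library(hypermem)
th <- make_fixture("planted_cross_lag", num_nodes = 8, max_order = 3,
                   horizon = 600, density = 0.05, lag = 5, seed = 42)
th
#> <temporal_hypergraph> N = 8 nodes, D = 3, T = 600 snapshots
#>   hyperedges per snapshot: mean 5.30, max 12
#>   order 2: 1122 hyperedge events
#>   order 3: 2060 hyperedge events

s2 <- adjacency_sequence(th, 2)
s3 <- adjacency_sequence(th, 3)
gap <- cross_order_gap(s2, s3, 1:30)
head(as.data.frame(gap), 7)
#>   tau         value
#> 1   1 -1.116552e-03
#> 2   2 -7.232023e-04
#> 3   3 -2.582887e-03
#> 4   4 -1.233346e-02
#> 5   5  4.563953e-02
#> 6   6 -4.936084e-05
#> 7   7 -7.063386e-03
gap$lags[which.max(gap$values)]
#> [1] 5
```

The gap is flat at the background-noise level except at the planted lag
`tau = 5`, where pairs predict triads (`delta^(2,3)(5) = 0.046 > 0`). The
interaction matrix at that lag shows the same signal in its off-diagonal
`(2,3)` entry:

```r
interaction_matrix(th, 5)
#> <interaction_matrix> K(tau = 5), orders 2..3
#>         2      3
#> 2 -0.0026 0.0389
#> 3 -0.0067 0.0078
```

Simulating a hypergraph with genuine cross-order memory (3-hyperedges copy
the recent past of their 2-subsets) and analyzing it end to end:

```r
cfg <- cdarh_reference_config(seed = 1)   # N=10, D=3, T=3e4, p(3)=0.6, m_c(2,3)=60
th  <- cdarh_simulate(cfg)                # ~30 s
g   <- cross_order_gap(adjacency_sequence(th, 2), adjacency_sequence(th, 3), 1:1000)
binned_average(g, 10)$binned              # positive up to the memory horizon
```

## Command line

```sh
Rscript inst/cli/hypermem fixtures --kind planted_cross_lag --lag 5 --out toy.tsv
Rscript inst/cli/hypermem analyze --in toy.tsv --out analysis --max-lag 30
Rscript inst/cli/hypermem reconstruct --in contacts.tsv --resolution 20 --out events.tsv
Rscript inst/cli/hypermem null --in events.tsv --statistic gap --orders 2,3 \
        --realizations 20 --seed 7 --out null
```

Outputs are CSV (`tau,value`; `bin_center,mean,std,count`;
`tau,null_mean,null_std`) plus a JSON manifest per run directory. Exit
codes: 0 success, 2 input error, 1 internal error.

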