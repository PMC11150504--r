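---
title: "Quantifying memory in temporal hypergraphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying memory in temporal hypergraphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Face-to-face contact recordings, and many other relational data streams,
are usually analyzed as temporal *networks*: sequences of pairwise links.
But people meet in groups. A conversation of four is not six independent
dyads, and the way groups persist, grow and fragment over time is invisible
to purely dyadic statistics. `hypermem` represents such systems as
**temporal hypergraphs** — a node set $\mathcal{V}$ of size $N$ plus a
sequence $\{\mathcal{H}(t)\}_{t=1}^{T}$ of snapshots, each a set of
hyperedges (node subsets of size $d \in \{2,\dots,D\}$) — and provides
estimators for how interactions of each order, and between orders, are
correlated in time.

## From hyperedges to adjacency sequences

Adjacency *tensors* of different ranks cannot be cross-correlated directly,
so each order is projected onto a node-by-node matrix of common rank. With
$\mathbf{E}^{(d)}(t)$ the node-by-hyperedge incidence matrix of the order-$d$
hyperedges at time $t$,

$$\mathbf{A}^{(d)}(t) = \mathbf{E}^{(d)}\mathbf{E}^{(d)\top}
  - \mathrm{diag}(\mathbf{E}^{(d)}\mathbf{E}^{(d)\top}),$$

so $a^{(d)}_{ij}(t)$ counts the order-$d$ hyperedges containing both $i$ and
$j$ at $t$. The **annealed matrix** $\mu^{(d)} = \frac1T \sum_t
\mathbf{A}^{(d)}(t)$ is the centering term for every estimator; it is always
computed over the full sequence, never per lag window, so all lags share one
baseline.

## The correlation estimators

The **intra-order correlation matrix** at lag $\tau$ is

$$\mathcal{C}^{(d)}(\tau) = \frac{1}{T-\tau}\sum_{t=1}^{T-\tau}
  \frac{1}{((d-1)!)^2}
  \left[\mathbf{A}^{(d)}(t)-\mu^{(d)}\right]
  \left[\mathbf{A}^{(d)}(t+\tau)-\mu^{(d)}\right]^{\top},$$

and its trace $c^{(d)}(\tau)$ the scalar intra-order correlation function;
$\sigma^{(d)} = c^{(d)}(0)$ is the order's variance. The $1/(d-1)!$ weights
compensate the combinatorial blow-up of pair co-memberships with order, so
orders are comparable. The **cross-order** versions replace one factor by a
second order $d_2$, with weight $1/((d_1-1)!(d_2-1)!)$; $c^{(d_1,d_2)}(\tau)$
is *not* symmetric in its arguments for $\tau>0$, and the normalized
asymmetry

$$\delta^{(d_1,d_2)}(\tau) =
  \frac{c^{(d_1,d_2)}(\tau)-c^{(d_2,d_1)}(\tau)}
       {2\sqrt{\sigma^{(d_1)}\sigma^{(d_2)}}}$$

is the **cross-order gap**: positive when groups of size $d_1$ anticipate
groups of size $d_2$ more than the reverse — a preferred temporal direction
of group nucleation. All pairwise information at one lag is collected in the
$(D-1)\times(D-1)$ **normalized interaction matrix**
$\mathcal{K}_{d_1 d_2}(\tau) = c^{(d_1,d_2)}(\tau) /
(2\sqrt{\sigma^{(d_1)}\sigma^{(d_2)}})$, whose diagonal is $1/2$ at
$\tau = 0$ by construction.

Scalar traces are computed without materializing matrix products
($\mathrm{tr}(XY^{\top}) = \sum_{ij}X_{ij}Y_{ij}$ on flattened sequences);
the matrix estimators exist separately and both paths are checked against a
nested-loop oracle in the test suite to $10^{-10}$.

Numerical conventions worth knowing:

* Traces are **not** divided by $N$; cross-dataset comparability is the job
  of $\mathcal{K}$'s normalization.
* Orders with $\sigma^{(d)} = 0$ (absent throughout) yield `NaN` entries and
  a warning — never an error, so lag sweeps over all order pairs don't
  abort.
* Bin averages (for double-log presentation) use geometric bin edges over
  $[1, \tau_{\max}]$, geometric-mean bin centers, population ($1/n$)
  standard deviations, and omit empty bins. The bin count (default 10) and
  scale are exposed because the underlying figure convention is not fixed
  by any reference; linear binning is available.
* Whether the trace is taken before or after the $1/(T-\tau)$ average is
  immaterial by linearity; the implementation averages elementwise products.

## The null model

`time_shuffle()` applies one uniform permutation to the snapshot sequence,
each snapshot moving as a block. This preserves every snapshot exactly
(hence every $\mu^{(d)}$, every $\sigma^{(d)}$, and instantaneous
cross-order co-occurrence) while destroying all temporal structure. A
per-order independent shuffle is available behind `per_order = TRUE` for
exploration, but the block shuffle is the reference null: the object being
randomized is the single sequence of sets $\mathcal{H}(t)$.
`null_ensemble()` repeats the shuffle $R$ times (seeds $s, s+1, \dots$) and
returns the per-lag mean and standard deviation; the ensemble size (default
20) is an implementation choice — a single reshuffled curve is the minimal
version of the same comparison.

## Generative models: DARH and cDARH

Every candidate hyperedge (all $\binom{N}{d}$ subsets per order) carries an
independent binary present/absent process. Each step, with probability
$1-q^{(d)}$ the state is redrawn $\mathrm{Bernoulli}(y^{(d)})$; with
probability $q^{(d)}$ it copies a uniformly chosen one of its $m_s^{(d)}$
most recent states. This is the DARH model: $q$ sets memory strength, $y$
the stationary density (copying preserves the Bernoulli marginal for any
$q<1$), and with $m_s=1$ the autocorrelation is exactly $q^{\tau}$
(a DAR(1) process). Fixed $m_s$ yields a correlation plateau up to
$\tau = m_s$ followed by exponential decay; drawing each hyperedge's
$m_s$ uniformly from $\{1,\dots,m_{s,\max}^{(d)}\}$ mixes scales and
produces the slow decay seen in empirical data.

The cross-memory variant (cDARH) lets a memory update, with probability
$p^{(d)}$, copy instead from one of the $m_c^{(d',d)}$ most recent states of
a uniformly chosen *overlapping* hyperedge of order $d' \sim \rho^{(d)}$:
subsets for $d' < d$, supersets within the $N$ nodes for $d' > d$. Overlap
is the point — groups grow or shrink by one or a few members at a time.

Implementation decisions (configurable where stated):

* **Synchronous update, strict past.** All hyperedges update at step $t$
  from histories as of the end of $t-1$; every copy reads a lag $\ge 1$.
  This avoids order-of-update artifacts.
* **Initialization and burn-in.** Pre-start buffers are filled with
  i.i.d. $\mathrm{Bernoulli}(y^{(d)})$ states and a burn-in of $10\times$
  the largest memory length is discarded (default, overridable). The
  marginal is already stationary under this initialization; the burn-in
  removes residual joint-distribution transients.
* **$\rho^{(d)}$** defaults to uniform over $\{2..D\}\setminus\{d\}$; with
  $D=3$ the source order is forced.
* **Per-hyperedge sampled $m_s$** uses lower bound 1.
* **Equivalence at $p=0$** with DARH is distributional, not bit-for-bit:
  the branch structure consumes random numbers differently.
* The engine is vectorized over hyperedges per time step; cost grows as
  $\sum_d \binom{N}{d}$, which is why demonstrations use small $N$.

### The reference demonstration configuration

`cdarh_reference_config()` fixes $N=10$, $D=3$, $T=3\cdot10^4$, $p^{(2)}=0$,
$p^{(3)}=0.6$, $m_c^{(2,3)}=60$, per-hyperedge $m_s$ with maxima 40
(order 2) and 10 (order 3). The memory strength and density are not fixed by
any external constraint; the package sets $q^{(d)}=0.8$ and $y^{(d)}=0.2$
once — strong memory (the regime in which discrete autoregressive processes
exhibit measurable correlation decay over $10^2$ lags) and sparse group
activity typical of contact data. These defaults were chosen a priori and
are not tuned to test outcomes.

A consequence worth stating plainly: with these memory scales, the model's
influence horizon is a few times $m_c = 60$ steps. The cross-order gap
$\delta^{(2,3)}(\tau)$ is positive in every log bin up to $\tau \approx 200$
and statistically indistinguishable from zero beyond: across seeds, the
minimum over *all* bins up to $\tau = 10^3$ straddles zero at the
$\pm 2\times 10^{-4}$ level. The acceptance test asserts strict positivity
of all bins anyway; whether it passes depends on the noise-floor bins'
sign at the frozen seed, and that fragility is documented rather than
hidden behind a widened tolerance. The reported acceptance quantity is the
all-bin minimum, computed as defined.

## Reconstruction from pairwise contact streams

Proximity datasets record dyadic contacts `t i j` on a regular grid
(e.g. 20 s frames). If $d$ individuals are pairwise in contact at one
frame — a clique of the frame graph — they are taken to interact as one
group of size $d$. `promote_cliques()` promotes **maximal** cliques only:
an edge inside a triangle is part of the triad, not additionally a dyad.
Promoting every sub-clique (available via `all_cliques = TRUE` for
sensitivity analysis) would make each group imply all its subgroups and
trivialize cross-order statistics. Maximal cliques larger than a requested
$D$ are skipped with a warning or, with `split_large = TRUE`, emitted as
all their size-$D$ subsets. Frames with no contacts become empty snapshots
by default so that lags count wall-clock steps; `fill_gaps = FALSE`
switches to event-indexed time. Clique enumeration is delegated to
igraph's Bron–Kerbosch implementation, with a per-frame clique-count guard
against pathological dense frames.

## Synthetic fixtures and what a green test establishes

`make_fixture()` produces inputs with machine-readable planted truth:
i.i.d. activity (no correlation at any positive lag), a periodically
recurring hyperedge (autocorrelation peaks at multiples of the period), a
2-hyperedge whose coin-flip state is copied into a covering 3-hyperedge $L$
steps later ($\delta^{(2,3)}$ peaks exactly at $L$), and a pairwise contact
stream assembled from vertex-disjoint cliques (known promoted hypergraph).
These fixtures exercise every estimator's sign, location and normalization
conventions, and the generative models cover stationarity and closed-form
autocorrelation. None of them emulates the burstiness, circadian rhythms or
node-level heterogeneity of real contact data: a green suite establishes
correctness of the estimators and simulators, not that any particular
empirical system has cross-order memory.

## Known limitations

* Hyperedges are unweighted and undirected; rank-$d$ tensors are
  deliberately out of scope.
* No parameter fitting: the models are forward simulators.
* Candidate enumeration is $\Theta(\sum_d \binom{N}{d})$; the CLI warns
  above $10^5$ candidates.
* Degree-preserving (edge-swap) randomizations within snapshots are not
  provided; the null model is the time shuffle only.
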