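---
title: "Pseudotime by genetic algorithm: model, operators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudotime by genetic algorithm: model, operators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Cells captured in a single scRNA-seq experiment sit at different stages of
whatever process the tissue is running — differentiation, cell cycle,
response to a stimulus.  Pseudotime analysis tries to recover that latent
order from expression alone.  `gatraj` treats the problem combinatorially:
a trajectory is a *permutation* of the cells, and the best trajectory is
the permutation under which gene expression changes look smoothest.

For gene $j$, let $R_{ij}$ be the rank of cell $i$ among that gene's
expression values (ties, including ties among zeros, get the average rank;
zeros are ordinary numeric values).  Given a candidate pseudotime
$t_i \in \{1, \dots, n\}$ (a permutation), the model is

$$R_{ij} = \beta_{j0} + \beta_{j1} t_i + \beta_{j2} t_i^2 + \beta_{j3} t_i^3 + \epsilon_{ij},$$

fitted by least squares separately at degrees $d = 1, 2, 3$.  Each degree
is scored by
$\mathrm{BIC}_{dj} = n \ln \hat\sigma^2_{j} + d \ln n$,
the gene's cost is $C_j = \min_d \mathrm{BIC}_{dj}$, and the ordering's
cost is $C = \sum_j C_j$.  Working on ranks makes the cost invariant to any
strictly monotone transform of a gene's expression (normalisation choices,
log transforms) and robust to outliers; degree $\le 3$ covers monotone,
transient (up–down), and one-full-cycle patterns.  Because polynomials of
degree $\le 3$ are closed under $t \mapsto n + 1 - t$, every ordering and
its reverse have identical cost: orientation is not identifiable from the
data and must come from the user (a root cell or cluster).

Two numerical choices matter here.  First, fits use an orthonormal
polynomial basis in $t$ internally (raw powers of $t$ up to $n^3$ are
badly conditioned); residual variance, and hence BIC, is basis-invariant,
and reported coefficients are on centred scaled time $s = (t-(n+1)/2)/n$.
Second, a perfect fit would give $\hat\sigma^2 = 0$ and an infinite BIC,
so residual variances are floored at $10^{-8} n^2$ (ranks live on a scale
proportional to $n$); the floor is configurable in `gene_cost()` /
`total_cost()`.  Each fitted unit needs at least $n \ge 5$ cells (cubic
plus one residual degree of freedom) — this is also the minimum cluster
size.

## The genetic algorithm

The cost is minimised over the permutation space by a genetic algorithm
with three operators per generation, starting from `pop_size` $N = 100$
seeded uniform-random permutations:

* **Mutation** (inversion): two positions $i \le j$ are drawn uniformly
  and the segment between them is reversed; each member contributes one
  mutant ($N \to 2N$).
* **Recombination**: the $2N$ pool is split at random into two halves and
  paired across them.  For each pair, a Poisson($\lambda = 2$) number of
  cut points splits both parents into equal-length fragments; a child
  keeps alternate fragments of one parent and refills the vacated
  positions from the other parent via an exact minimum-weight bipartite
  matching between the positional indices of the left-behind entries
  (weight $|p - q|$).  For points on a line with absolute-difference
  weights, matching in sorted order is an exact optimum, so no general
  assignment solver is needed.  Each pair yields two children
  ($2N \to 4N$).
* **Selection**: the $N$ lowest-cost members of the $4N$ pool survive, so
  with the default $N = 100$ each generation weighs 400 candidate
  orderings and the incumbent best can never be lost (best cost is
  monotonically non-increasing — this is asserted in the tests and visible
  in the pipeline's generation log).

The loop runs at least `min_generations` (30) and stops when the best
cost improves by less than $\varepsilon$ (default $10^{-6} |C_{best}|$ at
generation 1, with an absolute override), with a hard cap
`max_generations` (200) since the $\varepsilon$ rule alone has no
worst-case bound.

Two refinements were added after profiling optimizer behaviour on tiny
instances ($n \le 8$, where exhaustive search is available as an oracle).
Plain truncation selection rapidly fills the population with copies of the
incumbent, after which only single-inversion neighbours are ever explored
and isolated optima (a permutation giving a near-perfect cubic fit) are
missed.  `evolve()` therefore (a) prefers *distinct* orderings when
selecting survivors, topping up with duplicates only when fewer than $N$
distinct candidates exist, and (b) on small instances ($n \le 12$)
re-seeds a converged population with fresh random permutations (keeping
the incumbent) up to three times within the generation budget.  With both,
the GA attains the exhaustive-search optimum on 40/40 small single-trend
instances; without them the hit rate is 55–70%.  `select_quarter()`
retains the plain behaviour by default so both variants are available.

## Clusters, branching, and the endpoint distance

For branching processes the data are first clustered (`cluster_cells()`:
k-means on up to 10 principal components of the rank matrix, $k$ chosen by
mean silhouette over 2–10, seeded; or user labels), genes are optionally
filtered (`filter_genes()`: Kruskal–Wallis across clusters on ranks, or
rank variance without labels; ties broken by gene id), and each cluster is
ordered independently on its own within-cluster ranks.

Each cluster path exposes two termination points.  The distance between
paths $\vec x$ (length $m$) and $\vec y$ (length $n$) is
$d(\vec x, \vec y) = \min(C(x_1), \dots, C(x_4))$ where the $x_k$
concatenate quarter-length end segments: head of $y$ reversed + head of
$x$; tail of $y$ + head of $x$; head of $x$ reversed + head of $y$; tail
of $x$ + head of $y$.  The third is the exact reversal of the first, so it
carries the same cost; the four are still all evaluated as defined.  Note
the set contains no tail–tail geometry; because within-cluster
orientations are arbitrary this does not restrict which physical junction
can win.  Ranks for each concatenation are recomputed on the union of the
two segments (ranks are only meaningful within the fitted unit);
concatenations shorter than 5 cells fall back to a degree-1 fit.
$d$ is symmetric, inherited from reversal invariance.

Clusters are joined smallest-$d$-first under a no-cycle rule (Kruskal)
until $k - 1$ inter-cluster edges span them; ties break lexicographically
on the cluster-id pair.  When several joins meet one termination point, a
branching node is inserted there with a zero-length edge — the minimal
reading of adding a fork "near" the shared point.  Rooting
(`root_tree()`) orients edges away from a user-chosen root cluster or
cell and flips within-cluster orderings so pseudotime increases along
every root-to-leaf walk; topology never changes.  Within-cluster
orderings are estimated once and only re-oriented afterwards, never
re-estimated after joining.

**A limitation worth knowing about.**  On data simulated as one smooth
continuum, the endpoint distance tends to join the most *separated*
states rather than the temporally adjacent ones: ranks discard effect
size, so a clean step (two well-separated quarter-segments) fits a cubic
better than the weak local trend between genuinely adjacent windows,
whose within-window signal is small relative to count noise.  The
package's tests therefore assert what the construction guarantees —
$k-1$ joins, spanning, acyclicity, symmetry, and that trendless junctions
(clusters sharing a state) lose to informative ones — rather than exact
fork recovery on continuum simulations.  The metric is most reliable when
clusters are transcriptionally distinct cell types, which is the setting
cluster-wise trajectory assembly targets in practice.

## Large datasets

The GA scales poorly in $n$, so for large $N$ the package estimates
pseudotime in two stages (`pseudotime_large()`).  A random subsample of
$M$ cells (default 100) is ordered by the GA; every cell $j$ then receives
the score $S_j = \frac{1}{r} \sum_{k \in N_r(j)} t_k$, the mean pseudotime
of its $r$ nearest subsampled cells (default $r = 5$), with distances
taken as Euclidean in rank-transformed expression space for consistency
with the cost model.  A subsampled cell is its own nearest neighbour, so
$r = 1$ reproduces its own $t$.  The ordering of $S$ is a pseudotime for
all $N$ cells.

With $B$ subsamples (default 30) each cell gets a $B$-dimensional score
vector.  Each subsample's orientation is arbitrary, so columns are first
sign-aligned (flipped to correlate positively with the first column, or
with the largest-variance column if the first is flat) — without this the
score cloud is not curve-like.  A one-dimensional principal curve is then
fitted through the $N$ points by iterative projection and smoothing:
arc-length positions are initialised from the first principal component,
each coordinate is spline-smoothed against arc length
(`smooth.spline`), points are re-projected onto the resulting polyline,
and the loop stops when the induced ordering stabilises (cap 50
iterations).  Cells ordered by final arc length are the consensus
pseudotime.  Per-subsample seeds derive from the master seed, so results
are bit-reproducible and independent of any execution interleaving.

## The simulator

`simulate_trajectory()` generates the study conditions used throughout
the tests.  Cells receive equally spaced latent pseudotimes
$u \in [0, 1]$ (storage order shuffled).  Genes split into five trend
classes (defaults 20% each): linear increasing, linear decreasing,
quadratic (peak or valley at mid-trajectory, orientation random),
sinusoidal (one full period, random phase), and pseudotime-independent.
A gene's trend curve, mapped into `shape_range` = (1, 20), sets the Gamma
shape; the per-cell mean is Gamma(shape, scale = 1) and the count is
Poisson with that mean — marginally negative binomial, so overdispersed,
which the tests verify.  Technical zeros are then injected under one of
three regimes: (1) low rate, probability decreasing in the generating
mean (logistic in log-mean centred at the median so the overall rate
stays near the 5% target); (2) a constant 5% independent of the mean;
(3) a constant 40%.  "Not expressed in this cell" and "dropped out" are
deliberately not modelled separately — they are indistinguishable in the
observed matrix.  `simulate_branching()` forks a stem into branches whose
Gamma shapes interpolate linearly from the gene's stem-terminal shape to
a branch-specific random target, so branch origins match the stem's
terminal state exactly in expectation.

What the simulator does *not* emulate: library-size variation between
cells, batch effects, doublets, gene–gene correlation beyond the shared
pseudotime, and bursting kinetics.  Passing tests show the method
recovers orderings under trajectory-driven Gamma-Poisson noise with
dropout; they do not certify performance under those additional
real-data artefacts.

## Problem sizes and reported numbers

The package's own accuracy checks, re-run by `scripts/acceptance.R` and
mirrored in the test suite, use: (a) a 1000-cell, 100-gene trajectory
with scenario-2 dropout, pooled over $B = 30$ size-100 subsamples, median
of 5 replicates — consensus $|\rho| \approx 0.99$; (b) 10 000-cell,
100-gene trajectories, ordering a 100-cell (1%) subsample — median
$|\rho| \approx 0.85$ on the subsample over 10 replicates — and extending
to all cells via $r$-NN scores — median $|\rho| \approx 0.96$; (c)
exhaustive-search equivalence on $n \le 8$; (d) 50-cell parameter
recovery at $|\rho| \ge 0.9$ in $\ge 90\%$ of 20 runs.  Replicate counts
were chosen so the whole suite runs comfortably on one CPU; all seeds are
fixed in the tests and derived from `--seed` in the script.

## Defaults at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `pop_size` | 100 | GA population $N$; 400 candidates weighed per generation |
| `min_generations` | 30 | generations before the convergence test applies |
| `max_generations` | 200 | hard cap on generations |
| `epsilon` | $10^{-6}\,|C_1|$ | best-cost improvement threshold |
| `poisson_lambda` | 2 | mean number of crossover cut points |
| `n_top` | 2000 | genes kept by filtering |
| `B`, `M`, `r` | 30, 100, 5 | subsamples, subsample size, neighbours |
| `shape_range` | (1, 20) | Gamma-shape span of trend curves |
| `gamma_scale` | 1 | Gamma scale of per-cell means |
| dropout rates | 0.05 / 0.05 / 0.40 | scenarios 1 / 2 / 3 |
| variance floor | $10^{-8} n^2$ | lower bound on $\hat\sigma^2$ |

## Worked example

```{r, eval = FALSE}
library(gatraj)

st <- simulate_trajectory(sim_config(n_cells = 120, n_genes = 100,
                                     dropout_scenario = 2, seed = 1))
rk <- rank_transform(st$counts)
fit <- evolve(rk, ga_config(seed = 1))
abs_spearman(fit$pseudotime, st$true_pseudotime)
count_functional_genes(st$counts, fit$ordering)
```
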