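---
title: "Analytic stochastic character mapping: models, numerics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic stochastic character mapping: models, numerics, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomap)
```

## The problem

Given a rooted phylogeny with branch lengths, a discrete character scored at
the tips, and a continuous-time Markov chain (CTMC) model of character
evolution, stochastic character mapping asks what happened *along the
branches*: how much time did the character spend in each state, and how many
times did it change? The classical answer is simulation: draw many full
histories conditional on the tip data and average. phylomap instead computes
the two summaries practitioners almost always want — per-branch **expected
dwelling times** and **expected numbers of transitions away from each
state** — in closed form. Because each tree costs a deterministic,
simulation-free computation, the method scales to whole posterior samples of
trees, which is where it earns its keep: ancestral-state inferences that
integrate over phylogenetic uncertainty rather than conditioning on a single
"true" topology.

## Model

Character evolution follows a CTMC with instantaneous rate matrix $Q$
($s \times s$, off-diagonals $q_{ij} \ge 0$, rows summing to zero), under one
of the standard constraint classes:

* **ER** — all off-diagonal rates equal (1 free parameter);
* **SYM** — $q_{ij} = q_{ji}$ ($s(s-1)/2$ free parameters);
* **ARD** — all rates different ($s(s-1)$ free parameters).

The root state carries a prior $\pi$. Transition probabilities over a branch
of length $T$ are $P(T) = e^{QT}$, evaluated through the spectral
decomposition $Q = U \Lambda U^{-1}$, so that
$P(T) = U\,\mathrm{diag}(e^{\lambda_k T})\,U^{-1}$.

### Endpoint-conditioned expectations

All per-branch quantities reduce to integrals of products of transition
probabilities. For eigenvalues $\lambda_k$ define the **integral factors**

$$J_{kl}(T) = \int_0^T e^{\lambda_k \tau} e^{\lambda_l (T-\tau)}\,d\tau
 = \frac{e^{\lambda_k T} - e^{\lambda_l T}}{\lambda_k - \lambda_l},$$

with the limit $T e^{\lambda_k T}$ when $\lambda_k = \lambda_l$ (declared at
tolerance $10^{-9}\max(1,|\lambda_k|)$). Then the expected dwelling time in
state $i$ on a branch with endpoint states $(a, b)$ is

$$D_i(a,b) = \frac{1}{P_{ab}(T)} \sum_{k,l} U_{ak} U^{-1}_{ki}
  U_{il} U^{-1}_{lb}\, J_{kl},$$

and the expected number of labelled $i \to j$ jumps is

$$N_{ij}(a,b) = \frac{q_{ij}}{P_{ab}(T)} \sum_{k,l} U_{ak} U^{-1}_{ki}
  U_{jl} U^{-1}_{lb}\, J_{kl}.$$

The $s^3$ cost of these decomposition-and-multiplication steps is the cubic
term in the method's $O(t\,n\,s^3)$ complexity over $t$ trees with $n$ tips.

### Conditioning on tip data

The joint posterior of a branch's endpoint states given all tip data is
assembled from Felsenstein's pruning algorithm run twice: a postorder pass
computing inside partial likelihoods $F$, and a preorder pass computing
outside partials, folding in sibling subtrees. For a branch from parent $v$
to child $c$,

$$W_{ab} \propto A(a)\, P_{ab}(T)\, F_c(b),$$

normalized to sum to one, where $A$ is the outside partial at the top of the
branch. The branch's unconditional-on-endpoints expectations are then
$\mathrm{dwell}_i = \sum_{ab} W_{ab} D_i(a,b)$ and
$\mathrm{pairwise}_{ij} = \sum_{ab} W_{ab} N_{ij}(a,b)$. Internally the
division by $P_{ab}(T)$ is never performed: the code sums
$\tilde W_{ab} = W_{ab}/P_{ab}(T) = A(a) F_c(b) / Z$ against the
*unconditional* kernels, so endpoint pairs with $P_{ab}(T) = 0$ contribute
exactly zero and no indeterminate $0/0$ terms can arise. Away-from-state
totals are always derived as $\mathrm{away}_i = \sum_{j \ne i}
\mathrm{pairwise}_{ij}$, never computed independently; the public result
emphasizes away-from-state counts (the robust, binary-lumpable quantity),
with the pairwise matrix exposed for users who want it.

### Rate estimation

$Q$ is fitted by maximum likelihood with `stats::nlminb` (bounded
quasi-Newton) in log-rate space. Defaults: rates bounded to
$[10^{-8}, 10^3] / \overline{\ell}$ where $\overline{\ell}$ is the mean
branch length, three multistarts spread log-uniformly around
$1/\overline{\ell}$, and objective tolerance $10^{-10}$. Over a tree set, the
matrix can be fitted per tree (default), once on the first tree and reused
("pooled", mirroring the common "empirical" usage of simulation-based
mappers), or supplied by the user. A list of characters is fitted jointly by
summing log-likelihoods (used for pooled rate recovery).

**Root prior.** The default is uniform ($1/s$), with `"stationary"` (of the
fitted $Q$) and user-vector options. The choice is recorded in the model
object and report; nothing downstream assumes one convention.

## Numerical choices

* **Scaling.** Partial likelihoods are rescaled per node (log accumulators),
  so trees with thousands of tips do not underflow.
* **Reversible vs general $Q$.** ER/SYM matrices (and any $Q$ passing a
  detailed-balance check against its stationary distribution) are decomposed
  through a symmetric similarity transform — real eigenvalues, orthogonal
  basis. ARD matrices use the general eigendecomposition, possibly complex;
  expectations are computed in complex arithmetic and validated to have
  imaginary parts below $10^{-8}$ before the real part is taken. An
  eigenbasis with condition number above $10^{10}$ is rejected with an error
  directing the user to quadrature (`stats::integrate` against
  `Matrix::expm`-style exponentials), the fallback the test suite uses as an
  independent oracle.
* **Degenerate branches.** Zero-length branches get identically zero
  dwelling and transition expectations and $P(0) = I$ in the conditioning
  pass. Tiny negative expectations from round-off (above $-10^{-10}$) are
  clamped to zero.
* **Tolerances.** Row sums of $P(t)$ are maintained to $10^{-10}$; dwelling
  conservation ($\sum_i \mathrm{dwell}_i = T$ per branch) holds to
  $10^{-8}$ on 128-tip trees.

## Posterior summarization and painting

Branches are matched across rooted trees by the **clade tip-set** below
them: two branches are "the same" iff the sets of tip labels descended from
them are identical. This is root-dependent by design; trees are used as
rooted as written and never rerooted. For each branch of a user-supplied
target tree (e.g. a MAP tree), the per-tree quantity — dwelling time as a
fraction of branch length, or expected transitions away from a state — is
collected from every posterior tree containing the clade, each tree
contributing equal weight $1/t$.

Dwelling fractions are binned in **5% tonality steps**: bin $k$ covers
$((k{-}0.5)\cdot 5\%,\,(k{+}0.5)\cdot 5\%]$, i.e. nearest-multiple-of-5%
rounding, with bin 0 anchored at 0% and bin 20 at 100%. The bin *edges* are
a package convention (only the 5% step is inherent to the scale) and are
recorded in output metadata. Transition counts are binned on 21 equal-width
bins spanning 0 to the maximum observed across matched target branches — an
adaptive scale, recomputed per summary.

A branch matched by no posterior tree is flagged **gray**. For partially
matched branches the default paints the unmatched remainder
$1 - \text{matched fraction}$ gray along the branch; a `renormalize` option
instead rescales the bin distribution to sum to one. Both behaviors are
legitimate readings of "posterior-proportional painting"; the choice is
stored in the summary.

Painted phylograms subdivide each branch into contiguous segments with
length proportional to bin mass, ordered by descending mass root-to-tip
(a fixed rule so output is deterministic), gray remainder last. The dwelling
colormap interpolates blue (0%) through green (50%) to pure red (100%) in
Lab space at 21 points; transitions use a perceptually uniform sequential
ramp. SVG output is plain deterministic XML carrying machine-readable
`data-clade`/`data-bin`/`data-share` attributes, so figures can be parsed
and checked; PNG/PDF render the same layout through the standard devices.

## What the simulators emulate

The synthetic module exists so that every analytic claim can be checked
against an independent route on data with known truth:

* `simulate_pure_birth_tree()` — constant-rate speciation-only (Yule)
  branching with exponential waiting times, observed at the moment the
  $n$-th lineage appears; the stem interval is kept as `root.edge`, so total
  depth has the textbook Yule expectation $\sum_{k=1}^{n-1} 1/(k\lambda)$.
  A side effect of observing exactly at the $n$-th birth is that the final
  split's daughters have zero length; downstream code treats zero-length
  branches analytically, and tests exercise that path.
* `simulate_history()` — exact forward CTMC realization with per-branch
  segments, realized dwelling times and transition counts.
* `sample_endpoint_conditioned_path()` — exact endpoint-conditioned paths
  by uniformization: a dominating Poisson process at rate
  $\mu = \max_i |q_{ii}|$ with self-jumps, jump counts drawn from the
  endpoint-conditioned Poisson mixture, the jump chain as a discrete Markov
  bridge, jump times as uniform order statistics. If $\mu T > 10^4$ the
  sampler switches to rejection sampling of forward paths (recorded in the
  result). The bulk path-sampling loop is implemented in C++ (via Rcpp) but
  draws from R's RNG, so everything is reproducible under a seed.
* `simulate_mappings()` — the classical SIMMAP-style simulation mapper:
  joint node states sampled from their conditional posterior, branches
  filled with endpoint-conditioned paths. By default it returns
  per-replicate realized summaries (dwelling and pairwise counts per
  branch); full segment lists are available with `keep_paths = TRUE`, which
  is intended for small replicate counts.

The cross-validation triangle — analytic expectations vs adaptive
quadrature vs endpoint-conditioned simulation — must close, and the test
suite closes it at $10^{-8}$ (quadrature) and three Monte-Carlo standard
errors (simulation, up to 200,000 paths per case).

What these simulations do **not** emulate: extinction (no birth–death
trees), rate heterogeneity across sites or branches, trait-dependent
diversification, model misspecification, or phylogenetic error in the input
trees. Passing tests therefore demonstrate internal correctness of the
expectations under the assumed CTMC — not robustness of ancestral-state
inference on real data, where the model is always wrong to some degree.

## Problem sizes and defaults

The packaged experiments run at desk scale, chosen once: the accuracy
experiment uses a 128-tip pure-birth tree (birth rate 1) with a binary
character at ER rate 1.0 — a rate giving on the order of one expected change
per unit branch length, so histories are informative but not saturated; the
analytic-vs-simulation comparison uses 16 tips with 50,000 replicates; rate
recovery pools 100 characters over 20 seeds; the replicate-ladder experiment
uses {100, 250, 500, 1000, 2500} on 16–32 tips. The accuracy harness
(`verify` subcommand) reports across 20 seeds rather than a single
simulation, because a single realized history deviates from its own
conditional expectation by amounts that dwarf method error.

## Known limitations

* Pairwise $i \to j$ expectations are computed and exposed, but the
  headline per-branch outputs are away-from-state totals; for multi-state
  characters where specific ordered pairs matter, lumping states into binary
  categories and re-estimating $Q$ is the recommended route.
* Non-diagonalizable (defective) $Q$ matrices are not handled analytically;
  the package refuses them rather than returning silently inaccurate
  results.
* Clade matching requires rooted trees on one taxon namespace; unrooted
  bipartition matching and polytomy resolution are out of scope.
* The method returns expectations, not sampled histories: analyses that
  need joint trajectories (e.g. character correlation tests) still require
  a simulation-based mapper.
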