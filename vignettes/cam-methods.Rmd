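---
title: "Convex analysis of mixtures: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convex analysis of mixtures: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camix)
```

## The latent variable model

A heterogeneous tissue sample is a weighted sum of the expression of its
constituent subpopulations. For gene $i$ and sample $j$,

$$x_j(i) = \sum_{k=1}^{K} a_{jk}\, s_k(i),$$

where $s_k(i) \ge 0$ is the expression of gene $i$ in subpopulation $k$
and $a_{jk} \ge 0$ is the proportion of subpopulation $k$ in sample $j$,
with $\sum_k a_{jk} = 1$. Everything is on the linear (un-logged)
intensity scale; log-transformed input breaks the additivity that the
whole method rests on, which is why `read_expression()` offers an
`unlog_base` argument. A **marker gene** of subpopulation $k$ is a gene
expressed in $k$ and in no other subpopulation.

## Why the simplex vertices are identifiable

Divide each gene's expression vector $x(i) = (x_1(i), \ldots, x_J(i))$
by its sum. Marker genes of subpopulation $k$ all collapse onto the same
point: the normalized mixing column $a_k / \lVert a_k \rVert_1$. Every
other gene is a non-negative combination of the columns and therefore
lands *inside* the convex hull of those $K$ points. The mixing process
thus compresses and rotates the scatter of pure profiles into a simplex
whose vertices (i) are the normalized mixing columns and (ii) are
occupied exactly by the marker genes. Locating the vertices therefore
solves three problems at once — markers, proportions, and (by regression)
profiles — with no supervision, provided the mixing matrix has full
column rank and each subpopulation owns at least one marker gene. When
there are fewer samples than subpopulations the mixing matrix and the
markers remain identifiable, but per-gene profile regression becomes
underdetermined; `estimate_profiles()` refuses that case rather than
returning arbitrary solutions.

## The pipeline and its tunable parameters

1. **Filtering** (`filter_genes`): genes whose row-vector L2 norm falls
   below the 5% quantile or above the 95% quantile of the norm
   distribution are removed (`filter_low_q`, `filter_high_q`). Very dim
   genes are noise-dominated and very bright ones are outliers; both
   distort the simplex boundary. We read the published filtering rule as
   quantile-based: cutting at fractions *of the mean norm itself* would
   remove almost every gene at the upper cut, so the quantile reading is
   the only workable one. The norm is configurable to L1. Filtering acts
   on raw values before normalization, since the norm of a normalized
   vector is uninformative.
2. **Normalization** (`sum_normalize`): rows are divided by their sums;
   zero-sum genes are dropped with a message.
3. **Aggregation** (`affinity_propagation`, `tune_preference`):
   affinity propagation with negative squared Euclidean similarity
   condenses the gene cloud to `n_clusters` ≈ 50 centers. Fifty centers
   keep the exhaustive vertex search below about $2.4 \times 10^6$
   subsets at $K \le 5$ while still resolving the simplex boundary.
   Damping defaults to 0.5 and stopping requires an exemplar set stable
   for 10 iterations.
4. **Vertex search** (`find_vertices`): every $K$-subset of centers is
   scored by the summed *margin of error* — the Euclidean distance of
   each remaining center to the convex hull of the subset — and the
   minimizing subset wins. The margin is computed as an
   equality-constrained non-negative quadratic program (projection onto
   the hull), solved by an active-set method in compiled code on the
   Gram matrix of the centers.
5. **Model selection** (`select_model`): the number of subpopulations is
   the $K$ minimizing the total description length; see below.
6. **Deconvolution** (`estimate_proportions`, `estimate_profiles`):
   proportions come from standardized averaging of marker rows (L1 norm
   by default, so marker vectors live on the same unit-sum simplex as
   the proportions); profiles come from per-gene non-negative least
   squares on the raw scale, so they keep interpretable intensity units.

## Numerical choices

**Margin of error.** The distance is Euclidean (L2); the projection
weights are constrained to the probability simplex because all vectors
are sum-standardized — a cone would be the wrong feasible set. Points
inside the hull get margin 0 up to $10^{-9}$. Ties between vertex
subsets within $10^{-12}$ resolve to the lexicographically smallest
index set, making the search deterministic. Subsets whose Gram matrix
has a Cholesky pivot below $10^{-8}$ cannot span a $K$-simplex and are
skipped. The search aborts a subset as soon as its partial exterior sum
exceeds the current best, which leaves the result exact while cutting
most of the work; a configurable `subset_budget` (default $5 \times
10^6$) guards against accidental combinatorial explosions.

**Mixing-matrix rescaling.** A selected vertex center estimates a mixing
column only up to a positive scale (normalization divides it by the
column's L1 norm). Row-normalizing the stacked centers does *not* undo
this — the row sums mix all column scales — so camix solves for the
per-column scales directly: find $c \ge 0$ minimizing $\lVert C\,
\mathrm{diag}(c)\, \mathbf{1} - \mathbf{1} \rVert_2$ (a tiny NNLS), then
renormalize rows exactly. On noise-free data this recovers the true
row-stochastic mixing matrix to machine precision; with noise the final
row renormalization absorbs the residual.

**Affinity propagation.** APC has no random initialization, so results
are deterministic given the input order; exact message-passing
symmetries (duplicated points) are broken by a tiny index-keyed
perturbation of the similarities ($\sim 10^{-6}$ relative), not by RNG.
Rows identical up to float round-off are collapsed to one point whose
preference is divided by its multiplicity — a point standing for $c$
genes shares the exemplar penalty among them — which matters in
noise-free data where all markers of a subpopulation are the same
point. Message updates at damping 0.5 can oscillate indefinitely on
data with many near-duplicates (reference implementations show the same
behavior); a run that has not stabilized within 250 iterations is
restarted once at damping 0.9, and a still-unconverged run returns its
current assignment with a warning. Because messages decay with time
constant $1/\log(1/\lambda)$, an apparently stable exemplar set is not
trusted before that transient has passed. The preference giving the
requested number of clusters is found by bisection on the log of its
magnitude (cluster count responds roughly as a power law); probes run
at damping 0.9 from cold starts so the count at the returned preference
is reproducible, and the search stops when the count is within 10% of
the target, the bracket collapses (achievable counts jump across the
target), or after 25 steps.

**MDL.** The data term is an isotropic Gaussian residual model on the
$M$ cluster centers reconstructed by projection onto the candidate
simplex: $-\log L = (MJ/2)(\ln 2\pi\hat\sigma^2 + 1)$ with the plug-in
variance $\hat\sigma^2 = \mathrm{RSS}/(MJ)$, floored at $10^{-12}$ so
exact reconstructions stay finite (the floor is flagged, not an error).
The coding penalty charges $(K-1)J \ln(M)/2$ for the mixing matrix and
$KM \ln(J)/2$ for the per-cluster sources. Natural logarithms are used
throughout; the argmin over $K$ is invariant to the base. Centers enter
the likelihood unweighted — the description is of the cluster-center
set, not of individual genes; weighting by cluster size would let a few
huge clusters dominate the variance estimate. Ties within $10^{-12}$
go to the smaller $K$.

## The synthetic-mixture generator

`simulate_mixture()` emulates the validation designs the method was
built against. Defaults: $K = 3$ subpopulations, $J = 9$ samples, 2000
genes, 30 planted exclusive markers per subpopulation, a 45° simplex
rotation, and additive Gaussian noise with standard deviation 1% of the
mean signal (truncated at zero; a multiplicative log-normal model is
available). Design choices, fixed once:

* All gene magnitudes — markers and non-markers alike — share one
  log-normal distribution (`meanlog = log(150)`, `sdlog = 0.6`,
  arbitrary intensity units). Markers are not systematically brighter,
  so intensity filtering removes markers at the same rate as other
  genes.
* By default every non-marker gene is *co-expressed*: a Dirichlet(2)
  combination of at least two subpopulations, redrawn until no single
  subpopulation contributes more than 70% of the gene. The cap encodes
  what "co-expressed" means — a gene at 95% from one subpopulation is
  operationally a marker of it, and labelling such genes non-markers
  would make the planted truth self-contradictory.
* "Rotation" is operationalized as the minimal pairwise angle between
  mixing-matrix columns, the geometric quantity that controls how
  compressed (ill-conditioned) the mixed simplex is. Rows are convex
  blends of a subpopulation indicator and a centroid-dominated Dirichlet
  target, with the blend weight solved by root finding to hit the
  requested angle within 0.5°; 90° with $J = K$ degenerates to the
  identity.

What the generator does **not** emulate: probe-level microarray
artifacts, normalization pipelines (MAS5 and kin), batch effects,
correlated noise, or time-course autocorrelation. Passing tests
demonstrate the geometry and the estimators, not robustness to
real-platform noise structure.

## Problem sizes used in the automated checks

The exactness and recovery properties are checked at reduced sizes so
the full suite runs quickly: exact-recovery panels use 1000 genes and
five seeds per $K \in \{2, 3, 4\}$ (with filtering disabled — noise-free
data has no unreliable genes to remove, and removing a planted marker
would make perfect sensitivity unattainable by construction);
model-selection recovery uses 1200-gene panels, ten seeds each for
$K = 3$ and $K = 4$, scanning up to $K + 1$ candidates. The acceptance
script (`scripts/acceptance.R`) runs the full-size design — 2000-gene
panels at 30°/45°/60°, five seeds each, and a single $K = 2..6$
model-selection scan at $M \approx 50$ — and reports the resulting
medians.

## Known limitations

* The exhaustive search is exact but exponential in $K$; beyond
  $M = 50, K = 6$ the subset budget is the safety valve. No greedy
  fallback is provided.
* Marker assignment is cluster-resolution limited: a vertex cluster
  contributes *all* its member genes as markers, so markers sitting in
  a cluster that straddles the vertex neighborhood dilute precision.
* MDL consistency degrades when the noise level approaches the simplex
  edge lengths (heavily compressed mixing); the curve flattens and the
  argmin becomes seed-dependent.
* Proportions are identifiable with $J \ge K$ diverse samples; profile
  recovery additionally needs the per-gene regressions to be
  well-posed, hence the hard $J \ge K$ guard.
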