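---
title: "Methods: nestedness, spanning-forest communities and fitness ranking of country-product production networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nestedness, spanning-forest communities and fitness ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodfitness)
```

## The data model

The package analyses bipartite country-by-food-product networks for one
year at a time. From long-format records `(country, product, year,
tonnes)` and a population table `(country, year, persons)` it builds

* the binary adjacency matrix `M`, with `M[c, p] = 1` exactly when
  country `c` reports a strictly positive summed tonnage of product `p`
  that year, and
* the per-capita weighted matrix `W[c, p] = tonnes / persons`, in tons
  per person per year.

Only countries with population strictly above half a million persons
enter the analysis (`min_pop = 5e5`, configurable). Three parsing rules
are deliberate design choices rather than consequences of the data
format: a reported tonnage of zero counts as *non-production* (no
threshold beyond strict positivity is applied); duplicate
`(country, product, year)` rows are summed, because production tables
often split a commodity across sub-items; and label matching is exact
after whitespace trimming — no fuzzy harmonization of country names is
attempted, so upstream renames/merges must be resolved before import.
All-zero rows and columns are kept in the panel and flagged, not
silently dropped; downstream stages decide individually how to treat
them.

## Nestedness (NODF) and its null model

Nestedness measures the degree to which the product baskets of
specialist countries are contained in those of generalists. For each
pair `i < j` on one side of the bipartite graph,

```
T_ij = o_ij / min(k_i, k_j),   or 0 when k_i = k_j,
```

where `o_ij` is the number of shared partners and `k` the degrees; NODF
is the sum of `T_ij` over both sides divided by
`C(C−1)/2 + P(P−1)/2`. Two details deserve note:

* **Scale.** `nodf()` reports the 0–1 scale of the defining formula;
  `percent = TRUE` multiplies by 100 for comparison with the
  conventional NODF literature.
* **Variant.** The default `"symmetric"` variant evaluates the formula
  exactly as written above, with unordered pairs and the min-degree
  denominator; it equals the classic order-sensitive definition
  whenever rows and columns are sorted by decreasing degree, and the
  test suite cross-checks this correspondence against
  `vegan::nestednodf()`. The `"classic"` variant (zero unless fill
  strictly decreases in the given matrix order) is available for
  cross-validation against reference implementations. Pairs involving
  an empty row or column contribute 0 but stay in the denominator.

Significance is assessed against an ensemble of random binary matrices
with the *same dimensions and the same number of links*, links placed
uniformly at random without replacement (`simulate_random_panel()`).
This Erdős–Rényi-style reading of "same size and connectivity" — rather
than a degree-preserving randomization — is a deliberate choice; a
curveball-style null is out of scope. The empirical p-value uses the
add-one rule `p = (1 + #{null ≥ obs}) / (n_null + 1)` so that a finite
ensemble can never report `p = 0`; a z-score is reported alongside and
flagged `NA` when the ensemble is degenerate.

## Projections, similarity and the spanning forest

The one-mode country projection is the Gram matrix `C = W Wᵀ` (product
side: `Wᵀ W`). The description of `C`'s entries as *counts* of shared
products strictly matches only the binary source `M Mᵀ`, while the
formula is stated on the weighted matrix; the package therefore exposes
both (`source = "weighted"` is the default, matching the formula) and
documents the discrepancy instead of resolving it. From `C` the
Dice-type similarity is

```
S_ij = 2 C_ij / (C_ii + C_jj)  ∈ [0, 1],
```

with unit diagonal; nodes with `C_ii = 0` carry no information and are
dropped with a warning.

The spanning forest scans candidate edges (strictly positive
similarity) in decreasing weight and accepts an edge only while **at
least one endpoint is still isolated**. This acceptance rule is the
only reading of "no edge between two nodes already connected to some
other node" that actually yields disconnected sub-trees on a dense
similarity matrix — plain Kruskal acceptance (reject same-component
edges only) returns a single spanning tree there, and is available as
`rule = "kruskal"` for comparison. Determinism under ties is guaranteed
by breaking equal weights lexicographically on the endpoint label pair.
Zero-weight edges are never added, so mutually disjoint producers
remain singletons. Components of at least `min_size = 4` members are
reported by default, matching the usual practice of hiding pair and
singleton sub-trees in forest figures.

## The fitness–specialization fixed point

Country fitness `F` and product specialization `Q` are the fixed point
of the coupled non-linear map

```
F̃_c = Σ_p W_cp Q_p          (previous Q)
Q̃_p = 1 / Σ_c W_cp (1/F_c)  (previous F)
```

followed by normalization of each vector to mean 1. Both updates use
the *previous* state (a Jacobi, not Gauss–Seidel, sweep), which is what
the vectorized form `F = W Q; Q = 1/(Wᵀ (1/F))` computes. The start is
`F⁰ = Q⁰ = 1`; random positive starts are available and converge to the
same fixed point. Iteration stops when the sup-norm change of both
normalized vectors falls below `tolerance = 1e-10` or after
`max_iter = 10000` sweeps, whichever comes first; non-convergence is a
diagnostic flag, not an error.

Numerical choices worth knowing:

* Products with no producers would make the `Q` update divide by zero,
  so all-zero rows and columns are removed before iterating and
  reported as dropped; `write_fitness()` appends them unranked after
  all ranked entries.
* For some matrices — notably when one country's weighted basket is
  strictly dominated — a fitness component decays to zero only
  algebraically (like `1/n`). The map is still well defined because the
  reciprocal in the `Q` update floors its argument at `1e-15`; reported
  fitness values are never floored. On such matrices the
  successive-difference criterion under-states the distance to the
  exact fixed point: two runs from different starts agree to roughly
  `sqrt(tolerance)`, not `tolerance`. The test suite pins this behavior
  on the canonical 2×2 dominated example.
* Mean-one normalization after every sweep makes the result invariant
  to any global rescaling of `W` (units cancel), which the tests check.

Ranking uses "largest = rank 1" with ties sharing the minimum rank and
lexicographic display order. `fitness_trajectory()` runs years
independently and aligns the results; no temporal smoothing is applied.

## Distribution fits

Degree distributions are summarised by the empirical CCDF
`P(X ≥ x)` and fitted with a three-parameter Weibull (shape α, scale β,
location μ); fitness and specialization values with a log-normal. The
log-normal MLE is the closed form (mean and 1/n-variance of the logs).
The Weibull location is estimated by profile likelihood: for each
candidate `μ < min(x)` the shifted two-parameter MLE is solved from the
shape score equation, and `μ` is chosen on a coarse grid refined by
golden-section search. Joint unconstrained maximization is ill-posed
when α ≤ 1 (the likelihood is unbounded as `μ → min(x)`), which the
profile approach with a strict `μ < min(x)` bound and a boundary flag
sidesteps. MLE, rather than least squares on the CCDF, is a documented
choice — the source procedure is unstated.

Because estimating parameters invalidates the plain Kolmogorov–Smirnov
p-value, goodness of fit uses a parametric bootstrap: each replicate is
drawn from the fitted law, refitted, and its KS distance compared with
the observed one (200 replicates by default, seeded). The printed fit
parameters of the original study are properties of its proprietary-scale
data extract and are *not* used as test targets; recovery tests draw
synthetic samples at comparable parameter values instead.

## The synthetic world

`simulate_panel()` provides ground truth for every stage. Countries get
i.i.d. log-normal capabilities `f*`, products log-normal difficulties
`q*`; a link exists with probability `1 − noise` when `f* ≥ q*` and
`noise` otherwise. This hard-threshold-plus-flip-noise mechanism is the
simplest generative model that produces the nested structure the
analysis assumes; at `noise = 0` the matrix is perfectly nested and
attains the maximal NODF its degree sequence allows. Link volumes are
`persons × exp(N(0, volume_sigma²))`, so per-capita weights are
log-normal — chosen because the fitted fitness and specialization
distributions are themselves log-normal-like. Defaults: 177 countries ×
157 products (the scale of a world production table), `noise = 0.05`
(small but non-zero assembly noise), `volume_sigma = 1` (volumes span
roughly two orders of magnitude within ±2σ, a realistic per-capita
spread), populations uniform on 0.6–100 million persons, above the
inclusion filter.

What a green test does **not** establish: the generator has no
temporal autocorrelation, no spatial or climatic covariates, no
correlation between population and capability, and volumes are
independent across links — so passing recovery tests demonstrate the
*algorithms* work where their assumptions hold, not that real
production data satisfies those assumptions.

## Reproducibility

Every stochastic entry point takes a seed and restores the caller's
RNG state. `run_pipeline()` records the seed and an MD5 hash of the
configuration (excluding the output directory) in `MANIFEST.json`
along with per-artifact checksums; re-running an identical
configuration reproduces every artifact byte for byte, which the
acceptance suite asserts. Weighted matrices are written with 17
significant digits so text round-trips are bit-exact. The per-file
config-hash header was deliberately traded away in favour of the
manifest so that matrix files stay directly machine-readable.

## Known limitations

* No degree-preserving null model; conclusions about nestedness are
  relative to the fixed-link-count random ensemble only.
* The isolated-endpoint forest rule is order-sensitive under exact
  weight ties; the lexicographic tie-break makes it deterministic but
  still arbitrary between genuinely tied edges.
* The fitness map's algebraically-decaying components mean reported
  low-fitness tails are upper bounds whose precision is set by the
  stopping rule, not machine precision.
* `fitness_trajectory()` treats years independently; country panels
  that change composition between years are aligned by label only.
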