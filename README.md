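# foodfitness

Network analysis of **country–food-production systems**. Given
long-format production (or import) records and a population table, the
package builds the bipartite country × product matrices

- binary `M` (`M[c,p] = 1` iff country *c* produces product *p* that
  year), and
- per-capita weighted `W[c,p] = tonnes / persons` (tons person⁻¹
  year⁻¹),

and answers three questions about them:

1. **Is the network nested?** Specialist countries' product baskets
   tend to be subsets of generalists'. The NODF statistic
   (`T_ij = o_ij / min(k_i, k_j)` over unordered same-side pairs,
   zero for equal degrees, normalised by `C(C−1)/2 + P(P−1)/2`) is
   compared against an ensemble of random networks with the same
   dimensions and link count, with an add-one empirical p-value and
   z-score.
2. **Which countries (products) form tightly correlated communities?**
   The one-mode projection `C = W Wᵀ` is normalised into the Dice-type
   similarity `S_ij = 2C_ij/(C_ii + C_jj)` and greedily pruned into a
   spanning **forest**: edges are scanned in decreasing weight and
   accepted only while one endpoint is still isolated, which splits
   the graph into disconnected sub-trees instead of one spanning tree.
3. **How do countries and products rank?** The coupled non-linear
   fitness–specialization map
   `F̃_c = Σ_p W_cp Q_p`, `Q̃_p = 1/Σ_c W_cp (1/F_c)` (each vector then
   normalised to mean 1) is iterated to its fixed point: fitness
   rewards a diversified, specialized basket; specialization penalises
   a product for every low-fitness country able to produce it.

Degree, fitness and specialization distributions are summarised by
empirical CCDFs with maximum-likelihood fits of the three-parameter
Weibull and the log-normal (parametric-bootstrap KS goodness of fit).
A synthetic-data generator with planted country capabilities and
product difficulties gives every stage a verifiable ground truth.

## Worked example

```r
library(foodfitness)

w <- simulate_panel(40, 30, noise = 0.05, seed = 42)
w$panel
#> bipartite_panel: year 2011, 40 countries x 30 products, 542 links (fill 0.452)

nodf_significance(w$panel$M, n_null = 100, seed = 43)
#> NODF = 0.8075 vs 100-network null: mean 0.4561, sd 0.0114
#> empirical p = 0.009901, z = 30.87

fit <- fitness_fixed_point(w$panel$W)
fit
#> fitness_result: 40 countries, 30 products; converged after 332 iterations (delta 9.3e-11)
head(rank_scores(fit$F), 3)
#>   label     value rank
#> 1  C012 14.616124    1
#> 2  C009  5.716178    2
#> 3  C025  3.575384    3

msf(similarity(project(w$panel, "country")))
#> forest (isolated rule): 40 nodes, 31 edges, 9 components
```

Reading the output: NODF = 0.81 on the 0–1 scale is far above the null
mean 0.46 (z ≈ 31) — the planted world is strongly nested, and the
empirical p of 1/101 is the smallest a 100-network ensemble can report.
The top-ranked country `C012` holds the largest planted capability in
this world; its fitness of 14.6 (against a population mean of 1) marks
it as the most diversified, most specialized producer. The forest
splits the 40 countries into 9 production communities.

For file-based runs, `read_records()` parses CSV/TSV production,
import and population tables (configurable column names),
`filter_countries()` applies the half-million population filter, and
`build_panel()` assembles the year's matrices.

## Command line

The full pipeline (panels → nestedness → forests → fitness →
distribution fits, plus a checksummed `MANIFEST.json`) runs via

```r
run_pipeline(run_config(simulate = TRUE, n_countries = 20,
                        n_products = 15, seed = 7, out_dir = "out"))
```

or from the shell through the installed script:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "foodfitness.R", package = "foodfitness"))')" \
  all --simulate TRUE --n_countries 20 --n_products 15 --seed 7 --out_dir out
```

Subcommands: `simulate | build | nestedness | msf | fitness | fitdist |
all`. Flags mirror `run_config()` field names; precedence is CLI flag >
`--config` file (`key = value` lines) > defaults. Exit codes: 0 ok,
1 usage, 2 data error, 3 fitness non-convergence under `--strict TRUE`.

## Documentation

See the methods vignette (`vignettes/methods.Rmd`) for the model
assumptions, numerical choices (tolerances, tie-breaks, degenerate
inputs), what the synthetic generator does and does not emulate, and
known limitations.
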