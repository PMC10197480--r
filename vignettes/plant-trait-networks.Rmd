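---
title: "Plant trait networks: model, resampling design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plant trait networks: model, resampling design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptnet)
library(dplyr)
```

## The model

A plant trait network treats each functional trait as a node and each
statistically significant pairwise association as an edge. The procedure has
three steps, each with assumptions worth making explicit.

**Log-transform.** Trait values (concentrations, areas, rates) are strictly
positive and right-skewed; `log_transform()` takes natural logarithms before
any correlation is computed. Pearson correlations are invariant to the log
base and to affine rescaling of the raw traits, so the choice of natural log
over log10 changes nothing downstream — the test suite asserts this
numerically. The positivity requirement is enforced at input: a zero or
negative trait value is an error, not a silent `NA`.

**Correlation and thresholding.** For every trait pair, `pairwise_pearson()`
computes r over pairwise-complete records and a two-sided p-value from
t = r√(n−2)/√(1−r²) on n−2 degrees of freedom, which assumes approximate
bivariate normality on the log scale. The adjacency is
a_ij = 1 ⟺ p_ij < α with α = 0.05 by default and a *strict* inequality
(p = α exactly is not an edge). Edges are unsigned: a significant negative
correlation is as much an interdependence as a positive one; the sign is kept
in the edge list for inspection. No multiple-testing correction is applied by
default, because the classical PTN recipe thresholds raw p-values across the
120 pairs; a Benjamini–Hochberg variant is available (`adjust = "BH"`) and
clearly labelled as a departure from that recipe. Missingness is handled
pairwise-complete with a minimum of `min_n = 4` observations per pair
(the smallest n for which the t reference has 2 df); sparser or
zero-variance pairs get p = 1 and can never be edges — in bootstrap
resamples this degrades gracefully instead of aborting a replicate.

**Parameters.** Degree, edge density and modularity are the three parameters
with an ecological reading: a high-degree (hub) trait is one whose variation
is entangled with most of the phenotype; high edge density means tight
coordination; high modularity means the phenotype decomposes into
semi-independent functional units. Modularity is Newman–Girvan
Q = Σ_c (e_cc − a_c²) on the binary graph.

## Numerical and algorithmic choices

- **Community detection.** The default is greedy agglomerative modularity
  maximisation, which is deterministic — module memberships are
  bit-reproducible across runs, which matters because module colourings are
  a primary reported output. The merge dendrogram is cut at the modularity
  maximum explicitly; this avoids a subtle failure on (near-)complete graphs
  where floating-point noise in the final merges can otherwise leave the cut
  one step short. Louvain is available behind `method = "louvain"` with a
  mandatory seed. Isolated traits form singleton modules, and the modularity
  of an edgeless network is defined as 0 (the formula is 0/0 there); both
  conventions arise naturally in small bootstrap resamples.
- **Hub ranking.** Ties in degree are broken lexicographically by trait name
  so `hub_traits()` is deterministic.
- **Duncan's multiple range test.** Implemented from first principles on
  `stats::qtukey`: items ranked by mean, pooled within-item mean square,
  harmonic-mean replicate count, and the span-p critical range at protection
  level 1 − (1 − α)^(p−1); a non-significant range shields all of its
  sub-ranges (step-down), and letters are maximal runs of mutually
  non-different items, `a` at the highest mean. The test suite validates the
  full letter-sharing relation against a second, independently structured
  step-down implementation on random problems.
- **Welch by default.** "Independent two-sample t-test" is implemented as
  Welch's unequal-variance test (pooled Student's t behind a flag). When both
  samples are constant and equal, t = 0, p = 1 by convention.
- **Seeds.** Every stochastic operation takes an explicit seed and derives
  per-replicate sub-seeds from it, so any single replicate can be regenerated
  in isolation and full pipeline runs are byte-identical given the same
  configuration.

## The resampling design

**Species bootstrap.** Uncertainty in the network parameters is quantified by
rebuilding the network on B random subsets of records, each keeping at least
three-fourths of them: the subset size is drawn uniformly from
[⌈0.75 n⌉, n] and records are sampled *without* replacement. A fixed-size
mode (always ⌈0.75 n⌉) exists because "at least three-fourths" is genuinely
ambiguous between the two readings. Summaries report mean, SD, SE = SD/√B,
min and max per parameter — including per-trait degree distributions, which
feed the Duncan letters and the error bars of degree plots. These bootstrap
replicates are *not* independent samples; Welch p-values computed on them are
descriptive contrasts, not confirmatory inference, and the documentation says
so wherever they appear.

**Rarefaction.** The species-number dependence is charted by drawing R
networks at each species count, by default *with* replacement (duplicates
kept as rows). Duplicated rows inflate the effective n of the p-values, which
pushes the false-edge rate above α as the count approaches the pool size; a
without-replacement mode exists and is what the calibration tests use. On
data with genuine correlations, mean edge density rises and mean modularity
falls with species count: small samples lack power, so their networks are
sparse and fragment into modules.

**Group comparison.** `split_groups()` divides records by life-form or by
aridity region with the boundary convention AI < 0.2 → arid,
AI ≥ 0.2 → semi-arid (the boundary value itself must land somewhere; it goes
to the semi-arid side and the convention is documented). Each group gets the
full pipeline; between-group contrasts use the bootstrap distributions.

## What the generator emulates — and what it does not

`simulate_traits()` draws records from a multivariate Gaussian on the log
scale and exponentiates, so marginals are lognormal (positive by
construction) and the planted correlation matrix is exact on the scale where
the pipeline works. The planted structure is block-modular: correlation
ρ_in within each block, ρ_out between blocks, with the three functional
categories (6/6/4 traits) as default blocks. Group effects multiply
(ρ_in, ρ_out) per group rather than shifting means, because the group
contrasts of interest concern connectivity, not trait levels. An optional
global hub trait is correlated at least ρ_hub with every other trait. The
implied correlation matrix is validated for positive semi-definiteness;
mild violations (e.g. block + hub constructions) are repaired with the
nearest correlation matrix and a warning, and repairs that would move entries
by more than 0.1 are errors.

Defaults are fixed at a realistic dryland survey: 188 records, 16 traits,
log-SD 0.6, ρ_in = 0.6, ρ_out = 0.1. With groups, the natural scale is ~94
records per group. For the group-contrast validation the baseline between-
category correlation is set to 0.2: real trait categories covary (the leaf
economics spectrum cuts across them), and with ρ_out = 0 the weaker group's
within-block correlations saturate the significance threshold at realistic
n, leaving no detectable group contrast to recover.

What the generator does **not** emulate: site or spatial structure,
phylogenetic signal, climate covariates, measurement error, or missingness
patterns. Passing the planted-recovery tests therefore shows the pipeline is
correct *given* block-structured exchangeable records; it does not show that
real floras satisfy those assumptions.

A limitation worth knowing when interpreting recovery tests: at high ρ_in a
block behaves like a single latent factor, and the *sample* correlation
between two blocks' factors exceeds the α = 0.05 threshold in roughly 3–5 %
of datasets per block pair — independent of n, because the threshold and the
factor-correlation spread both scale as 1/√n. When that happens, a coherent
sheet of cross-block edges appears and merging the two blocks genuinely
maximises Q, so no modularity-based algorithm can recover the planted
partition. Exact recovery across all three block pairs consequently tops out
around 80–90 % of seeds, not ~100 %, and the acceptance suite records this
ceiling rather than papering over it.

## Problem sizes used in the checks

The validation suite enumerates all labelled graphs on 2–6 nodes
exhaustively (plus 1000 random 16-node graphs) for the metric oracles; uses
200 Monte-Carlo replicates at n = 200 for the α-calibration; 50 seeds at
n = 500 for planted recovery; B = 500 for the bootstrap contract; 20 seeds ×
5 counts × R = 100 for rarefaction; and 20 seeds × B = 100 per group for the
group contrast. These sizes give Monte-Carlo standard errors comfortably
below the effect sizes being checked while keeping a full run of the suite
within a few minutes on one CPU.
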