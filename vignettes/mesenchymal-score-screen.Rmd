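---
title: "The mesenchymal-score screen: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mesenchymal-score screen: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtscreen)
```

## The screening model

Bulk tumor expression is a mixture. Writing $f_s \in [0,1]$ for the
stromal fraction of sample $s$, and $E_g$, $S_g$ for the pure epithelial
and stromal expression of gene $g$ on the linear scale, the observed bulk
signal is approximately

$$B_{gs} = (1-f_s)\,E_g + f_s\,S_g .$$

Because EMT-induced carcinoma cells imitate stromal cells
transcriptionally, any gene whose bulk expression co-varies with $f_s$
looks "mesenchymal" in bulk data regardless of which cell type expresses
it. The screen separates the two cases with two independent measurements:

* **Compartment of expression.** From paired micro-dissected tissue,
  the per-gene log fold change
  $L(x) = \log_2\!\big(\text{stroma}/\text{epithelium}\big)$.
  $L(x) > 0$: the gene lives in the stroma; $L(x) < 0$: in the carcinoma
  epithelium.
* **Bulk co-expression neighborhood.** For a target gene $g$, the
  genome-wide Pearson profile $r_g(x)$ across bulk samples, condensed into
  the *mesenchymal score*
  $$MS(g) = \operatorname{cor}_x\big(r_g(x),\, L(x)\big),$$
  the correlation — taken across genes — between $g$'s co-expression
  profile and the fold-change vector. $MS$ is high exactly when $g$'s
  co-expression neighbors are stroma-expressed genes.

A stromal gene has $MS \gg 0$ and $L > 0$. An epithelium-expressed EMT
mediator has $MS \gg 0$ yet $L < 0$ — it co-varies with the stromal
program without being stromal. Adding a per-gene univariable Cox Wald
statistic $z(g)$ (positive = adverse) yields the joint selection rule

$$MS(g) > 0.3, \qquad L(g) < 0, \qquad z(g) > 1.96,$$

with all three inequalities strict and genes missing any metric excluded
and counted. The assumptions worth stating: admixture is additive in
transcript abundance (hence linear-scale mixing); Pearson correlation is a
meaningful similarity on the chosen expression scale (hence the default
`log2(x+1)` transform for linear-scale inputs such as RSEM); and the
proportional-hazards approximation is adequate for a per-gene univariable
screen.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `pseudocount` | 1 | linear-scale offset before ratios; guards zeros |
| `aggregation` | `ratio_of_means` | how $L$ pools the tissue pairs |
| `exclude_self` | `TRUE` | drop the degenerate $(r_g(g)=1, L(g))$ pair |
| `log2_transform` | `TRUE` | apply $\log_2(x+1)$ to bulk input |
| `ms_min`, `log_ratio_max`, `z_min` | 0.3, 0, 1.96 | the selection rule |
| `transform` (Cox) | `log2p1` | per-gene covariate scale |
| `ties` (Cox) | `efron` | partial-likelihood tie correction |
| `distance`, `linkage`, `k` | `one_minus_pearson`, `average`, 2 | cell-line clustering |
| `split` (dichotomize) | *none* | mean- vs median-split, always explicit |

Design decisions where the method itself is underdetermined:

* **Aggregation of the tissue pairs.** Whether $L$ should be computed
  per-pair and averaged, or from pooled means, is an open choice. The
  default is `ratio_of_means` (mean linear expression across stroma
  columns over mean across epithelium columns, then log2) because it is
  robust to single-pair dropouts; `mean_of_ratios` is provided and both
  modes are tested against direct arithmetic.
* **Self-exclusion.** $r_g(g) = 1$ is a degenerate point that would pull
  every score toward the sign of $L(g)$; it is excluded by default and the
  flag is exposed.
* **No multiple-testing adjustment.** The screen uses the raw $z > 1.96$
  cut by design — it is a candidate-generation step, not a confirmatory
  test. An optional Benjamini–Hochberg mode (`fdr = TRUE` in
  `select_candidates()`) is off by default.
* **Chi-square form.** `chi2_independence()` defaults to the
  likelihood-ratio (G) form with the $0\ln(0/E)=0$ convention and no
  continuity correction: on small clinical 2×2 tables (including
  zero-cell tables) it is the form that reproduces standard clinical-table
  software output, which the test suite pins down against printed
  worked examples; the Pearson form is available and cross-checked against
  `chisq.test`.
* **Cox ties.** Efron's correction is the default (better with heavily
  tied, integer-like times). Note one subtlety the tests document: under
  Efron, duplicating every subject does *not* leave the estimate exactly
  unchanged — that invariance is a property of the plain (Breslow) partial
  likelihood, so `ties = "breslow"` is exposed and the invariance is
  asserted there.
* **Dichotomization.** Clinical survival comparisons use both mean- and
  median-splits in practice; `dichotomize()` therefore has *no default*
  split rule — callers must state it.
* **Clustering standardization.** Per-gene z-scoring before clustering is
  available but **off** by default. With 1−Pearson sample-profile
  distance, z-scoring is degenerate whenever group separation is carried
  by one shared program: every informative gene standardizes to the same
  two-group pattern, sample profiles become nearly flat, and profile
  correlations are driven by noise. Correlation on unstandardized
  log-expression (the common sample-dendrogram convention) retains the
  between-gene structure the correlation is computed over. Standardization
  pairs naturally with Euclidean distance instead.

## What the synthetic cohort emulates

`sim_config()` / `generate_cohort()` instantiate the mixture model
directly: $f_s \sim \mathrm{Beta}(2, 3)$ (mean 0.4 — no published purity
distribution exists for the motivating cohorts, so a flexible bounded
family with realistic spread was chosen once); log-normal archetype
profiles ($E_g \sim \mathcal N(6, 1.5^2)$ in log2 units); stromal
archetype genes elevated $+3$ log2 in stroma; planted mediators depleted
$-1$ log2 in stroma (epithelium-dominant, but modestly, as expected of a
gene that is induced rather than compartment-exclusive) and coupled to
stromal fraction in bulk with slope `mediator_coupling = 3` log2 units per
unit $f$; i.i.d. Gaussian log2 noise with `noise_sd = 0.4`. Mixing happens
on the linear scale and is reported in log2, so at zero noise the *linear*
bulk expression of every gene is exactly affine in $f$ (the tests assert
this; in log2 space the relation is monotone but concave). EMT activity is
the mediator coupling signal `mediator_coupling * f`; survival is
exponential with hazard $0.1\,e^{1.2 \cdot \text{activity}}$ — about a
hazard ratio of 2 per standard deviation of activity, a strong but
plausible prognostic effect — with exponential censoring scaled so the
censoring probability is exactly `censor_rate = 0.3`. The cell-line panel
is admixture-free; EMT-prone lines elevate the marker and mediator blocks
with gene-specific effect sizes (uniform 1–3 log2), which is what gives
EMT-prone lines correlated marker *profiles* rather than a flat offset.
The clinical-table generator plants a binary marker, a covariate linked to
it by a configurable odds ratio, and exponential survival.

What it deliberately does **not** emulate: count-level noise
(negative-binomial overdispersion, library-size effects), batch effects,
probe-level microarray artifacts, correlated background co-expression
modules, partial EMT continua, or gene-gene regulatory structure beyond
the single stromal program. Passing tests therefore demonstrate that the
screen's machinery is correct and calibrated under its own generative
assumptions — not that real cohorts satisfy those assumptions.

## Numerical choices and degenerate inputs

* The batch score uses the standardized-matrix product
  $R = Z Z_c^\top/(n-1)$ for the gene-gene correlation block, then a cheap
  per-gene correlation with $L$; it is tested to agree with the naive
  double loop to $10^{-10}$ and is invariant to positive affine rescaling
  of any gene and to sample order.
* Genes constant across bulk samples have no defined correlation: they are
  dropped from the score universe, flagged `constant_bulk`, and reported
  as `NA` rather than aborting the batch. A constant target, a constant
  $L$, or fewer than 3 usable genes raise errors.
* Zeros in both tissue compartments with `pseudocount = 0` yield `NA`
  fold changes, flagged, never `Inf`.
* Cox non-convergence (monotone likelihood / perfect separation) is
  detected and raised as an error in `cox_fit()`; the per-gene screen
  catches it, flags the gene `failed`, and continues.
* Mann–Whitney p-values are exact up to $n_a n_b \le 400$ without ties,
  tie-corrected normal approximation beyond; percentages round half-up
  (one decimal) and p-values to three decimals in `build_table_one()`,
  matching clinical-table formatting.
* EMT-prone cluster ties (equal mean marker expression) resolve to the
  lowest cluster ID and are flagged.

## Problem sizes used by the test suite

The suite exercises the full default cohort — 2000 genes, 200 bulk
samples, 13 micro-dissection pairs, 150 stromal archetype genes, 60
planted mediators — for the recovery and calibration checks, and
desk-scale cohorts (200–500 genes) for the per-module property tests;
calibration simulations use 2000 replicates (chi-square type-I error),
20 seeds × n = 1000 (Cox recovery), and 500 replicates (null uniformity
checks). These sizes give stable, seeded results while keeping the whole
suite fast.

## Known limitations

* Gene matching across the bulk, micro-dissection and cell-line inputs is
  exact-string on the ID intersection; no symbol aliasing or probe-to-gene
  mapping.
* The screen is univariable throughout; no adjustment for clinical
  covariates in the per-gene z-scores, no time-varying effects, no
  stratified Cox.
* The mesenchymal score inherits Pearson's sensitivity to outliers and to
  the chosen expression scale; rank-based profiles are not implemented.
* Threshold values (0.3, 0, 1.96) are conventions of the screen, not
  optimized quantities; monotonicity of selection in each threshold is
  tested, optimality is not claimed.
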