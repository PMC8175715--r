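# emtscreen

Screening bulk tumor expression for candidate epithelial–mesenchymal
transition (EMT) mediator genes.

## The problem

EMT-induced cancer cells acquire a stromal-like expression signature, so in
bulk tumor profiles the EMT signal is confounded with plain stromal
contamination: most of what looks "mesenchymal" in a bulk sample comes from
fibroblasts and other stromal cells, not from carcinoma cells undergoing
EMT. Genes that *drive* EMT from within the epithelium are therefore
invisible to naive differential expression.

`emtscreen` implements a screen that untangles the two signals by combining
three observable layers:

1. **Stroma:epithelium log fold change** `L(x)` from paired laser
   micro-dissected tissue — which compartment a gene is actually expressed
   in,
   `L(x) = log2( stroma expression / epithelium expression )`.
2. **Mesenchymal score** `MS(g)` from bulk co-expression — for a target
   gene *g*, first the genome-wide correlation profile
   `r_g(x) = cor( E_g, E_x )` across bulk samples, then
   `MS(g) = cor_x( r_g(x), L(x) )`,
   the correlation (across genes) between that profile and the fold-change
   vector. A high score means *g*'s co-expression neighborhood looks like
   the stromal program.
3. **Prognostic Cox z-score** `z(g)` — the Wald statistic from a
   univariable proportional-hazards fit of survival on the gene's
   expression; `z > 0` is adverse.

Candidate EMT mediators are genes with `MS > 0.3`, `L < 0` and `z > 1.96`
(all strict): epithelium-expressed, yet co-varying with stromal content in
bulk and carrying adverse prognostic weight — the signature expected of an
upstream EMT driver rather than a passively contaminating stromal gene.

The package also provides the surrounding statistics used to validate such
candidates clinically: Cox fits with Wald hazard ratios and 95% CIs,
Kaplan–Meier curves with mean- or median-split dichotomization, log-rank
tests, likelihood-ratio (G) and Pearson chi-square tests on contingency
tables, Mann–Whitney tests, a clinical "table one" builder, hierarchical
clustering of cell-line panels with EMT-prone cluster labeling, and a
synthetic-cohort generator with known ground truth for end-to-end testing.

## Worked example

```r
library(emtscreen)

cfg <- sim_config(n_genes = 500, n_bulk_samples = 120,
                  n_stromal_archetype = 60, n_planted_mediators = 20,
                  seed = 42)
sim <- generate_cohort(cfg)                      # bulk + ground truth
fit <- emt_screen(sim$bulk,
                  generate_microdissection(cfg, sim$truth),
                  generate_survival(cfg, sim$truth),
                  log2_transform = FALSE)        # simulator is already log2
fit
#> EMT mediator screen
#>   500 genes; score universe 500 genes; fold-change aggregation: ratio_of_means
#>   mesenchymal scores: 500 genes scored, median 0.049
#>   score-prognosis correlation: r = 0.820 (p = 1.11e-122, n = 500)
#>   candidates: 22 genes pass MS > 0.3 & log2 stroma:epi < 0 & z > 1.96

recovery_metrics(fit$candidates, sim$truth)[c("sensitivity", "precision")]
#> $sensitivity
#> [1] 1
#> $precision
#> [1] 0.9090909
```

The simulated cohort plants 20 mediator genes whose bulk expression is
coupled to each sample's stromal fraction while remaining
epithelium-dominant in pure tissue; the screen recovers all 20 (2 of the 22
selected genes are false positives). `coef(fit)` returns the
gene-by-metric matrix, `plot(fit)` draws the fold-change-versus-score
selection plane, and `summary(fit)` lists the top candidates.

Clinical association statistics reproduce standard printed tables, e.g. the
likelihood-ratio chi-square on a 2×2 marker-by-lymph-node table:

```r
chi2_independence(matrix(c(52, 15, 19, 14), 2, byrow = TRUE))
#> $statistic 4.185166  $df 1  $p.value 0.04077923
```

For file-based runs, `run_emt_pipeline()` reads TSV matrices, executes all
stages, and writes per-stage TSVs plus a JSON report with parameters, seed
and input hashes.

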