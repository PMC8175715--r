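test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(stromal_fraction_alpha = -1),
               "stromal_fraction_alpha")
  expect_error(sim_config(censor_rate = 1), "censor_rate")
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
  expect_error(sim_config(n_genes = 50, n_stromal_archetype = 40,
                          n_planted_mediators = 20), "n_stromal_archetype")
})

test_that("generators are bit-identical under the same config and seed", {
  cfg <- quick_config(seed = 9)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$bulk, s2$bulk)
  expect_identical(s1$truth$stromal_fraction, s2$truth$stromal_fraction)
  expect_identical(generate_microdissection(cfg, s1$truth),
                   generate_microdissection(cfg, s2$truth))
  expect_identical(generate_survival(cfg, s1$truth),
                   generate_survival(cfg, s2$truth))
  expect_identical(generate_cellline_panel(cfg), generate_cellline_panel(cfg))
  expect_identical(generate_clinical_table(cfg), generate_clinical_table(cfg))
})

test_that("bulk mixture degenerates to the pure archetypes at f = 0 and f = 1", {
  cfg0 <- quick_config(noise_sd = 0, fixed_stromal_fraction = 0, seed = 2)
  sim0 <- generate_cohort(cfg0)
  expect_equal(unname(sim0$bulk[, 1]),
               unname(sim0$truth$archetypes$epithelium), tolerance = 1e-12)
  expect_true(all(sim0$truth$emt_activity == 0))

  # at f = 1 the mixture itself is the stromal archetype; the mediator
  # coupling term is a separate additive signal, so switch it off here
  cfg1 <- quick_config(noise_sd = 0, fixed_stromal_fraction = 1,
                       mediator_coupling = 0, seed = 2)
  sim1 <- generate_cohort(cfg1)
  expect_equal(unname(sim1$bulk[, 3]),
               unname(sim1$truth$archetypes$stroma), tolerance = 1e-12)
})

test_that("at zero noise a stromal-archetype gene tracks the stromal fraction", {
  cfg <- quick_config(noise_sd = 0, seed = 4)
  sim <- generate_cohort(cfg)
  f <- sim$truth$stromal_fraction
  arch <- names(sim$truth$gene_role)[sim$truth$gene_role == "stromal_archetype"]
  # linear-scale bulk expression is exactly affine in f at zero noise
  r_lin <- vapply(arch, function(g) cor(2^sim$bulk[g, ], f), numeric(1))
  expect_true(all(r_lin > 0.999))
  # in log2 space the relation is monotone but concave
  r_log <- vapply(arch, function(g) cor(sim$bulk[g, ], f), numeric(1))
  expect_true(all(r_log > 0.95))
  expect_true(all(vapply(arch, function(g)
    cor(sim$bulk[g, ], f, method = "spearman"), numeric(1)) == 1))
})

test_that("microdissection separates roles by construction", {
  cfg <- quick_config(noise_sd = 0, seed = 5)
  sim <- generate_cohort(cfg)
  micro <- generate_microdissection(cfg, sim$truth)
  med <- names(sim$truth$gene_role)[sim$truth$gene_role == "planted_mediator"]
  # zero noise: mediators identical across epithelium columns
  expect_true(all(apply(micro$epithelium[med, ], 1,
                        function(v) length(unique(v)) == 1)))
  L <- stroma_epithelium_logfc(micro, pseudocount = 0)
  arch <- names(sim$truth$gene_role)[sim$truth$gene_role == "stromal_archetype"]
  expect_true(all(L[med] < 0))
  expect_true(all(L[arch] > 0))

  # default noise: stroma-vs-epithelium t statistic positive per archetype gene
  cfgn <- quick_config(seed = 1)
  simn <- generate_cohort(cfgn)
  micron <- generate_microdissection(cfgn, simn$truth)
  archn <- names(simn$truth$gene_role)[simn$truth$gene_role == "stromal_archetype"]
  tstats <- vapply(archn, function(g)
    t.test(micron$stroma[g, ], micron$epithelium[g, ])$statistic, numeric(1))
  expect_true(all(tstats > 0))

  expect_error(generate_microdissection(quick_config(n_genes = 100), sim$truth),
               "mismatch")
})

test_that("role separation holds at moderate noise", {
  cfg <- quick_config(noise_sd = 0.1, seed = 8)
  sim <- generate_cohort(cfg)
  L <- stroma_epithelium_logfc(generate_microdissection(cfg, sim$truth))
  med <- names(sim$truth$gene_role)[sim$truth$gene_role == "planted_mediator"]
  arch <- names(sim$truth$gene_role)[sim$truth$gene_role == "stromal_archetype"]
  expect_gte(mean(L[med] < 0), 0.95)
  expect_gte(mean(L[arch] > 0), 0.95)
})

test_that("survival generation honours censoring and the null", {
  cfg <- quick_config(censor_rate = 0, seed = 3)
  sim <- generate_cohort(cfg)
  surv <- generate_survival(cfg, sim$truth)
  expect_true(all(surv$event == 1))
  expect_equal(nrow(surv), cfg$n_bulk_samples)

  # hazard_coef = 0: event times are iid exponential(lambda0)
  cfg0 <- sim_config(n_genes = 20, n_bulk_samples = 3000,
                     n_stromal_archetype = 5, n_planted_mediators = 5,
                     hazard_coef = 0, censor_rate = 0, seed = 11)
  sim0 <- generate_cohort(cfg0)
  s0 <- generate_survival(cfg0, sim0$truth)
  expect_equal(mean(s0$time), 1 / cfg0$baseline_hazard, tolerance = 0.1)
  expect_gt(cor.test(s0$time, sim0$truth$stromal_fraction)$p.value, 0.01)
})

test_that("a Cox fit on true EMT activity recovers the hazard coefficient", {
  cfg <- sim_config(n_genes = 20, n_bulk_samples = 1000,
                    n_stromal_archetype = 5, n_planted_mediators = 5,
                    hazard_coef = 0.7, seed = 21)
  sim <- generate_cohort(cfg)
  surv <- generate_survival(cfg, sim$truth)
  d <- data.frame(time = surv$time, event = surv$event,
                  emt = sim$truth$emt_activity)
  fit <- cox_fit(d, "emt")
  expect_equal(fit$coefficients$beta, 0.7, tolerance = 0.1)
})

test_that("cell-line panel separates the EMT-prone subset", {
  cfg <- quick_config(seed = 6)
  panel <- generate_cellline_panel(cfg)
  expect_equal(length(panel$labels), cfg$n_celllines)
  med <- rownames(panel$expr)[generate_cohort(cfg)$truth$gene_role ==
                                "planted_mediator"]
  m_emt <- mean(panel$expr[med, panel$labels == "EMT_prone"])
  m_epi <- mean(panel$expr[med, panel$labels == "epithelial"])
  expect_gt(m_emt, m_epi)
})

test_that("clinical table matches its configured cell probabilities", {
  cfg <- quick_config(n_patients = 10000, marker_prevalence = 0.3,
                      covariate_odds_ratio = 2.5, covariate_base_rate = 0.4,
                      seed = 13)
  clin <- generate_clinical_table(cfg)
  expect_equal(nrow(clin), 10000)
  # analytic cell probabilities for the 2x2 marker x covariate table
  p_pos <- plogis(qlogis(0.4) + log(2.5))
  obs <- table(clin$marker, clin$lymphatic_invasion)
  expect_equal(mean(clin$marker), 0.3, tolerance = 0.02)
  expect_equal(obs["1", "present"] / sum(obs["1", ]), p_pos, tolerance = 0.02)
  expect_equal(obs["0", "present"] / sum(obs["0", ]), 0.4, tolerance = 0.02)
})

test_that("marker-covariate independence yields uniform G-test p-values", {
  p <- vapply(seq_len(500), function(i) {
    cfg <- quick_config(n_patients = 200, covariate_odds_ratio = 1,
                        seed = 5000 + i)
    clin <- generate_clinical_table(cfg)
    tab <- table(clin$marker, clin$lymphatic_invasion)
    chi2_independence(unclass(tab))$p.value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
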