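test_that("stroma:epithelium log fold change matches direct arithmetic", {
  micro <- fixture_micro()
  # identical compartments -> L = 0
  same <- micro
  same$stroma <- micro$epithelium
  colnames(same$stroma) <- colnames(micro$stroma)
  expect_equal(unname(stroma_epithelium_logfc(same, pseudocount = 0)),
               rep(0, 4), ignore_attr = TRUE)
  # stroma = 2 x epithelium -> L = +1 in both aggregation modes
  dbl <- micro
  dbl$stroma <- 2 * micro$epithelium
  colnames(dbl$stroma) <- colnames(micro$stroma)
  for (mode in c("ratio_of_means", "mean_of_ratios"))
    expect_equal(unname(stroma_epithelium_logfc(dbl, pseudocount = 0,
                                                aggregation = mode)),
                 rep(1, 4), ignore_attr = TRUE)
  # integer fixture, pseudocount 1: spreadsheet-style recomputation
  rom <- log2(rowMeans(micro$stroma) + 1) - log2(rowMeans(micro$epithelium) + 1)
  expect_equal(stroma_epithelium_logfc(micro, pseudocount = 1),
               rom, ignore_attr = TRUE)
  mor <- rowMeans(log2(micro$stroma + 1) - log2(micro$epithelium + 1))
  expect_equal(stroma_epithelium_logfc(micro, pseudocount = 1,
                                       aggregation = "mean_of_ratios"),
               mor, ignore_attr = TRUE)
})

test_that("log fold change validates inputs and handles scale/zeros", {
  micro <- fixture_micro()
  bad <- micro
  rownames(bad$stroma) <- paste0("x", 1:4)
  expect_error(stroma_epithelium_logfc(bad), "intersection")
  neg <- micro
  neg$epithelium[1, 1] <- -1
  expect_error(stroma_epithelium_logfc(neg), "negative")
  # declared-log2 input converts internally: log2 of the doubled matrix
  lg <- micro
  lg$epithelium <- log2(micro$epithelium)
  lg$stroma <- log2(2 * micro$epithelium)
  colnames(lg$stroma) <- colnames(micro$stroma)
  lg$log2 <- TRUE
  expect_equal(unname(stroma_epithelium_logfc(lg, pseudocount = 0)), rep(1, 4),
               ignore_attr = TRUE)
  # zero in both compartments with zero pseudocount -> NA
  z <- micro
  z$epithelium[2, ] <- 0
  z$stroma[2, ] <- 0
  expect_true(is.na(stroma_epithelium_logfc(z, pseudocount = 0)[2]))
})

test_that("correlation profile equals a naive per-pair Pearson loop", {
  bulk <- fixture_a()
  r <- correlation_profile(bulk, "g1")
  naive <- vapply(rownames(bulk),
                  function(g) naive_pearson(bulk["g1", ], bulk[g, ]),
                  numeric(1))
  expect_lt(max(abs(r - naive)), 1e-12)
  expect_identical(attr(r, "self"), "g1")
  # perfect and perfectly negated copies
  b2 <- rbind(bulk, dup = bulk["g1", ], neg = -bulk["g1", ])
  r2 <- correlation_profile(b2, "g1")
  expect_equal(unname(r2["dup"]), 1)
  expect_equal(unname(r2["neg"]), -1)
  # independence at large n
  set.seed(31)
  big <- matrix(rnorm(2 * 10000), 2, dimnames = list(c("a", "b"), NULL))
  colnames(big) <- paste0("s", 1:10000)
  expect_lt(abs(correlation_profile(big, "a")["b"]), 0.05)
  # errors
  expect_error(correlation_profile(bulk, "nope"), "unknown gene")
  cons <- rbind(bulk, flat = rep(5, 6))
  expect_error(correlation_profile(cons, "flat"), "constant")
})

test_that("mesenchymal score equals the naive double-loop oracle", {
  bulk <- fixture_a()
  L <- fixture_a_L()
  for (g in rownames(bulk)) {
    got <- mesenchymal_score(bulk, L, g)
    expect_lt(abs(got$score - naive_mesenchymal_score(bulk, L, g)), 1e-12)
    expect_equal(got$n_genes_used, 4L)
  }
  got_inc <- mesenchymal_score(bulk, L, "g1", exclude_self = FALSE)
  expect_lt(abs(got_inc$score -
                  naive_mesenchymal_score(bulk, L, "g1", FALSE)), 1e-12)
})

test_that("a two-point increasing score is exactly +1 and degeneracies error", {
  bulk <- fixture_a()[1:3, ]
  # after self-exclusion two gene pairs remain; arrange L increasing with r
  r <- correlation_profile(bulk, "g1")
  L <- setNames(rank(r) / 2, names(r))
  expect_equal(mesenchymal_score(bulk, L, "g1")$score, 1.0)
  expect_error(mesenchymal_score(bulk, setNames(rep(1, 3), rownames(bulk)),
                                 "g1"), "constant")
  expect_error(mesenchymal_score(fixture_a(),
                                 c(g1 = 1, g2 = 2), "g1"), "insufficient")
})

test_that("batch scores equal looped single-gene scores", {
  bulk <- fixture_a()
  L <- fixture_a_L()
  for (ex in c(TRUE, FALSE)) {
    st <- mesenchymal_score_all(bulk, L, exclude_self = ex)
    for (g in rownames(bulk)) {
      single <- mesenchymal_score(bulk, L, g, exclude_self = ex)
      row <- st[st$gene_id == g, ]
      expect_lt(abs(row$mesenchymal_score - single$score), 1e-10)
      expect_equal(row$n_genes_used, single$n_genes_used)
    }
  }
  # larger seeded case
  set.seed(77)
  big <- matrix(rnorm(30 * 20), 30, 20,
                dimnames = list(sprintf("G%02d", 1:30), paste0("s", 1:20)))
  Lb <- setNames(rnorm(30), rownames(big))
  stb <- mesenchymal_score_all(big, Lb)
  loop <- vapply(rownames(big),
                 function(g) mesenchymal_score(big, Lb, g)$score, numeric(1))
  expect_lt(max(abs(stb$mesenchymal_score - loop)), 1e-10)
  expect_true(all(abs(stb$mesenchymal_score) <= 1 + 1e-12))
})

test_that("scores are invariant to positive affine rescaling and sample order", {
  set.seed(12)
  bulk <- matrix(rnorm(10 * 8), 10, 8,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  L <- setNames(rnorm(10), rownames(bulk))
  base <- mesenchymal_score_all(bulk, L)
  resc <- bulk
  resc["g3", ] <- 2.5 * resc["g3", ] + 7
  expect_lt(max(abs(mesenchymal_score_all(resc, L)$mesenchymal_score -
                      base$mesenchymal_score)), 1e-10)
  perm <- bulk[, sample(ncol(bulk))]
  expect_lt(max(abs(mesenchymal_score_all(perm, L)$mesenchymal_score -
                      base$mesenchymal_score)), 1e-10)
})

test_that("batch scoring flags constant genes instead of aborting", {
  bulk <- rbind(fixture_a(), flat = rep(4, 6))
  L <- c(fixture_a_L(), flat = 0.2)
  st <- mesenchymal_score_all(bulk, L)
  expect_true(is.na(st$mesenchymal_score[st$gene_id == "flat"]))
  expect_equal(st$flags[st$gene_id == "flat"], "constant_bulk")
  expect_false(anyNA(st$mesenchymal_score[st$gene_id != "flat"]))
})

test_that("gene-set comparison reproduces the exact minimal Mann-Whitney p", {
  # set_a strictly above every background score: p is the exact two-sided
  # minimum for 8 vs 8, computed here by full enumeration
  scores <- setNames(c(seq(10, 17), seq_len(50) / 100),
                     c(paste0("a", 1:8), paste0("b", 1:50)))
  cmp <- compare_gene_set_scores(scores, paste0("a", 1:8), n_rep = 5,
                                 seed = 1)
  p_min <- mw_exact_p(scores[paste0("a", 1:8)], scores[paste0("b", 1:8)])
  expect_equal(p_min, 2 / choose(16, 8))
  expect_true(all(abs(cmp$p_values - p_min) < 1e-12))
  expect_equal(cmp$fraction_significant, 1)
})

test_that("gene-set comparison is calibrated under the null and reproducible", {
  set.seed(99)
  scores <- setNames(rnorm(200), paste0("g", 1:200))
  p <- vapply(seq_len(500), function(i) {
    set_a <- sample(names(scores), 8)
    compare_gene_set_scores(scores, set_a, n_rep = 1,
                            seed = 700 + i)$p_values
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.08)

  c1 <- compare_gene_set_scores(scores, paste0("g", 1:8), n_rep = 1, seed = 4)
  c2 <- compare_gene_set_scores(scores, paste0("g", 1:8), n_rep = 1, seed = 4)
  expect_identical(c1$draws, c2$draws)
  expect_error(compare_gene_set_scores(scores, paste0("g", 1:8), k = 500),
               "exceeds")
  expect_error(compare_gene_set_scores(scores, "absent"), "not among")
})

test_that("archetype and mediator genes outscore the background on synthetic data", {
  cfg <- quick_config(seed = 19)
  sim <- generate_cohort(cfg)
  L <- stroma_epithelium_logfc(generate_microdissection(cfg, sim$truth))
  st <- mesenchymal_score_all(sim$bulk, L)
  ms <- setNames(st$mesenchymal_score, st$gene_id)
  role <- sim$truth$gene_role
  expect_gt(mean(ms[role == "stromal_archetype"]),
            mean(ms[role == "epithelial_background"]))
  mw <- mann_whitney(ms[role == "planted_mediator"],
                     ms[role == "epithelial_background"])
  expect_lt(mw$p.value, 0.001)
})
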