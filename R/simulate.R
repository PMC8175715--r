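#' Configuration for the synthetic tumor-admixture cohort
#'
#' The simulator emulates the data-generating structure the screen assumes:
#' bulk tumor samples are convex linear-scale mixtures of a pure epithelial
#' and a pure stromal expression archetype, with per-sample stromal fraction
#' `f ~ Beta(alpha, beta)`. A block of stromal-archetype genes is elevated in
#' the stromal archetype; a block of planted EMT-mediator genes is
#' epithelium-dominant in pure tissue (log2 stroma:epithelium ratio below
#' zero) yet receives an additive log2-space coupling
#' `mediator_coupling * f` in bulk, so mediators co-vary with stromal content
#' exactly as an epithelium-expressed EMT program would. Survival hazard is
#' tied to the per-sample EMT activity (the mediator coupling signal).
#'
#' @param n_genes number of genes.
#' @param n_bulk_samples number of bulk tumor samples.
#' @param n_microdissection_pairs number of paired epithelium/stroma
#'   micro-dissected specimens (default 13).
#' @param n_celllines number of cell lines in the pure-tumor panel.
#' @param n_stromal_archetype number of stromal-archetype genes.
#' @param n_planted_mediators number of planted EMT-mediator genes.
#' @param stromal_fraction_alpha,stromal_fraction_beta Beta shape parameters
#'   of the per-sample stromal fraction.
#' @param mediator_coupling log2 units of bulk mediator expression added per
#'   unit stromal fraction.
#' @param noise_sd standard deviation of log2-space Gaussian noise.
#' @param hazard_coef log hazard ratio per unit EMT activity.
#' @param censor_rate probability a sample is censored rather than observed.
#' @param archetype_offset log2 elevation of archetype genes in stroma.
#' @param mediator_offset log2 depletion of mediator genes in stroma (their
#'   epithelial dominance in pure tissue).
#' @param baseline_hazard baseline event rate per time unit.
#' @param emt_prone_fraction fraction of cell lines in the EMT-prone group.
#' @param n_patients,marker_prevalence,covariate_odds_ratio,covariate_base_rate
#'   clinical-table parameters: cohort size, marker-positive probability,
#'   odds ratio linking the binary covariate to the marker, and the covariate
#'   rate in marker-negative patients.
#' @param fixed_stromal_fraction optional constant stromal fraction replacing
#'   the Beta draw (degenerate purity, used for mixture-consistency checks).
#' @param seed integer RNG seed; every generator is deterministic given the
#'   config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_bulk_samples = 200,
                       n_microdissection_pairs = 13,
                       n_celllines = 30,
                       n_stromal_archetype = 150,
                       n_planted_mediators = 60,
                       stromal_fraction_alpha = 2,
                       stromal_fraction_beta = 3,
                       mediator_coupling = 3,
                       noise_sd = 0.4,
                       hazard_coef = 1.2,
                       censor_rate = 0.3,
                       archetype_offset = 3,
                       mediator_offset = 1,
                       baseline_hazard = 0.1,
                       emt_prone_fraction = 0.4,
                       n_patients = 100,
                       marker_prevalence = 0.3,
                       covariate_odds_ratio = 2.5,
                       covariate_base_rate = 0.4,
                       fixed_stromal_fraction = NULL,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, n_bulk_samples = n_bulk_samples,
              n_microdissection_pairs = n_microdissection_pairs,
              n_celllines = n_celllines,
              n_stromal_archetype = n_stromal_archetype,
              n_planted_mediators = n_planted_mediators,
              stromal_fraction_alpha = stromal_fraction_alpha,
              stromal_fraction_beta = stromal_fraction_beta,
              mediator_coupling = mediator_coupling, noise_sd = noise_sd,
              hazard_coef = hazard_coef, censor_rate = censor_rate,
              archetype_offset = archetype_offset,
              mediator_offset = mediator_offset,
              baseline_hazard = baseline_hazard,
              emt_prone_fraction = emt_prone_fraction,
              n_patients = n_patients, marker_prevalence = marker_prevalence,
              covariate_odds_ratio = covariate_odds_ratio,
              covariate_base_rate = covariate_base_rate,
              fixed_stromal_fraction = fixed_stromal_fraction, seed = seed)
  counts <- c("n_genes", "n_bulk_samples", "n_microdissection_pairs",
              "n_celllines", "n_stromal_archetype", "n_planted_mediators",
              "n_patients")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop("invalid sim_config field '", f, "': must be a count >= 1",
           call. = FALSE)
  }
  if (n_stromal_archetype + n_planted_mediators > n_genes)
    stop("invalid sim_config field 'n_stromal_archetype': ",
         "n_stromal_archetype + n_planted_mediators must not exceed n_genes",
         call. = FALSE)
  for (f in c("stromal_fraction_alpha", "stromal_fraction_beta"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("invalid sim_config field '", f, "': Beta shape must be > 0",
           call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("invalid sim_config field 'noise_sd': must be >= 0", call. = FALSE)
  if (!is.numeric(censor_rate) || censor_rate < 0 || censor_rate >= 1)
    stop("invalid sim_config field 'censor_rate': must be in [0, 1)",
         call. = FALSE)
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0)
    stop("invalid sim_config field 'baseline_hazard': must be > 0",
         call. = FALSE)
  if (!is.null(fixed_stromal_fraction) &&
      (fixed_stromal_fraction < 0 || fixed_stromal_fraction > 1))
    stop("invalid sim_config field 'fixed_stromal_fraction': must be in [0, 1]",
         call. = FALSE)
  if (marker_prevalence <= 0 || marker_prevalence >= 1)
    stop("invalid sim_config field 'marker_prevalence': must be in (0, 1)",
         call. = FALSE)
  if (covariate_odds_ratio <= 0)
    stop("invalid sim_config field 'covariate_odds_ratio': must be > 0",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d genes (%d stromal archetype, %d planted mediators), %d bulk samples\n",
              x$n_genes, x$n_stromal_archetype, x$n_planted_mediators,
              x$n_bulk_samples))
  cat(sprintf("  stromal fraction ~ Beta(%g, %g); coupling %g; noise sd %g; seed %d\n",
              x$stromal_fraction_alpha, x$stromal_fraction_beta,
              x$mediator_coupling, x$noise_sd, x$seed))
  invisible(x)
}

# archetype log2 profiles and gene roles, deterministic given config$seed
sim_archetypes <- function(config) {
  set.seed(config$seed)
  g_ids <- sprintf("g%05d", seq_len(config$n_genes))
  role <- rep("epithelial_background", config$n_genes)
  role[seq_len(config$n_stromal_archetype)] <- "stromal_archetype"
  role[config$n_stromal_archetype + seq_len(config$n_planted_mediators)] <-
    "planted_mediator"
  names(role) <- g_ids
  epi <- rnorm(config$n_genes, mean = 6, sd = 1.5)
  str <- epi
  str[role == "stromal_archetype"] <-
    epi[role == "stromal_archetype"] + config$archetype_offset
  str[role == "planted_mediator"] <-
    epi[role == "planted_mediator"] - config$mediator_offset
  names(epi) <- names(str) <- g_ids
  list(gene_ids = g_ids, role = role, epithelium = epi, stroma = str)
}

#' Generate a bulk tumor cohort with known ground truth
#'
#' Per sample, a stromal fraction `f` is drawn from the configured Beta
#' distribution; bulk log2 expression is the log2 of the linear-scale convex
#' mixture `(1 - f) * 2^E + f * 2^S` of the epithelial and stromal archetype
#' profiles, plus `mediator_coupling * f` for planted mediators and Gaussian
#' log2 noise. Mixing is done in linear space because admixture of cell
#' populations is additive in transcript counts. The per-sample EMT activity
#' is the mediator coupling signal `mediator_coupling * f`.
#'
#' @param config a [sim_config()].
#' @return list with `bulk` (log2 expression matrix, genes x samples) and
#'   `truth`, an object of class `synthetic_truth` holding `gene_role`
#'   (named vector: stromal_archetype / planted_mediator /
#'   epithelial_background), `stromal_fraction`, `emt_activity`, and
#'   `true_hazard_coef`.
#' @examples
#' sim <- generate_cohort(sim_config(n_genes = 50, n_bulk_samples = 20))
#' dim(sim$bulk)
#' table(sim$truth$gene_role)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arch <- sim_archetypes(config)
  n <- config$n_bulk_samples
  s_ids <- sprintf("bulk%04d", seq_len(n))
  f <- if (!is.null(config$fixed_stromal_fraction)) {
    rep(config$fixed_stromal_fraction, n)
  } else {
    rbeta(n, config$stromal_fraction_alpha, config$stromal_fraction_beta)
  }
  names(f) <- s_ids
  mix <- log2(outer(2^arch$epithelium, 1 - f) + outer(2^arch$stroma, f))
  coupling <- outer(as.numeric(arch$role == "planted_mediator") *
                      config$mediator_coupling, f)
  noise <- matrix(rnorm(config$n_genes * n, 0, config$noise_sd),
                  config$n_genes, n)
  bulk <- mix + coupling + noise
  dimnames(bulk) <- list(arch$gene_ids, s_ids)
  truth <- structure(
    list(gene_role = arch$role,
         stromal_fraction = f,
         emt_activity = config$mediator_coupling * f,
         true_hazard_coef = config$hazard_coef,
         archetypes = arch[c("epithelium", "stroma")]),
    class = "synthetic_truth")
  list(bulk = bulk, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth:", length(x$gene_role), "genes,",
      length(x$stromal_fraction), "bulk samples\n")
  print(table(x$gene_role))
  invisible(x)
}

check_truth <- function(config, truth) {
  if (!inherits(truth, "synthetic_truth") ||
      length(truth$gene_role) != config$n_genes ||
      sum(truth$gene_role == "stromal_archetype") != config$n_stromal_archetype ||
      sum(truth$gene_role == "planted_mediator") != config$n_planted_mediators)
    stop("config/truth mismatch: truth was not produced by generate_cohort ",
         "with this config", call. = FALSE)
}

#' Generate paired micro-dissected epithelium and stroma profiles
#'
#' Emulates laser micro-dissection: each of the configured pairs contributes
#' one pure epithelium column drawn around the epithelial archetype and one
#' pure stroma column around the stromal archetype, with independent log2
#' noise. Planted mediators are epithelium-dominant (their stroma:epithelium
#' log2 ratio is negative by construction), stromal archetype genes
#' stroma-dominant.
#'
#' @param config a [sim_config()].
#' @param truth the `synthetic_truth` emitted by [generate_cohort()] under
#'   the same config.
#' @return object of class `microdissection_set`: list with log2 matrices
#'   `epithelium` and `stroma`, a `pairing` data.frame, and `log2 = TRUE`.
#' @export
generate_microdissection <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  check_truth(config, truth)
  set.seed(config$seed + 1L)
  p <- config$n_microdissection_pairs
  g <- config$n_genes
  epi <- matrix(truth$archetypes$epithelium, g, p) +
    matrix(rnorm(g * p, 0, config$noise_sd), g, p)
  str <- matrix(truth$archetypes$stroma, g, p) +
    matrix(rnorm(g * p, 0, config$noise_sd), g, p)
  e_ids <- sprintf("epi%02d", seq_len(p))
  s_ids <- sprintf("str%02d", seq_len(p))
  dimnames(epi) <- list(names(truth$gene_role), e_ids)
  dimnames(str) <- list(names(truth$gene_role), s_ids)
  structure(list(epithelium = epi, stroma = str,
                 pairing = data.frame(epithelium = e_ids, stroma = s_ids,
                                      stringsAsFactors = FALSE),
                 log2 = TRUE),
            class = "microdissection_set")
}

#' @export
print.microdissection_set <- function(x, ...) {
  cat(sprintf("Micro-dissection set: %d genes, %d epithelium/stroma pairs (%s scale)\n",
              nrow(x$epithelium), nrow(x$pairing),
              if (isTRUE(x$log2)) "log2" else "linear"))
  invisible(x)
}

#' Generate survival outcomes tied to EMT activity
#'
#' Event times are exponential with per-sample hazard
#' `baseline_hazard * exp(hazard_coef * emt_activity)`. Censoring is an
#' independent exponential time whose rate is scaled to the same per-sample
#' hazard so that the probability of being censored equals `censor_rate`
#' exactly.
#'
#' @inheritParams generate_microdissection
#' @return data.frame with `sample_id`, `time`, `event` (one row per bulk
#'   sample).
#' @export
generate_survival <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  check_truth(config, truth)
  set.seed(config$seed + 2L)
  lambda <- config$baseline_hazard *
    exp(config$hazard_coef * truth$emt_activity)
  n <- length(lambda)
  t_event <- rexp(n, lambda)
  if (config$censor_rate > 0) {
    t_cens <- rexp(n, lambda * config$censor_rate / (1 - config$censor_rate))
    data.frame(sample_id = names(truth$stromal_fraction),
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = names(truth$stromal_fraction),
               time = t_event, event = 1L, stringsAsFactors = FALSE)
  }
}

#' Generate a pure-tumor cell-line panel with an EMT-prone subset
#'
#' Cell lines carry no stromal admixture. A configured fraction of lines is
#' EMT-prone: both the mesenchymal-marker block (the stromal archetype genes)
#' and the planted mediators are elevated in those lines, each gene by its
#' own effect size (drawn once, uniform on 1-3 log2 units) - marker genes
#' respond to the mesenchymal program with gene-specific magnitudes, which
#' is also what gives EMT-prone lines correlated marker profiles.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (log2 matrix, genes x lines) and `labels`
#'   (named character vector, `EMT_prone` or `epithelial`).
#' @export
generate_cellline_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arch <- sim_archetypes(config)
  set.seed(config$seed + 3L)
  n <- config$n_celllines
  n_emt <- max(1L, round(config$emt_prone_fraction * n))
  l_ids <- sprintf("line%02d", seq_len(n))
  labels <- setNames(rep("epithelial", n), l_ids)
  labels[seq_len(n_emt)] <- "EMT_prone"
  in_block <- arch$role %in% c("stromal_archetype", "planted_mediator")
  shift <- in_block * runif(config$n_genes, 1, 3)
  expr <- matrix(arch$epithelium, config$n_genes, n) +
    outer(shift, as.numeric(labels == "EMT_prone")) +
    matrix(rnorm(config$n_genes * n, 0, config$noise_sd), config$n_genes, n)
  dimnames(expr) <- list(arch$gene_ids, l_ids)
  list(expr = expr, labels = labels)
}

#' Generate a clinical table with a marker-covariate association
#'
#' Emits one row per patient: a binary marker (0 = negative, 1 = positive),
#' a binary covariate (`lymphatic_invasion`) whose odds of being present are
#' multiplied by `covariate_odds_ratio` in marker-positive patients, an
#' independent `sex` covariate, `age`, and exponential survival with a
#' hazard ratio of 2 for marker-positive patients.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `patient_id`, `marker`, `lymphatic_invasion`,
#'   `sex`, `age`, `time`, `event`.
#' @export
generate_clinical_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  n <- config$n_patients
  marker <- rbinom(n, 1, config$marker_prevalence)
  p_cov <- plogis(qlogis(config$covariate_base_rate) +
                    log(config$covariate_odds_ratio) * marker)
  invasion <- rbinom(n, 1, p_cov)
  lambda <- config$baseline_hazard * exp(log(2) * marker)
  t_event <- rexp(n, lambda)
  t_cens <- if (config$censor_rate > 0) {
    rexp(n, lambda * config$censor_rate / (1 - config$censor_rate))
  } else rep(Inf, n)
  data.frame(patient_id = sprintf("pt%04d", seq_len(n)),
             marker = marker,
             lymphatic_invasion = ifelse(invasion == 1, "present", "absent"),
             sex = ifelse(rbinom(n, 1, 0.55) == 1, "male", "female"),
             age = round(rnorm(n, 66, 12), 1),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}
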