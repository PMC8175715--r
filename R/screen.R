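#' Per-gene prognostic Cox z-scores
#'
#' Fits one univariable Cox proportional-hazards model per gene, survival on
#' transformed expression, and reports the Wald z. A positive z is an
#' adverse prognostic association, negative z a favorable one. Failed fits
#' (separation, non-convergence) are flagged and excluded, not fatal.
#'
#' @param bulk expression matrix, genes x samples.
#' @param survival data.frame with `sample_id`, `time`, `event`; every bulk
#'   sample must be present.
#' @param transform expression transform before fitting: `"log2p1"`
#'   (log2(x + 1), the default for linear-scale abundances), `"raw"`, or
#'   `"zscore"`. The Wald z is invariant to affine covariate rescaling, so
#'   `zscore` changes beta but not z.
#' @return a `z_table` data.frame with columns `gene_id`, `beta`, `se`, `z`
#'   and `status` (`ok` / `failed`).
#' @export
prognostic_z_all <- function(bulk, survival,
                             transform = c("log2p1", "raw", "zscore")) {
  transform <- match.arg(transform)
  validate_expression_matrix(bulk, "bulk matrix")
  validate_survival_table(survival)
  common <- intersect(colnames(bulk), survival$sample_id)
  if (!length(common))
    stop("no overlapping samples between bulk matrix and survival table",
         call. = FALSE)
  surv <- survival[match(common, survival$sample_id), ]
  x <- bulk[, common, drop = FALSE]
  x <- switch(transform,
              raw = x,
              log2p1 = {
                if (any(x < 0))
                  stop("log2p1 transform requires nonnegative expression",
                       call. = FALSE)
                log2(x + 1)
              },
              zscore = t(scale(t(x))))
  if (sum(surv$event) < 1) stop("need at least one event", call. = FALSE)
  genes <- rownames(x)
  beta <- se <- z <- rep(NA_real_, length(genes))
  status <- rep("failed", length(genes))
  base <- data.frame(time = surv$time, event = surv$event)
  for (i in seq_along(genes)) {
    base$expr <- x[i, ]
    fit <- tryCatch(cox_fit(base, "expr"), error = function(e) NULL)
    if (!is.null(fit)) {
      beta[i] <- fit$coefficients$beta[1]
      se[i] <- fit$coefficients$se[1]
      z[i] <- fit$coefficients$z[1]
      status[i] <- "ok"
    }
  }
  structure(data.frame(gene_id = genes, beta = beta, se = se, z = z,
                       status = status, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("z_table", "data.frame"), transform = transform)
}

#' @export
print.z_table <- function(x, ...) {
  ok <- x$status == "ok"
  cat(sprintf("Prognostic z table: %d genes (%d fitted), transform = %s\n",
              nrow(x), sum(ok), attr(x, "transform")))
  if (any(ok))
    cat(sprintf("  z range %.2f .. %.2f; %d genes with z > 1.96\n",
                min(x$z[ok]), max(x$z[ok]), sum(x$z[ok] > 1.96)))
  invisible(x)
}

#' Joint selection thresholds for candidate EMT mediators
#'
#' The published selection rule: mesenchymal score above `ms_min`,
#' stroma:epithelium log2 ratio below `log_ratio_max` (epithelium-dominant),
#' and prognostic z above `z_min`. All inequalities are strict.
#'
#' @param ms_min minimum mesenchymal score (default 0.3).
#' @param log_ratio_max maximum log2 stroma:epithelium ratio (default 0).
#' @param z_min minimum prognostic Wald z (default 1.96, two-sided 5%).
#' @return object of class `selection_thresholds`.
#' @export
selection_thresholds <- function(ms_min = 0.3, log_ratio_max = 0,
                                 z_min = 1.96) {
  if (!is.numeric(ms_min) || ms_min <= -1 || ms_min >= 1)
    stop("ms_min must lie in (-1, 1)", call. = FALSE)
  structure(list(ms_min = ms_min, log_ratio_max = log_ratio_max,
                 z_min = z_min),
            class = "selection_thresholds")
}

#' @export
print.selection_thresholds <- function(x, ...) {
  cat(sprintf("Selection thresholds: MS > %g, log2 stroma:epi < %g, z > %g\n",
              x$ms_min, x$log_ratio_max, x$z_min))
  invisible(x)
}

#' Select candidate EMT mediator genes
#'
#' Applies the joint strict-inequality rule to the mesenchymal score table
#' and the prognostic z table. Genes missing any of the three metrics are
#' excluded and counted. No multiple-testing adjustment is applied - the
#' screen uses the raw z threshold by design; pass `fdr = TRUE` to use a
#' Benjamini-Hochberg adjusted q-value threshold of 0.05 on the one-sided
#' Wald p instead of `z_min`.
#'
#' @param scores a `score_table` from [mesenchymal_score_all()].
#' @param z a `z_table` from [prognostic_z_all()].
#' @param thresholds a [selection_thresholds()] object.
#' @param fdr apply BH correction to the prognosis criterion (default FALSE).
#' @return object of class `candidate_set`: data.frame of selected genes
#'   with their (MS, L, z) triplets, plus the thresholds and exclusion
#'   counts.
#' @export
select_candidates <- function(scores, z, thresholds = selection_thresholds(),
                              fdr = FALSE) {
  stopifnot(inherits(thresholds, "selection_thresholds"))
  m <- merge(scores[, c("gene_id", "mesenchymal_score", "log2_stroma_epi")],
             z[, c("gene_id", "z", "status")], by = "gene_id")
  if (!nrow(m))
    stop("empty gene intersection between score table and z table",
         call. = FALSE)
  complete <- is.finite(m$mesenchymal_score) & is.finite(m$log2_stroma_epi) &
    is.finite(m$z) & m$status == "ok"
  mc <- m[complete, ]
  prog_ok <- if (fdr) {
    q <- stats::p.adjust(pnorm(-mc$z), method = "BH")
    q < 0.05
  } else {
    mc$z > thresholds$z_min
  }
  sel <- mc$mesenchymal_score > thresholds$ms_min &
    mc$log2_stroma_epi < thresholds$log_ratio_max & prog_ok
  out <- mc[sel, c("gene_id", "mesenchymal_score", "log2_stroma_epi", "z")]
  names(out)[4] <- "cox_z"
  rownames(out) <- NULL
  structure(list(candidates = out, thresholds = thresholds, fdr = fdr,
                 n_tested = nrow(m), n_missing = sum(!complete),
                 n_selected = nrow(out)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("Candidate EMT mediators: %d selected of %d genes tested (%d excluded for missing metrics)\n",
              x$n_selected, x$n_tested, x$n_missing))
  print(x$thresholds)
  if (x$n_selected)
    print(head(x$candidates[order(-x$candidates$mesenchymal_score), ], 10),
          row.names = FALSE)
  invisible(x)
}

#' Correlation between mesenchymal scores and prognostic z-scores
#'
#' Gene-wise Pearson correlation between the two metrics across all genes
#' carrying both, with the two-sided p-value from the t distribution. A
#' positive correlation indicates that stroma-like co-expression carries
#' adverse prognostic weight.
#'
#' @inheritParams select_candidates
#' @return list with `r`, `p.value` and `n`.
#' @export
score_prognosis_correlation <- function(scores, z) {
  m <- merge(scores[, c("gene_id", "mesenchymal_score")],
             z[z$status == "ok", c("gene_id", "z")], by = "gene_id")
  m <- m[is.finite(m$mesenchymal_score) & is.finite(m$z), ]
  if (nrow(m) < 3)
    stop("need at least 3 genes with both metrics", call. = FALSE)
  if (sd(m$mesenchymal_score) == 0 || sd(m$z) == 0)
    stop("degenerate input: a metric is constant", call. = FALSE)
  ct <- cor.test(m$mesenchymal_score, m$z, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = nrow(m))
}

#' Recovery of planted mediators by the candidate screen
#'
#' Confusion-matrix summary of a candidate set against simulator ground
#' truth, with the planted-mediator role as the positive class. Sensitivity
#' = TP / (number of planted mediators); precision = TP / (number selected),
#' `NA` and flagged when nothing was selected; specificity = TN / (number of
#' non-mediator genes).
#'
#' @param candidates a `candidate_set` from [select_candidates()] or a
#'   character vector of gene IDs.
#' @param truth a `synthetic_truth` from [generate_cohort()].
#' @return list with `sensitivity`, `precision`, `specificity`, the counts,
#'   and `precision_defined`.
#' @export
recovery_metrics <- function(candidates, truth) {
  sel <- if (inherits(candidates, "candidate_set")) {
    candidates$candidates$gene_id
  } else as.character(candidates)
  roles <- truth$gene_role
  if (!all(sel %in% names(roles)))
    stop("truth does not cover all candidate genes", call. = FALSE)
  pos <- names(roles)[roles == "planted_mediator"]
  neg <- names(roles)[roles != "planted_mediator"]
  tp <- length(intersect(sel, pos))
  fp <- length(intersect(sel, neg))
  list(sensitivity = tp / length(pos),
       precision = if (length(sel)) tp / length(sel) else NA_real_,
       precision_defined = length(sel) > 0,
       specificity = (length(neg) - fp) / length(neg),
       n_selected = length(sel), n_true_positive = tp,
       n_planted = length(pos))
}
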