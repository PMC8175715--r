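#' Screen bulk tumor expression for candidate EMT mediator genes
#'
#' The central fitting function of the package. Given bulk tumor expression,
#' paired micro-dissected epithelium/stroma profiles and per-sample survival,
#' it (1) computes the stroma:epithelium log2 fold-change vector `L`,
#' (2) scores every gene by its mesenchymal score - the correlation between
#' the gene's genome-wide bulk co-expression profile and `L`, (3) fits one
#' univariable Cox model per gene for a prognostic Wald z, and (4) selects
#' candidate EMT mediators as genes that are epithelium-dominant in pure
#' tissue (`L < 0`) yet stroma-like in bulk co-expression (high score) and
#' prognostically adverse (high z). Optionally a pure cell-line panel is
#' clustered on the markers plus candidates and the EMT-prone cluster
#' labeled.
#'
#' @param bulk expression matrix, genes x samples. If `log2_transform` is
#'   TRUE (default, appropriate for linear-scale abundances such as RSEM),
#'   `log2(x + 1)` is applied before any correlation or Cox work.
#' @param microdissection a `microdissection_set` (see
#'   [generate_microdissection()] for the structure).
#' @param survival optional data.frame (`sample_id`, `time`, `event`);
#'   without it only `L` and the scores are computed.
#' @param panel optional cell-line expression matrix to cluster.
#' @param marker_genes marker gene IDs used (together with the selected
#'   candidates) to cluster the panel and label the EMT-prone cluster;
#'   required when `panel` is given.
#' @param log2_transform apply `log2(x + 1)` to `bulk` (and `panel`).
#' @param pseudocount,aggregation passed to [stroma_epithelium_logfc()].
#' @param exclude_self passed to [mesenchymal_score_all()].
#' @param thresholds a [selection_thresholds()] object.
#' @param k number of cell-line clusters (default 2).
#' @param distance,linkage passed to [hierarchical_cluster()].
#' @return object of class `emt_screen` with components `L`, `scores`
#'   (a `score_table`), `z` (a `z_table` or NULL), `candidates`
#'   (a `candidate_set` or NULL), `score_z_cor`, `clustering` (tree +
#'   labels or NULL) and `params`. Methods: `print`, `summary`, `coef`
#'   (gene-by-metric matrix), `plot` (selection plane).
#' @examples
#' cfg <- sim_config(n_genes = 120, n_bulk_samples = 60,
#'                   n_stromal_archetype = 20, n_planted_mediators = 10,
#'                   seed = 7)
#' sim <- generate_cohort(cfg)
#' fit <- emt_screen(sim$bulk, generate_microdissection(cfg, sim$truth),
#'                   generate_survival(cfg, sim$truth),
#'                   log2_transform = FALSE)
#' fit
#' @export
emt_screen <- function(bulk, microdissection, survival = NULL, panel = NULL,
                       marker_genes = NULL, log2_transform = TRUE,
                       pseudocount = 1,
                       aggregation = c("ratio_of_means", "mean_of_ratios"),
                       exclude_self = TRUE,
                       thresholds = selection_thresholds(), k = 2,
                       distance = c("one_minus_pearson", "euclidean"),
                       linkage = c("average", "complete", "ward")) {
  aggregation <- match.arg(aggregation)
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  validate_expression_matrix(bulk, "bulk matrix")
  if (!is.null(panel) && is.null(marker_genes))
    stop("marker_genes is required when a cell-line panel is given",
         call. = FALSE)
  if (log2_transform) {
    if (any(bulk < 0))
      stop("log2_transform requires nonnegative bulk expression",
           call. = FALSE)
    bulk <- log2(bulk + 1)
    if (!is.null(panel)) panel <- log2(panel + 1)
  }
  L <- stroma_epithelium_logfc(microdissection, pseudocount = pseudocount,
                               aggregation = aggregation)
  scores <- mesenchymal_score_all(bulk, L, exclude_self = exclude_self)
  z <- candidates <- score_z_cor <- clustering <- NULL
  if (!is.null(survival)) {
    z <- prognostic_z_all(bulk, survival, transform = "raw")
    candidates <- select_candidates(scores, z, thresholds)
    score_z_cor <- score_prognosis_correlation(scores, z)
  }
  if (!is.null(panel)) {
    subset <- unique(c(marker_genes,
                       if (!is.null(candidates))
                         candidates$candidates$gene_id))
    tree <- hierarchical_cluster(panel, gene_subset = subset,
                                 distance = distance, linkage = linkage)
    labels <- cut_and_label_emt(tree, panel, marker_genes, k = k)
    clustering <- list(tree = tree, labels = labels)
  }
  structure(list(L = L, scores = scores, z = z, candidates = candidates,
                 score_z_cor = score_z_cor, clustering = clustering,
                 params = list(log2_transform = log2_transform,
                               pseudocount = pseudocount,
                               aggregation = aggregation,
                               exclude_self = exclude_self,
                               thresholds = thresholds, k = k,
                               distance = distance, linkage = linkage),
                 call = match.call()),
            class = "emt_screen")
}

#' @export
print.emt_screen <- function(x, ...) {
  cat("EMT mediator screen\n")
  cat(sprintf("  %d genes; score universe %d genes; fold-change aggregation: %s\n",
              nrow(x$scores), attr(x$scores, "n_universe"),
              x$params$aggregation))
  ok <- is.finite(x$scores$mesenchymal_score)
  cat(sprintf("  mesenchymal scores: %d genes scored, median %.3f\n",
              sum(ok), median(x$scores$mesenchymal_score[ok])))
  if (!is.null(x$score_z_cor))
    cat(sprintf("  score-prognosis correlation: r = %.3f (p = %.3g, n = %d)\n",
                x$score_z_cor$r, x$score_z_cor$p.value, x$score_z_cor$n))
  if (!is.null(x$candidates))
    cat(sprintf("  candidates: %d genes pass MS > %g & log2 stroma:epi < %g & z > %g\n",
                x$candidates$n_selected, x$params$thresholds$ms_min,
                x$params$thresholds$log_ratio_max, x$params$thresholds$z_min))
  if (!is.null(x$clustering))
    cat(sprintf("  cell-line panel: EMT-prone cluster = %d of %d\n",
                x$clustering$labels$emt_cluster,
                length(x$clustering$labels$cluster_marker_means)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.emt_screen <- function(object, ...) {
  co <- coef(object)
  top <- NULL
  if (!is.null(object$candidates) && object$candidates$n_selected) {
    top <- object$candidates$candidates
    top <- top[order(-top$mesenchymal_score), ]
  }
  structure(list(n_genes = nrow(object$scores),
                 n_scored = sum(is.finite(object$scores$mesenchymal_score)),
                 score_quartiles = quantile(co[, "mesenchymal_score"],
                                            c(.25, .5, .75), na.rm = TRUE),
                 score_z_cor = object$score_z_cor,
                 n_candidates = if (!is.null(object$candidates))
                   object$candidates$n_selected else NA_integer_,
                 top_candidates = head(top, 10),
                 thresholds = object$params$thresholds),
            class = "summary.emt_screen")
}

#' @export
print.summary.emt_screen <- function(x, ...) {
  cat(sprintf("EMT mediator screen: %d/%d genes scored\n",
              x$n_scored, x$n_genes))
  cat("  mesenchymal score quartiles: ",
      paste(sprintf("%.3f", x$score_quartiles), collapse = " / "), "\n")
  if (!is.null(x$score_z_cor))
    cat(sprintf("  score-prognosis correlation r = %.3f (p = %.3g)\n",
                x$score_z_cor$r, x$score_z_cor$p.value))
  if (!is.na(x$n_candidates)) {
    cat(sprintf("  %d candidate EMT mediators", x$n_candidates))
    print(x$thresholds)
    if (!is.null(x$top_candidates)) {
      cat("  top candidates by mesenchymal score:\n")
      print(x$top_candidates, row.names = FALSE)
    }
  }
  invisible(x)
}

#' @export
coef.emt_screen <- function(object, ...) {
  m <- cbind(mesenchymal_score = object$scores$mesenchymal_score,
             log2_stroma_epi = object$scores$log2_stroma_epi,
             cox_z = if (!is.null(object$z))
               object$z$z[match(object$scores$gene_id, object$z$gene_id)]
             else NA_real_)
  rownames(m) <- object$scores$gene_id
  m
}

#' Selection-plane plot of an EMT screen
#'
#' Scatter of the stroma:epithelium log2 fold change (x) against the
#' mesenchymal score (y); selected candidates are highlighted and the
#' selection region (x below the fold-change threshold, y above the score
#' threshold) is framed.
#'
#' @param x an `emt_screen` object.
#' @param ... further arguments to [plot.default()].
#' @export
plot.emt_screen <- function(x, ...) {
  co <- coef(x)
  keep <- is.finite(co[, 1]) & is.finite(co[, 2])
  plot.default(co[keep, "log2_stroma_epi"], co[keep, "mesenchymal_score"],
               pch = 16, cex = 0.4, col = "grey60",
               xlab = "log2 stroma : epithelium",
               ylab = "mesenchymal score", ...)
  th <- x$params$thresholds
  rect(min(co[keep, 2], na.rm = TRUE) - 1, th$ms_min, th$log_ratio_max,
       1.05, border = "red", lty = 2)
  if (!is.null(x$candidates) && x$candidates$n_selected) {
    sel <- x$candidates$candidates
    points(sel$log2_stroma_epi, sel$mesenchymal_score, pch = 16,
           cex = 0.5, col = "red")
  }
  abline(h = th$ms_min, col = "red", lty = 3)
  abline(v = th$log_ratio_max, col = "red", lty = 3)
  invisible(x)
}
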