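#' Stroma-to-epithelium log2 fold change
#'
#' Computes, per gene, the log2 ratio of expression in micro-dissected cancer
#' stroma to micro-dissected cancer epithelium. Matrices flagged as log2 are
#' converted to linear scale internally; ratios are always formed on linear
#' values after adding the pseudocount. Two aggregation modes over the paired
#' specimens are available: `ratio_of_means` (default; mean linear expression
#' across stroma samples over mean across epithelium samples, then log2 -
#' robust to single-pair dropouts) and `mean_of_ratios` (log2 ratio per pair,
#' averaged).
#'
#' @param micro a `microdissection_set`: list with `epithelium` and `stroma`
#'   matrices, a `pairing` data.frame (`epithelium`, `stroma` sample IDs) and
#'   a logical `log2` scale flag.
#' @param pseudocount nonnegative value added to linear expression before
#'   forming ratios (default 1), guarding against zeros.
#' @param aggregation `"ratio_of_means"` or `"mean_of_ratios"`.
#' @return named numeric vector `L` over the gene intersection of the two
#'   matrices, with attributes `kind = "log_ratio_L"`, `aggregation` and
#'   `pseudocount`. Genes with zero in both compartments and zero pseudocount
#'   are `NA`.
#' @export
stroma_epithelium_logfc <- function(micro, pseudocount = 1,
                                    aggregation = c("ratio_of_means",
                                                    "mean_of_ratios")) {
  aggregation <- match.arg(aggregation)
  if (!is.numeric(pseudocount) || pseudocount < 0)
    stop("pseudocount must be >= 0", call. = FALSE)
  epi <- micro$epithelium
  str <- micro$stroma
  validate_expression_matrix(epi, "epithelium matrix")
  validate_expression_matrix(str, "stroma matrix")
  genes <- intersect(rownames(epi), rownames(str))
  if (!length(genes))
    stop("empty gene intersection between epithelium and stroma matrices",
         call. = FALSE)
  epi <- epi[genes, , drop = FALSE]
  str <- str[genes, , drop = FALSE]
  if (isTRUE(micro$log2)) {
    epi <- 2^epi
    str <- 2^str
  }
  if (any(epi < 0) || any(str < 0))
    stop("negative linear-scale expression values", call. = FALSE)
  if (aggregation == "ratio_of_means") {
    L <- log2(rowMeans(str) + pseudocount) - log2(rowMeans(epi) + pseudocount)
  } else {
    pr <- micro$pairing
    if (is.null(pr) || !all(pr$epithelium %in% colnames(epi)) ||
        !all(pr$stroma %in% colnames(str)))
      stop("mean_of_ratios requires a pairing referencing existing samples",
           call. = FALSE)
    per_pair <- log2(str[, pr$stroma, drop = FALSE] + pseudocount) -
      log2(epi[, pr$epithelium, drop = FALSE] + pseudocount)
    L <- rowMeans(per_pair)
  }
  L[!is.finite(L)] <- NA_real_
  structure(setNames(as.numeric(L), genes), kind = "log_ratio_L",
            aggregation = aggregation, pseudocount = pseudocount)
}

#' Genome-wide co-expression profile of a target gene
#'
#' Pearson correlation, across bulk samples, between the target gene and
#' every gene in the matrix. Genes constant across samples yield `NA`
#' (Pearson undefined); the self-correlation is 1 and the target is recorded
#' in the `self` attribute.
#'
#' @param bulk log2 (or otherwise comparably scaled) expression matrix,
#'   genes x samples, at least 3 samples.
#' @param target_gene gene ID present in the matrix.
#' @return named numeric vector `r` with attributes `kind =
#'   "correlation_profile_r"` and `self = target_gene`.
#' @export
correlation_profile <- function(bulk, target_gene) {
  validate_expression_matrix(bulk, "bulk matrix")
  if (ncol(bulk) < 3)
    stop("need at least 3 bulk samples", call. = FALSE)
  if (!target_gene %in% rownames(bulk))
    stop("unknown gene: ", target_gene, call. = FALSE)
  x <- bulk[target_gene, ]
  if (sd(x) == 0)
    stop("target gene ", target_gene, " is constant across samples",
         call. = FALSE)
  r <- suppressWarnings(as.numeric(cor(x, t(bulk))))
  names(r) <- rownames(bulk)
  r[target_gene] <- 1
  structure(r, kind = "correlation_profile_r", self = target_gene)
}

# genes usable for scoring: present in both bulk and L, non-constant, finite L
ms_common_genes <- function(bulk, L) {
  keep <- names(L)[is.finite(L)]
  genes <- intersect(rownames(bulk), keep)
  sds <- apply(bulk[genes, , drop = FALSE], 1, sd)
  genes[sds > 0]
}

#' Mesenchymal score of a single gene
#'
#' The mesenchymal score of a target gene is the Pearson correlation, taken
#' across genes, between the target's genome-wide bulk co-expression profile
#' and the stroma:epithelium log2 fold-change vector. A high score means the
#' target's co-expression neighborhood looks like the stromal program - the
#' signature of either a stromal gene or an epithelium-expressed EMT
#' mediator.
#'
#' @inheritParams correlation_profile
#' @param L log2 stroma:epithelium fold-change vector from
#'   [stroma_epithelium_logfc()].
#' @param exclude_self drop the degenerate self pair (r = 1, L(target))
#'   before correlating (default TRUE).
#' @return list with `score`, `n_genes_used` and `target_gene`.
#' @export
mesenchymal_score <- function(bulk, L, target_gene, exclude_self = TRUE) {
  r <- correlation_profile(bulk, target_gene)
  common <- intersect(ms_common_genes(bulk, L), names(r)[is.finite(r)])
  if (length(common) < 3)
    stop("insufficient data: fewer than 3 usable genes shared by bulk and L",
         call. = FALSE)
  use <- if (exclude_self) setdiff(common, target_gene) else common
  if (sd(L[use]) == 0)
    stop("degenerate input: L is constant across usable genes", call. = FALSE)
  list(score = as.numeric(cor(r[use], L[use])),
       n_genes_used = length(use),
       target_gene = target_gene)
}

#' Mesenchymal scores of all genes
#'
#' Batch version of [mesenchymal_score()]: the full gene-gene correlation
#' matrix is obtained as a standardized-matrix product and each row is then
#' correlated with the fold-change vector. Numerically equal to looping
#' [mesenchymal_score()] over genes. Per-gene degeneracies (constant bulk
#' expression, missing fold change) are flagged, not fatal.
#'
#' @inheritParams mesenchymal_score
#' @return a `score_table` data.frame with columns `gene_id`,
#'   `mesenchymal_score`, `n_genes_used`, `log2_stroma_epi` and `flags`.
#' @export
mesenchymal_score_all <- function(bulk, L, exclude_self = TRUE) {
  validate_expression_matrix(bulk, "bulk matrix")
  if (ncol(bulk) < 3) stop("need at least 3 bulk samples", call. = FALSE)
  genes <- rownames(bulk)
  sds <- apply(bulk, 1, sd)
  common <- ms_common_genes(bulk, L)
  if (length(common) < 3)
    stop("insufficient data: fewer than 3 usable genes shared by bulk and L",
         call. = FALSE)
  if (sd(L[common]) == 0)
    stop("degenerate input: L is constant across usable genes", call. = FALSE)

  scoreable <- genes[sds > 0]
  Z <- bulk[scoreable, , drop = FALSE]
  Z <- (Z - rowMeans(Z)) / apply(Z, 1, sd)
  Zc <- Z[common, , drop = FALSE]
  # rows: all scoreable genes; columns: the common gene universe
  R <- tcrossprod(Z, Zc) / (ncol(bulk) - 1)

  Lc <- L[common]
  ms <- rep(NA_real_, length(genes))
  nused <- rep(NA_integer_, length(genes))
  names(ms) <- names(nused) <- genes
  idx_self <- match(scoreable, common)  # NA when gene not part of universe
  for (i in seq_along(scoreable)) {
    g <- scoreable[i]
    if (exclude_self && !is.na(idx_self[i])) {
      use <- -idx_self[i]
      ms[g] <- cor(R[i, use], Lc[use])
      nused[g] <- length(common) - 1L
    } else {
      ms[g] <- cor(R[i, ], Lc)
      nused[g] <- length(common)
    }
  }
  flags <- rep("", length(genes))
  flags[sds == 0] <- "constant_bulk"
  flags[!(genes %in% names(L))] <- paste0(flags[!(genes %in% names(L))],
                                          ";missing_L")
  flags <- sub("^;", "", flags)
  out <- data.frame(gene_id = genes,
                    mesenchymal_score = as.numeric(ms),
                    n_genes_used = as.integer(nused),
                    log2_stroma_epi = as.numeric(L[genes]),
                    flags = flags,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("score_table", "data.frame"),
            exclude_self = exclude_self, n_universe = length(common))
}

#' @export
print.score_table <- function(x, ...) {
  ok <- is.finite(x$mesenchymal_score)
  cat(sprintf("Mesenchymal score table: %d genes (%d scored), universe %d genes\n",
              nrow(x), sum(ok), attr(x, "n_universe")))
  if (any(ok)) {
    q <- quantile(x$mesenchymal_score[ok], c(0, .25, .5, .75, 1))
    cat(sprintf("  score range %.3f .. %.3f (median %.3f)\n",
                q[1], q[5], q[3]))
  }
  invisible(x)
}

#' Compare mesenchymal scores of a gene set against random gene sets
#'
#' For each repetition, `k` genes are drawn uniformly without replacement
#' from the scored genes outside `set_a`, and the score distributions of
#' `set_a` and the random draw are compared by a two-sided Mann-Whitney U
#' test (exact when sample sizes permit and there are no ties). Mirrors the
#' known-markers-versus-random-genes comparison used to validate that
#' established mesenchymal markers rank high.
#'
#' @param scores a `score_table` from [mesenchymal_score_all()] or a named
#'   numeric vector of scores.
#' @param set_a character vector of gene IDs, all present among the scored
#'   genes (default [emt_marker_genes]).
#' @param k size of each random draw (default `length(set_a)`).
#' @param n_rep number of repetitions (default 20).
#' @param seed optional RNG seed for the draws.
#' @return list of class `gene_set_comparison`: per-rep `p_values`, the
#'   `fraction_significant` at 0.05, and the drawn sets.
#' @export
compare_gene_set_scores <- function(scores, set_a = emt_marker_genes,
                                    k = length(set_a), n_rep = 20,
                                    seed = NULL) {
  s <- if (inherits(scores, "score_table")) {
    setNames(scores$mesenchymal_score, scores$gene_id)
  } else scores
  s <- s[is.finite(s)]
  missing_a <- setdiff(set_a, names(s))
  if (length(missing_a))
    stop("set_a genes not among scored genes: ",
         paste(head(missing_a, 5), collapse = ", "), call. = FALSE)
  if (k < 1 || n_rep < 1) stop("k and n_rep must be >= 1", call. = FALSE)
  pool <- setdiff(names(s), set_a)
  if (k > length(pool))
    stop("k exceeds the number of available background genes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  a <- s[set_a]
  draws <- vector("list", n_rep)
  p <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    draws[[i]] <- sample(pool, k)
    b <- s[draws[[i]]]
    p[i] <- mann_whitney(a, b)$p.value
  }
  structure(list(p_values = p, fraction_significant = mean(p < 0.05),
                 set_a = set_a, k = k, n_rep = n_rep, draws = draws),
            class = "gene_set_comparison")
}

#' @export
print.gene_set_comparison <- function(x, ...) {
  cat(sprintf("Gene-set score comparison: %d genes vs %d random genes, %d reps\n",
              length(x$set_a), x$k, x$n_rep))
  cat(sprintf("  median p = %.3g; fraction of reps with p < 0.05: %.2f\n",
              median(x$p_values), x$fraction_significant))
  invisible(x)
}
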