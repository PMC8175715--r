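#' Hierarchical clustering of samples on a gene subset
#'
#' Agglomerative clustering of expression columns (samples or cell lines):
#' distances are 1 - Pearson correlation between sample log-expression
#' profiles by default (the usual sample-dendrogram convention) with average
#' linkage; Euclidean distance and complete or Ward linkage are available.
#' Per-gene z-score standardization is available but off by default: with
#' correlation distance it removes the between-gene expression-level
#' structure that sample-profile correlations are computed over, and when
#' the group difference is a single shared program it flattens every
#' informative gene to the same pattern, leaving profile correlations
#' noise-driven. Standardization is the natural companion of Euclidean
#' distance, where it stops high-variance genes from dominating.
#'
#' @param expr expression matrix, genes x samples (at least 2 samples).
#' @param gene_subset optional gene IDs to cluster on (e.g. known EMT
#'   markers plus candidates); must intersect the matrix.
#' @param distance `"one_minus_pearson"` or `"euclidean"`.
#' @param linkage `"average"`, `"complete"` or `"ward"` (Ward.D2).
#' @param standardize z-score each gene across samples first (default
#'   FALSE); constant genes are dropped when standardizing.
#' @return an `hclust` tree (class `emt_hclust`/`hclust`) with attributes
#'   `distance`, `linkage` and `standardize`.
#' @export
hierarchical_cluster <- function(expr, gene_subset = NULL,
                                 distance = c("one_minus_pearson",
                                              "euclidean"),
                                 linkage = c("average", "complete", "ward"),
                                 standardize = FALSE) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  validate_expression_matrix(expr, "expression matrix")
  if (ncol(expr) < 2) stop("need at least 2 samples", call. = FALSE)
  if (!is.null(gene_subset)) {
    keep <- intersect(gene_subset, rownames(expr))
    if (!length(keep))
      stop("gene_subset does not intersect the expression matrix",
           call. = FALSE)
    expr <- expr[keep, , drop = FALSE]
  }
  if (standardize) {
    sds <- apply(expr, 1, sd)
    expr <- expr[sds > 0, , drop = FALSE]
    if (!nrow(expr))
      stop("no non-constant genes left after standardization", call. = FALSE)
    expr <- (expr - rowMeans(expr)) / apply(expr, 1, sd)
  }
  if (distance == "one_minus_pearson") {
    csd <- apply(expr, 2, sd)
    if (any(csd == 0))
      stop("constant sample profile with correlation distance: ",
           paste(colnames(expr)[csd == 0], collapse = ", "), call. = FALSE)
    d <- as.dist(1 - cor(expr))
  } else {
    d <- dist(t(expr))
  }
  method <- c(average = "average", complete = "complete",
              ward = "ward.D2")[[linkage]]
  tree <- hclust(d, method = method)
  attr(tree, "distance") <- distance
  attr(tree, "linkage") <- linkage
  attr(tree, "standardize") <- standardize
  class(tree) <- c("emt_hclust", "hclust")
  tree
}

#' Cut a sample tree and label the EMT-prone cluster
#'
#' Cuts the tree into `k` clusters and designates as EMT-prone the cluster
#' with the highest mean standardized expression of the marker gene set.
#' Ties go to the lowest cluster ID and are flagged.
#'
#' @param tree tree from [hierarchical_cluster()].
#' @param expr the expression matrix the tree was built from.
#' @param marker_set marker gene IDs (must intersect the matrix).
#' @param k number of clusters (2 <= k <= number of leaves; default 2).
#' @return object of class `cluster_labels`: `labels` (named cluster IDs),
#'   `emt_cluster`, `cluster_marker_means`, and `tie`.
#' @export
cut_and_label_emt <- function(tree, expr, marker_set, k = 2) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (k < 2 || k > n)
    stop("k must satisfy 2 <= k <= number of leaves", call. = FALSE)
  markers <- intersect(marker_set, rownames(expr))
  if (!length(markers))
    stop("marker_set does not intersect the expression matrix", call. = FALSE)
  cl <- cutree(tree, k = k)
  m <- expr[markers, names(cl), drop = FALSE]
  sds <- apply(m, 1, sd)
  m <- m[sds > 0, , drop = FALSE]
  if (!nrow(m))
    stop("all marker genes are constant across samples", call. = FALSE)
  mz <- (m - rowMeans(m)) / apply(m, 1, sd)
  marker_mean <- colMeans(mz)
  means <- vapply(split(marker_mean, cl), mean, numeric(1))
  top <- max(means)
  winners <- as.integer(names(means)[means == top])
  structure(list(labels = cl, emt_cluster = min(winners),
                 cluster_marker_means = means,
                 tie = length(winners) > 1),
            class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf("Cluster labels: %d samples in %d clusters; EMT-prone cluster = %d%s\n",
              length(x$labels), length(x$cluster_marker_means),
              x$emt_cluster, if (x$tie) " (tie)" else ""))
  cat("  mean standardized marker expression per cluster:\n")
  print(round(x$cluster_marker_means, 3))
  invisible(x)
}

#' Export a sample tree in Newick format
#'
#' Leaf names are sample IDs; branch lengths derive from merge heights.
#'
#' @param tree tree from [hierarchical_cluster()].
#' @return single Newick string.
#' @export
tree_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree))
}
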