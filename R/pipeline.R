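#' Run the full candidate-mediator pipeline from files
#'
#' File-in/file-out driver over [emt_screen()]: reads the bulk,
#' micro-dissection and survival TSVs named in the config, runs fold change
#' -> mesenchymal scores -> per-gene Cox z -> candidate selection (and
#' cell-line clustering when a panel is configured), writes every stage
#' output as TSV plus a JSON run report, and returns the report. All inputs
#' are validated before any computation starts; the run is deterministic
#' given the seed.
#'
#' @param config named list or path to a JSON file with elements:
#'   `bulk`, `epithelium`, `stroma`, `survival` (paths; `survival` optional),
#'   `panel` (optional path), `marker_genes` (optional character vector,
#'   required with `panel`), `out_dir`, `seed` (default 1), and optional
#'   stage parameters `log2_transform`, `pseudocount`, `aggregation`,
#'   `exclude_self`, `ms_min`, `log_ratio_max`, `z_min`, `k`, `distance`,
#'   `linkage`.
#' @return the run report (named list), invisibly also written to
#'   `out_dir/report.json`.
#' @export
run_emt_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  need <- c("bulk", "epithelium", "stroma", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("pipeline config is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  paths <- unlist(config[intersect(c("bulk", "epithelium", "stroma",
                                     "survival", "panel"), names(config))])
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop("pipeline input file(s) not found: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (!is.null(config$panel) && is.null(config$marker_genes))
    stop("pipeline config: 'marker_genes' is required with 'panel'",
         call. = FALSE)
  seed <- config$seed %||% 1L
  set.seed(seed)

  bulk <- read_expression_tsv(config$bulk)
  micro <- structure(list(epithelium = read_expression_tsv(config$epithelium),
                          stroma = read_expression_tsv(config$stroma),
                          pairing = NULL,
                          log2 = isTRUE(config$micro_log2)),
                     class = "microdissection_set")
  np <- min(ncol(micro$epithelium), ncol(micro$stroma))
  micro$pairing <- data.frame(epithelium = colnames(micro$epithelium)[seq_len(np)],
                              stroma = colnames(micro$stroma)[seq_len(np)],
                              stringsAsFactors = FALSE)
  surv <- if (!is.null(config$survival)) read_survival_tsv(config$survival)
  panel <- if (!is.null(config$panel)) read_expression_tsv(config$panel)

  thresholds <- selection_thresholds(
    ms_min = config$ms_min %||% 0.3,
    log_ratio_max = config$log_ratio_max %||% 0,
    z_min = config$z_min %||% 1.96)
  fit <- emt_screen(bulk, micro, survival = surv, panel = panel,
                    marker_genes = config$marker_genes,
                    log2_transform = config$log2_transform %||% TRUE,
                    pseudocount = config$pseudocount %||% 1,
                    aggregation = config$aggregation %||% "ratio_of_means",
                    exclude_self = config$exclude_self %||% TRUE,
                    thresholds = thresholds, k = config$k %||% 2,
                    distance = config$distance %||% "one_minus_pearson",
                    linkage = config$linkage %||% "average")

  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  version <- as.character(utils::packageVersion("emtscreen"))
  meta <- c(paste("emtscreen", version), paste("seed", seed))
  write_table_tsv(data.frame(gene_id = names(fit$L), value = fit$L),
                  file.path(out, "logfc.tsv"), meta)
  write_table_tsv(fit$scores, file.path(out, "scores.tsv"), meta)
  if (!is.null(fit$z))
    write_table_tsv(fit$z, file.path(out, "cox_z.tsv"), meta)
  if (!is.null(fit$candidates))
    write_table_tsv(fit$candidates$candidates,
                    file.path(out, "candidates.tsv"), meta)
  if (!is.null(fit$clustering)) {
    lb <- fit$clustering$labels
    write_table_tsv(data.frame(sample_id = names(lb$labels),
                               cluster = unname(lb$labels),
                               emt_prone = unname(lb$labels) == lb$emt_cluster),
                    file.path(out, "cluster_labels.tsv"), meta)
    writeLines(tree_newick(fit$clustering$tree),
               file.path(out, "tree.nwk"))
  }
  report <- list(
    version = version, seed = seed,
    parameters = fit$params[c("log2_transform", "pseudocount", "aggregation",
                              "exclude_self", "k", "distance", "linkage")],
    thresholds = unclass(thresholds),
    input_hashes = as.list(tools::md5sum(paths)),
    counts = list(
      n_genes = nrow(fit$scores),
      n_scored = sum(is.finite(fit$scores$mesenchymal_score)),
      n_candidates = if (!is.null(fit$candidates))
        fit$candidates$n_selected else NA),
    score_z_cor = fit$score_z_cor)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(report = report, fit = fit))
}
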