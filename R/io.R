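#' Validate a gene-by-sample expression matrix
#'
#' Expression matrices throughout the package are plain numeric matrices with
#' unique gene identifiers as row names and unique sample identifiers as
#' column names. Values may be linear-scale abundances or log2 intensities;
#' functions that care about the scale take an explicit flag.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @param what label used in error messages.
#' @return `x`, invisibly, after validation.
#' @keywords internal
validate_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have gene row names and sample column names", call. = FALSE)
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g))
    stop(what, ": duplicate gene IDs: ", paste(head(dup_g, 5), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(what, ": duplicate sample IDs", call. = FALSE)
  if (any(!is.finite(x)))
    stop(what, ": non-finite values present", call. = FALSE)
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a UTF-8 tab-separated file whose header row is `gene_id` followed
#' by sample identifiers; lines starting with `#` are metadata comments and
#' are skipped. Duplicate gene IDs and non-numeric cells are rejected with
#' coordinates.
#'
#' @param path file path.
#' @return numeric matrix with gene row names and sample column names.
#' @seealso [write_expression_tsv()]
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2 || names(df)[1] != "gene_id")
    stop("expression TSV must have header 'gene_id' followed by sample IDs: ",
         path, call. = FALSE)
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene_id rows in ", path, ": ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell in %s at row %d (gene %s), column '%s'",
                 path, bad[1, 1], ids[bad[1, 1]], colnames(vals)[bad[1, 2]]),
         call. = FALSE)
  dimnames(num) <- list(ids, colnames(vals))
  validate_expression_matrix(num, paste0("expression TSV ", path))
  num
}

#' Write an expression matrix to TSV
#'
#' @param x numeric matrix (genes x samples).
#' @param path output file path.
#' @param comments optional character vector written as leading `# ` lines
#'   (provenance: tool version, seed, parameters).
#' @export
write_expression_tsv <- function(x, path, comments = NULL) {
  validate_expression_matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table from TSV
#'
#' Requires columns `sample_id`, `time`, `event`; any further columns are kept
#' as covariates. `time` must be nonnegative and `event` coded 0/1, with no
#' missing values in either.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
read_survival_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  validate_survival_table(df, paste0("survival TSV ", path))
  df
}

#' @keywords internal
validate_survival_table <- function(df, what = "survival table") {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(df$time) || anyNA(df$event))
    stop(what, ": missing time/event values", call. = FALSE)
  if (!is.numeric(df$time) || any(df$time < 0))
    stop(what, ": time must be nonnegative numeric", call. = FALSE)
  if (!all(df$event %in% c(0, 1)))
    stop(what, ": event must be coded 0/1", call. = FALSE)
  invisible(df)
}

#' Write a survival (or clinical) table to TSV
#'
#' @param df data.frame.
#' @param path output file path.
#' @param comments optional `# ` provenance lines.
#' @export
write_table_tsv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
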