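# round-half-up at d decimals (base round() is round-half-even)
round_half_up <- function(x, d = 0) {
  s <- sign(x)
  s * floor(abs(x) * 10^d + 0.5) / 10^d
}

#' Chi-square test of independence on a contingency table
#'
#' Two forms of the chi-square test for an r x c table of counts: the
#' likelihood-ratio form (G-test, `G = 2 * sum(O * ln(O / E))`, with the
#' convention `0 * ln(0 / E) = 0`) and the Pearson form
#' (`sum((O - E)^2 / E)`). No continuity correction in either form. The
#' likelihood-ratio form is the default: it is the form whose p-values
#' reproduce standard clinical-table software output for small cohorts,
#' including tables with empty cells.
#'
#' @param table matrix of nonnegative counts, at least 2 x 2, with positive
#'   row and column margins.
#' @param method `"likelihood_ratio"` (default) or `"pearson"`.
#' @return list with `statistic`, `df`, `p.value`, `method` and `expected`.
#' @examples
#' # lymph-node metastasis vs marker status
#' chi2_independence(matrix(c(52, 15, 19, 14), 2, byrow = TRUE))
#' @export
chi2_independence <- function(table,
                              method = c("likelihood_ratio", "pearson")) {
  method <- match.arg(method)
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  if (any(m < 0) || any(!is.finite(m)))
    stop("counts must be nonnegative and finite", call. = FALSE)
  if (sum(m) <= 0) stop("table total must be positive", call. = FALSE)
  rs <- rowSums(m)
  cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate input: zero row or column margin", call. = FALSE)
  E <- outer(rs, cs) / sum(m)
  stat <- if (method == "likelihood_ratio") {
    2 * sum(ifelse(m > 0, m * log(m / E), 0))
  } else {
    sum((m - E)^2 / E)
  }
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE),
       method = method, expected = E)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with the U statistic on
#' midranks. The p-value is exact when `n_a * n_b <= 400` and there are no
#' ties, and uses the tie-corrected normal approximation (with continuity
#' correction) otherwise.
#'
#' @param a,b numeric samples (non-empty).
#' @return list with `U` (for sample `a`), `p.value` and `method`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  exact <- length(a) * length(b) <= 400 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(U = unname(wt$statistic), p.value = wt$p.value,
       method = if (exact) "exact" else "normal_approximation")
}

#' Build a clinical characteristics table (table one)
#'
#' Summarizes patient characteristics by binary marker status the way
#' clinical papers print them: for each categorical variable, counts with
#' row percentages (each category row sums to 100% across marker states) and
#' a chi-square p-value; for each continuous variable, mean +/- SD per group
#' and a Mann-Whitney p-value. Percentages are rounded half-up to one
#' decimal and p-values to three decimals, matching the usual table format.
#'
#' @param clinical data.frame, one row per patient.
#' @param marker name of the binary marker column (0/1 or two levels; 0 /
#'   first level is reported as "negative").
#' @param variables named character vector mapping variable column names to
#'   `"categorical"` or `"continuous"`.
#' @param method chi-square form for categorical tests (default
#'   `"likelihood_ratio"`).
#' @return a `table_one` data.frame with columns `variable`, `level`,
#'   `negative`, `pct_negative`, `positive`, `pct_positive`, `p_value`,
#'   `test`.
#' @export
build_table_one <- function(clinical, marker, variables,
                            method = c("likelihood_ratio", "pearson")) {
  method <- match.arg(method)
  if (!marker %in% names(clinical))
    stop("marker column not found: ", marker, call. = FALSE)
  mk <- clinical[[marker]]
  lev <- sort(unique(mk))
  if (length(lev) != 2)
    stop("marker must be binary (two observed levels)", call. = FALSE)
  neg <- mk == lev[1]
  rows <- list()
  for (v in names(variables)) {
    type <- variables[[v]]
    x <- clinical[[v]]
    if (is.null(x)) stop("variable column not found: ", v, call. = FALSE)
    if (type == "categorical") {
      tab <- table(factor(x), factor(mk, levels = lev))
      p <- tryCatch(
        round_half_up(chi2_independence(unclass(tab), method)$p.value, 3),
        error = function(e) NA_real_)
      for (i in seq_len(nrow(tab))) {
        tot <- sum(tab[i, ])
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = rownames(tab)[i],
          negative = as.integer(tab[i, 1]),
          pct_negative = round_half_up(100 * tab[i, 1] / tot, 1),
          positive = as.integer(tab[i, 2]),
          pct_positive = round_half_up(100 * tab[i, 2] / tot, 1),
          p_value = if (i == 1) p else NA_real_,
          test = if (i == 1) paste0("chi2_", method) else "",
          stringsAsFactors = FALSE)
      }
    } else if (type == "continuous") {
      p <- round_half_up(mann_whitney(x[neg], x[!neg])$p.value, 3)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v,
        level = sprintf("mean %.1f +/- %.1f | %.1f +/- %.1f",
                        mean(x[neg]), sd(x[neg]),
                        mean(x[!neg]), sd(x[!neg])),
        negative = sum(neg), pct_negative = NA_real_,
        positive = sum(!neg), pct_positive = NA_real_,
        p_value = p, test = "mann_whitney", stringsAsFactors = FALSE)
    } else {
      stop("variable type must be 'categorical' or 'continuous': ", v,
           call. = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("table_one", "data.frame"),
            marker = marker, n = nrow(clinical))
}

#' @export
print.table_one <- function(x, ...) {
  cat(sprintf("Patient characteristics by %s status (n = %d)\n",
              attr(x, "marker"), attr(x, "n")))
  print.data.frame(x, row.names = FALSE, na.print = "")
  invisible(x)
}

#' Cohort inclusion arithmetic with audit trail
#'
#' Subtracts itemized exclusions from an initial cohort size and returns the
#' included count together with the per-reason audit trail.
#'
#' @param total initial cohort size.
#' @param exclusions nonnegative counts, optionally named by exclusion
#'   reason.
#' @return list with `included`, `total` and `audit` (a data.frame of
#'   reasons and counts).
#' @export
inclusion_filter <- function(total, exclusions = numeric(0)) {
  if (length(exclusions) && any(exclusions < 0))
    stop("exclusion counts must be nonnegative", call. = FALSE)
  included <- total - sum(exclusions)
  if (included < 0)
    stop("exclusions exceed the cohort size", call. = FALSE)
  reasons <- names(exclusions)
  if (is.null(reasons))
    reasons <- if (length(exclusions))
      paste0("exclusion_", seq_along(exclusions)) else character(0)
  list(included = included, total = total,
       audit = data.frame(reason = reasons, n = as.numeric(exclusions),
                          stringsAsFactors = FALSE))
}
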