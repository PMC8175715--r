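#' Cox proportional-hazards fit
#'
#' Univariable or multivariable Cox regression by partial-likelihood
#' maximization with the Efron tie correction, reporting per covariate the
#' log hazard ratio, its standard error, the Wald z (`beta / se`; positive z
#' means adverse prognostic association), the hazard ratio and its Wald 95%
#' confidence interval `exp(beta +/- 1.96 se)`, and the two-sided Wald p.
#'
#' @param data data.frame with columns `time` (nonnegative), `event` (0/1)
#'   and the covariates.
#' @param covariates character vector of covariate column names.
#' @param ties tie-handling for the partial likelihood: `"efron"` (default;
#'   more accurate with heavily tied integer-like times) or `"breslow"`
#'   (under which, unlike Efron, duplicating every subject leaves the
#'   estimate exactly unchanged).
#' @return object of class `cox_fit`: a coefficient data.frame plus
#'   `loglik`, `n`, `n_events` and the `ties` method tag.
#' @examples
#' d <- data.frame(time = c(6, 7, 10, 15, 19, 25),
#'                 event = c(1, 0, 1, 1, 0, 1),
#'                 x = c(1.2, 0.5, 1.7, 0.1, 0.3, 0.9))
#' cox_fit(d, "x")
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  validate_survival_table(
    cbind(data.frame(sample_id = seq_len(nrow(data))), data))
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop("covariate(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (sum(data$event) < 1)
    stop("need at least one event", call. = FALSE)
  for (v in covariates) {
    if (anyNA(data[[v]]))
      stop("missing values in covariate ", v, call. = FALSE)
    if (is.numeric(data[[v]]) && sd(data[[v]]) == 0)
      stop("degenerate input: covariate ", v, " is constant", call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (!is.null(warn) && grepl("infinite|converge", warn)) {
    stop("Cox fit did not converge (monotone likelihood / separation?): ",
         warn, call. = FALSE)
  }
  if (any(!is.finite(beta)) || any(!is.finite(se)))
    stop("Cox fit did not converge: non-finite coefficient or SE",
         call. = FALSE)
  z <- beta / se
  tab <- data.frame(covariate = names(beta), beta = unname(beta),
                    se = unname(se), z = unname(z),
                    hr = exp(unname(beta)),
                    ci_lower = exp(unname(beta) - 1.96 * unname(se)),
                    ci_upper = exp(unname(beta) + 1.96 * unname(se)),
                    p = 2 * pnorm(-abs(unname(z))),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coefficients = tab,
                 loglik = fit$loglik[length(fit$loglik)],
                 n = fit$n, n_events = fit$nevent, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  setNames(object$coefficients$beta, object$coefficients$covariate)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, overall or per group,
#' with the usual convention that censorings tied with an event time occur
#' after the events at that time.
#'
#' @param data data.frame with `time` and `event` columns.
#' @param group optional vector of group labels (one per row).
#' @return object of class `km_curve`: per group a data.frame with `time`,
#'   `n_risk`, `n_event`, `n_censor` and `surv` (right-continuous steps;
#'   S(0) = 1 implicitly).
#' @export
km_curve <- function(data, group = NULL) {
  validate_survival_table(
    cbind(data.frame(sample_id = seq_len(nrow(data))), data))
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
    curves <- list(overall = data.frame(
      time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
      n_censor = fit$n.censor, surv = fit$surv))
  } else {
    stopifnot(length(group) == nrow(data))
    d <- data
    d$.group <- as.factor(group)
    fit <- survival::survfit(survival::Surv(time, event) ~ .group, data = d)
    strata <- rep(sub("^\\.group=", "", names(fit$strata)), fit$strata)
    curves <- lapply(split(seq_along(fit$time), strata), function(i) {
      data.frame(time = fit$time[i], n_risk = fit$n.risk[i],
                 n_event = fit$n.event[i], n_censor = fit$n.censor[i],
                 surv = fit$surv[i])
    })
  }
  structure(curves, class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve(s):\n")
  for (g in names(x)) {
    cu <- x[[g]]
    cat(sprintf("  %s: %d time points, %d events, final S = %.3f\n",
                g, nrow(cu), sum(cu$n_event), tail2(cu$surv)))
  }
  invisible(x)
}

tail2 <- function(v) if (length(v)) v[length(v)] else 1

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank statistic comparing survival
#' across two or more groups; p from the chi-square distribution with
#' (groups - 1) degrees of freedom.
#'
#' @inheritParams km_curve
#' @param group vector of group labels, at least two distinct.
#' @return list with `statistic`, `df` and `p.value`.
#' @export
logrank_test <- function(data, group) {
  validate_survival_table(
    cbind(data.frame(sample_id = seq_len(nrow(data))), data))
  g <- as.factor(group)
  if (nlevels(droplevels(g)) < 2)
    stop("log-rank test needs at least 2 groups", call. = FALSE)
  if (sum(data$event) < 1)
    stop("need at least one event", call. = FALSE)
  d <- data
  d$.group <- droplevels(g)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ .group, data = d)
  df <- nlevels(d$.group) - 1
  list(statistic = as.numeric(sd_$chisq), df = df,
       p.value = pchisq(as.numeric(sd_$chisq), df, lower.tail = FALSE))
}

#' Split a continuous variable into two groups
#'
#' Dichotomization helper for survival comparisons. The split rule is an
#' explicit required argument - clinical practice uses both mean and median
#' splits, and the two are not interchangeable.
#'
#' @param x numeric vector.
#' @param split `"mean"` or `"median"` (no default).
#' @return factor with levels `low` (x <= threshold) and `high`
#'   (x > threshold); the threshold is stored as attribute `threshold`.
#' @export
dichotomize <- function(x, split) {
  if (missing(split))
    stop("'split' must be given explicitly (\"mean\" or \"median\")",
         call. = FALSE)
  split <- match.arg(split, c("mean", "median"))
  thr <- if (split == "mean") mean(x) else median(x)
  structure(factor(ifelse(x > thr, "high", "low"), levels = c("low", "high")),
            threshold = thr, split = split)
}
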