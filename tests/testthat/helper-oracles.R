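# Fixtures and independent brute-force oracles used across the suite.
# Oracles are written naively (loops, enumeration, closed forms) and never
# share code with the package implementation they check.

# FIXTURE-A: 5 genes x 6 samples, integers
fixture_a <- function() {
  m <- matrix(c(3, 7, 5, 9, 4, 8,
                1, 2, 6, 4, 5, 3,
                10, 6, 7, 3, 9, 2,
                2, 8, 3, 7, 6, 5,
                4, 4, 9, 1, 8, 6),
              nrow = 5, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  storage.mode(m) <- "double"
  m
}

fixture_a_L <- function() {
  c(g1 = 0.5, g2 = -1.2, g3 = 2.0, g4 = -0.3, g5 = 0.8)
}

# 4 genes x 3 pairs, linear-scale integers
fixture_micro <- function() {
  epi <- matrix(c(2, 4, 6,
                  1, 3, 5,
                  8, 2, 5,
                  3, 3, 3),
                nrow = 4, byrow = TRUE,
                dimnames = list(paste0("m", 1:4), paste0("e", 1:3)))
  str <- matrix(c(4, 8, 12,
                  2, 1, 7,
                  1, 9, 2,
                  6, 6, 6),
                nrow = 4, byrow = TRUE,
                dimnames = list(paste0("m", 1:4), paste0("t", 1:3)))
  storage.mode(epi) <- storage.mode(str) <- "double"
  list(epithelium = epi, stroma = str,
       pairing = data.frame(epithelium = paste0("e", 1:3),
                            stroma = paste0("t", 1:3),
                            stringsAsFactors = FALSE),
       log2 = FALSE)
}

# plain-formula Pearson correlation
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# double-loop mesenchymal score: per-pair correlation profile, then
# correlation with L over the gene universe
naive_mesenchymal_score <- function(bulk, L, target, exclude_self = TRUE) {
  universe <- intersect(rownames(bulk), names(L)[is.finite(L)])
  universe <- universe[apply(bulk[universe, , drop = FALSE], 1,
                             function(v) length(unique(v)) > 1)]
  r <- vapply(universe,
              function(g) naive_pearson(bulk[target, ], bulk[g, ]),
              numeric(1))
  use <- if (exclude_self) setdiff(universe, target) else universe
  naive_pearson(r[use], L[use])
}

# O(n^3) agglomerative clustering over an explicit distance matrix;
# cluster-cluster distance is the mean (average linkage) or max (complete)
# over all original cross-pairs; returns the n-1 merge heights, sorted
naive_linkage_heights <- function(D, method = c("average", "complete")) {
  method <- match.arg(method)
  f <- if (method == "average") mean else max
  members <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(members) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(members) - 1)) {
      for (j in (i + 1):length(members)) {
        d <- f(D[members[[i]], members[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    heights <- c(heights, best[1])
    members[[best[2]]] <- c(members[[best[2]]], members[[best[3]]])
    members[[best[3]]] <- NULL
  }
  sort(heights)
}

# Cox partial log-likelihood for distinct event times (no ties)
cox_partial_loglik <- function(beta, time, event, x) {
  s <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  s
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_exact_p <- function(a, b) {
  na <- length(a)
  vals <- c(a, b)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(length(vals), na)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# two-group log-rank statistic from a hand-maintained risk table
logrank_oracle <- function(time, event, g) {
  o <- e <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    n <- sum(at)
    n1 <- sum(at & g == 1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# small config for fast synthetic runs
quick_config <- function(...) {
  args <- list(n_genes = 200, n_bulk_samples = 60, n_stromal_archetype = 30,
               n_planted_mediators = 12, n_celllines = 16)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
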