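#' Pearson correlation significance via the t-statistic
#'
#' Computes the Pearson coefficient on untransformed values, the t-statistic
#' `t* = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom, and
#' the two-sided p-value, plus a Spearman rank-correlation pair for
#' confirmation.
#'
#' @param x,y Aligned numeric vectors, `n >= 3`.
#' @return One-row tibble: `r`, `t_star`, `df`, `p`, `spearman_rho`,
#'   `spearman_p`, `undefined` (true when either vector has zero variance).
#' @export
correlation_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y are not aligned", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble(r = NA_real_, t_star = NA_real_, df = n - 2L, p = NA_real_,
                  spearman_rho = NA_real_, spearman_p = NA_real_,
                  undefined = TRUE))
  }
  r <- stats::cor(x, y)
  if (1 - r^2 <= 4 * .Machine$double.eps) {
    t_star <- sign(r) * Inf
    p <- 0
  } else {
    t_star <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t_star), df = n - 2)
  }
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble(r = r, t_star = t_star, df = n - 2L, p = p,
         spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
         undefined = FALSE)
}

#' One-way subtype ANOVA with homoscedasticity checks
#'
#' Runs a one-way ANOVA on log-transformed values across the labelled groups,
#' together with the Brown-Forsythe test (ANOVA on absolute deviations from
#' the group medians), the max/min group-variance ratio (the Dean-Voss
#' criterion; ratios below `var_ratio_max` support variance homogeneity), and
#' a Kruskal-Wallis confirmation on the same groups.
#'
#' @param values Per-sample positive values (log2-transformed internally;
#'   zeros become missing and are dropped).
#' @param labels Per-sample group labels; every group needs >= 2 samples.
#' @param var_ratio_max Dean-Voss threshold recorded alongside the ratio
#'   (default 3).
#' @return One-row tibble: `anova_p`, `brown_forsythe_p`, `variance_ratio`,
#'   `variance_ratio_ok`, `kruskal_p`.
#' @export
subtype_anova <- function(values, labels, var_ratio_max = 3) {
  stopifnot(length(values) == length(labels))
  keep <- !is.na(values) & values > 0 & !is.na(labels)
  v <- log2(values[keep])
  g <- factor(labels[keep])
  tab <- table(g)
  if (length(tab) < 2 || any(tab < 2))
    stop("every group needs at least 2 samples", call. = FALSE)
  anova_p <- stats::oneway.test(v ~ g, var.equal = TRUE)$p.value
  med <- tapply(v, g, stats::median)
  z <- abs(v - med[g])
  bf_p <- stats::oneway.test(z ~ g, var.equal = TRUE)$p.value
  vars <- tapply(v, g, stats::var)
  ratio <- max(vars) / min(vars)
  kw_p <- stats::kruskal.test(v, g)$p.value
  tibble(anova_p = anova_p, brown_forsythe_p = bf_p,
         variance_ratio = unname(ratio),
         variance_ratio_ok = unname(ratio) <= var_ratio_max,
         kruskal_p = kw_p)
}

#' Two-tailed exact binomial enrichment per group
#'
#' For each group tests the count of "above" samples against the expected
#' frequency with the exact two-tailed binomial test (minimum-likelihood
#' two-sided convention, as in [stats::binom.test()]), then adds a
#' Benjamini-Hochberg FDR across the groups. Groups with zero total are
#' skipped with a warning.
#'
#' @param above Integer vector of per-group success counts.
#' @param totals Integer vector of per-group totals (same length).
#' @param expected Expected success probability in `(0, 1)` (default 0.5).
#' @param group Optional group labels.
#' @return A tibble: `group`, `above`, `total`, `p`, `fdr`.
#' @export
binomial_enrichment <- function(above, totals, expected = 0.5, group = NULL) {
  stopifnot(length(above) == length(totals))
  if (expected <= 0 || expected >= 1)
    stop("expected must lie in (0, 1)", call. = FALSE)
  if (any(above > totals)) stop("above exceeds total", call. = FALSE)
  if (is.null(group)) group <- as.character(seq_along(above))
  zero <- totals == 0
  if (any(zero))
    warning(sum(zero), " group(s) with zero total skipped", call. = FALSE)
  p <- rep(NA_real_, length(above))
  p[!zero] <- vapply(which(!zero), function(i)
    stats::binom.test(above[i], totals[i], p = expected)$p.value, 0)
  fdr <- rep(NA_real_, length(above))
  if (any(!zero)) fdr[!zero] <- bh_fdr(p[!zero])
  tibble(group = group, above = above, total = totals, p = p, fdr = fdr)
}
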