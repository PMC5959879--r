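# Rank-based threshold helpers. "Strictly in the top f" is rank-above-cut
# with average ranks for ties, so a tie straddling the cut fails; "strictly
# in the lowest f" mirrors it from below.
in_top_frac <- function(x, frac) {
  n <- length(x)
  rank(x, ties.method = "average") > n * (1 - frac)
}

in_bottom_frac <- function(x, frac) {
  n <- length(x)
  rank(x, ties.method = "average") <= n * frac
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment, capped at 1 with monotonicity enforced.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 with the smoother method (natural cubic
#' spline of `pi0(lambda) = mean(p > lambda) / (1 - lambda)` over
#' `lambda = 0.05, 0.10, ..., 0.95`, evaluated at the largest lambda) and
#' converts p-values to q-values by the step-down minimum rule. With few
#' p-values (or a degenerate spline fit) pi0 falls back to 1, making the
#' q-values equal the Benjamini-Hochberg adjustment.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param lambda Grid for the pi0 smoother.
#' @return Q-values in the input order; monotone in p, inside `[0, 1]`.
#' @export
storey_q <- function(pvals, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(pvals) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p <- pvals[!is.na(pvals)]
  m <- length(p)
  pi0 <- 1
  if (m >= 100 && length(unique(p)) > 4) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    pi0 <- tryCatch({
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      stats::predict(fit, x = max(lambda))$y
    }, error = function(e) 1)
    pi0 <- min(max(pi0, 0), 1)
    if (pi0 <= 0) pi0 <- min(pi0_l[pi0_l > 0], 1)
  }
  o <- order(p, decreasing = TRUE)
  q <- rep(NA_real_, m)
  q[o] <- pmin(1, cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o]))
  out <- rep(NA_real_, length(pvals))
  out[!is.na(pvals)] <- q
  out
}

wilcoxon_p <- function(a, b) {
  # "calculable" fails only in the fully degenerate identical-constant case
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  if (length(unique(c(a, b))) == 1) return(NA_real_)
  exact <- length(a) <= 20 && length(b) <= 20
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

#' Multi-criterion differential gene selection between two sample groups
#'
#' The hybrid selection cascade keeps a gene when all five criteria hold:
#' \describe{
#'   \item{a}{the relative variation of its two group medians,
#'     `(max - min) / (min + eps)` with `eps` the machine double epsilon,
#'     is strictly in the top 50% across all genes;}
#'   \item{b}{its two-sided Wilcoxon rank-sum p-value between the groups is
#'     calculable and `< p_cut`, and its presence count (samples with value
#'     `>= presence_value` across all samples) exceeds `presence_frac` of the
#'     sample total;}
#'   \item{c}{its Storey q-value, computed among the criterion-(b) calculable
#'     and presence-passing p-values, is `< q_cut`;}
#'   \item{d}{its overall median is strictly greater than the first octile
#'     (nearest-rank lower 12.5th percentile) of the ranked gene medians;}
#'   \item{e}{its standard deviation is strictly in the top `sd_top_frac`
#'     (default 1/2) across all genes.}
#' }
#'
#' @param x An expression tibble.
#' @param group1,group2 Disjoint, non-empty character vectors of sample ids.
#' @param p_cut,q_cut Wilcoxon p and Storey q thresholds (defaults 0.01).
#' @param presence_value Signal threshold defining presence (default 0.5).
#' @param presence_frac Required presence fraction of all samples (default 0.6,
#'   strict: the count must exceed `presence_frac * n`).
#' @param sd_top_frac Fraction for criterion (e); [go_variant_select()] uses
#'   1/3.
#' @return A `gene_filter_report` tibble: per gene the criterion statistics
#'   (`relative_median_variation`, `wilcoxon_p`, `presence_count`, `storey_q`,
#'   `median_value`, `sd_value`), the pass flags `crit_a`..`crit_e` and
#'   `selected`.
#' @export
hybrid_select <- function(x, group1, group2, p_cut = 0.01, q_cut = 0.01,
                          presence_value = 0.5, presence_frac = 0.6,
                          sd_top_frac = 0.5) {
  smp <- expr_samples(x)
  if (length(group1) == 0 || length(group2) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  if (length(intersect(group1, group2)) > 0)
    stop("groups must be disjoint", call. = FALSE)
  bad <- setdiff(c(group1, group2), smp)
  if (length(bad) > 0)
    stop("unknown sample(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  m <- expr_mat(x)
  if (nrow(m) < 8)
    stop("need at least 8 genes (first octile undefined)", call. = FALSE)
  n <- ncol(m)
  m1 <- m[, group1, drop = FALSE]
  m2 <- m[, group2, drop = FALSE]

  med1 <- apply(m1, 1, stats::median, na.rm = TRUE)
  med2 <- apply(m2, 1, stats::median, na.rm = TRUE)
  lo <- pmin(med1, med2)
  hi <- pmax(med1, med2)
  relvar <- (hi - lo) / (lo + .Machine$double.eps)
  crit_a <- in_top_frac(relvar, 0.5)

  wp <- vapply(seq_len(nrow(m)), function(i)
    wilcoxon_p(m1[i, ][!is.na(m1[i, ])], m2[i, ][!is.na(m2[i, ])]), 0)
  presence <- rowSums(m >= presence_value, na.rm = TRUE)
  relevant <- presence > presence_frac * n
  crit_b <- !is.na(wp) & wp < p_cut & relevant

  qv <- rep(NA_real_, nrow(m))
  eligible <- !is.na(wp) & relevant
  if (any(eligible)) qv[eligible] <- storey_q(wp[eligible])
  crit_c <- crit_b & !is.na(qv) & qv < q_cut

  med_all <- apply(m, 1, stats::median, na.rm = TRUE)
  octile <- sort(med_all)[max(1L, floor(nrow(m) / 8))]
  crit_d <- med_all > octile

  sd_all <- apply(m, 1, stats::sd, na.rm = TRUE)
  crit_e <- in_top_frac(sd_all, sd_top_frac)

  out <- tibble(
    symbol = x$symbol, entrez = x$entrez,
    relative_median_variation = unname(relvar),
    wilcoxon_p = wp,
    presence_count = unname(presence),
    storey_q = qv,
    median_value = unname(med_all),
    sd_value = unname(sd_all),
    crit_a = unname(crit_a), crit_b = unname(crit_b), crit_c = unname(crit_c),
    crit_d = unname(crit_d), crit_e = unname(crit_e))
  out$selected <- out$crit_a & out$crit_b & out$crit_c & out$crit_d &
    out$crit_e
  class(out) <- c("gene_filter_report", class(out))
  out
}

#' @rdname hybrid_select
#' @details [go_variant_select()] is the stricter variant used upstream of
#'   gene-ontology analysis: criterion (e) becomes e' — the standard deviation
#'   must be strictly in the top 1/3 over the full gene universe — so its
#'   selection is always a subset of the hybrid selection.
#' @export
go_variant_select <- function(x, group1, group2, p_cut = 0.01, q_cut = 0.01,
                              presence_value = 0.5, presence_frac = 0.6) {
  hybrid_select(x, group1, group2, p_cut = p_cut, q_cut = q_cut,
                presence_value = presence_value,
                presence_frac = presence_frac, sd_top_frac = 1 / 3)
}

#' @export
print.gene_filter_report <- function(x, ...) {
  cat("Gene selection cascade:", sum(x$selected), "of", nrow(x),
      "genes selected\n")
  NextMethod()
}

#' Trim sparse/flat genes before gene-set export
#'
#' Removes every gene whose mean, standard deviation, or presence count
#' (samples with value `>= presence_value`) is strictly in the lowest 1/8 of
#' the dataset; ranks are computed on the full input, and ties straddling the
#' 1/8 cut are retained (strictness).
#'
#' @param x An expression tibble.
#' @param presence_value Signal threshold (default 0.5).
#' @return The trimmed expression tibble.
#' @export
trim_for_gene_set_export <- function(x, presence_value = 0.5) {
  m <- expr_mat(x)
  means <- rowMeans(m, na.rm = TRUE)
  sds <- apply(m, 1, stats::sd, na.rm = TRUE)
  presence <- rowSums(m >= presence_value, na.rm = TRUE)
  drop <- in_bottom_frac(means, 1 / 8) | in_bottom_frac(sds, 1 / 8) |
    in_bottom_frac(presence, 1 / 8)
  x[!drop, ]
}

#' Filter an external enrichment tool's term table
#'
#' Keeps terms that (1) belong to an accepted ontology branch (by default
#' biological process), (2) have at least `min_members` member genes, and
#' (3) have `p < p_cut`. Terms with an unknown ontology tag are skipped with
#' a warning.
#'
#' @param terms Tibble with columns `ontology`, `term`, `p`, and `n_members`
#'   (or a `members` list-column whose lengths are used instead).
#' @param min_members Minimum member-gene count (default 2).
#' @param p_cut P-value threshold (default 0.001).
#' @param ontologies Accepted ontology tags (default `"BP"`).
#' @return The filtered tibble.
#' @export
filter_enrichment_terms <- function(terms, min_members = 2, p_cut = 0.001,
                                    ontologies = "BP") {
  if (!"n_members" %in% names(terms)) {
    if (!"members" %in% names(terms))
      stop("terms needs an n_members or members column", call. = FALSE)
    terms$n_members <- lengths(terms$members)
  }
  known <- c("BP", "MF", "CC")
  odd <- !terms$ontology %in% known
  if (any(odd)) {
    warning("skipping ", sum(odd), " term(s) with unknown ontology tag(s): ",
            paste(unique(terms$ontology[odd]), collapse = ", "),
            call. = FALSE)
    terms <- terms[!odd, ]
  }
  terms[terms$ontology %in% ontologies & terms$n_members >= min_members &
          terms$p < p_cut, ]
}
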