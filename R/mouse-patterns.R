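#' Collapse duplicated probe rows to one row per gene symbol
#'
#' Rows without a gene symbol are dropped. For a symbol with several rows,
#' fully identical rows are deduplicated to one; otherwise the row with the
#' highest standard deviation across samples is kept.
#'
#' @param x An expression tibble (probe-level; `symbol` may repeat or be
#'   `NA`).
#' @return The collapsed expression tibble, one row per symbol.
#' @export
collapse_probes <- function(x) {
  x <- x[!is.na(x$symbol), ]
  m <- expr_mat(x)
  sds <- apply(m, 1, stats::sd, na.rm = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(x)), x$symbol), function(idx) {
    if (length(idx) == 1) return(idx)
    idx[which.max(sds[idx])]
  }), use.names = FALSE)
  x[sort(keep), ]
}

#' Implied p-value of complete separation between two replicate groups
#'
#' Under exchangeable random ordering of `n1 + n2` values, the probability
#' that all values of the designated group strictly exceed all values of the
#' other in a given direction is `1 / choose(n1 + n2, n2)`.
#'
#' @param n1,n2 Replicate counts (>= 1).
#' @return The probability.
#' @export
separation_p <- function(n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  1 / choose(n1 + n2, n2)
}

#' Differential-expression flags between two replicate groups
#'
#' Three criteria define differential expression for replicate microarray
#' data: (a) complete separation — every replicate of one group strictly
#' above every replicate of the other, in either direction; (b) the relative
#' difference of the group means, `|mean(a) - mean(b)| / min(mean(a),
#' mean(b))`, is at least `mean_diff_min` (default 0.5); (c) the gene's
#' range is within the top fraction of ranges genome-wide — a matrix-level
#' criterion supplied here as the precomputed `range_pass` flag (see
#' [select_pattern_genes()]).
#'
#' @param a,b Finite replicate value vectors.
#' @param mean_diff_min Relative mean-difference threshold (default 0.5).
#' @param range_pass Logical criterion-(c) flag (default `TRUE` when no
#'   genome-wide context is available).
#' @return One-row tibble: `flag_a`, `flag_b`, `flag_c`, `differential`,
#'   `indeterminate` (true when a nonpositive mean degenerates the (b)
#'   denominator).
#' @export
differential_flags <- function(a, b, mean_diff_min = 0.5, range_pass = TRUE) {
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  flag_a <- max(a) < min(b) || max(b) < min(a)
  lo <- min(mean(a), mean(b))
  indeterminate <- lo <= 0
  flag_b <- if (indeterminate) NA else
    abs(mean(a) - mean(b)) / lo >= mean_diff_min
  differential <- flag_a && isTRUE(flag_b) && range_pass
  tibble(flag_a = flag_a, flag_b = flag_b, flag_c = range_pass,
         differential = differential, indeterminate = indeterminate)
}

#' Classify the expression gradient pattern of one gene
#'
#' Evaluates the four sub-pattern definitions over the three ordered
#' conditions normal (MBEC) -> primary (KLN205) -> metastatic (LN4K1):
#' \describe{
#'   \item{A-1}{every LN4K1 value strictly above every KLN205 value, every
#'     KLN205 value strictly above every MBEC value, and mean(LN4K1) strictly
#'     above mean(KLN205);}
#'   \item{A-2}{every LN4K1 value strictly above, and every KLN205 and MBEC
#'     value strictly below, the grand mean over all replicates;}
#'   \item{B-1, B-2}{the mirrored descending definitions.}
#' }
#' A-1/A-2 (and B-1/B-2) may co-occur; an A-family and a B-family flag never
#' can.
#'
#' @param mbec,kln,ln4k1 Replicate value vectors for the three conditions.
#' @return One-row tibble: `A1`, `A2`, `B1`, `B2`, `pattern_A`, `pattern_B`.
#' @export
classify_pattern <- function(mbec, kln, ln4k1) {
  gm <- mean(c(mbec, kln, ln4k1))
  a1 <- min(ln4k1) > max(kln) && min(kln) > max(mbec) &&
    mean(ln4k1) > mean(kln)
  a2 <- all(ln4k1 > gm) && all(kln < gm) && all(mbec < gm)
  b1 <- max(ln4k1) < min(kln) && max(kln) < min(mbec) &&
    mean(ln4k1) < mean(kln)
  b2 <- all(ln4k1 < gm) && all(kln > gm) && all(mbec > gm)
  tibble(A1 = a1, A2 = a2, B1 = b1, B2 = b2,
         pattern_A = a1 || a2, pattern_B = b1 || b2)
}

#' Select monotone-gradient genes from a three-condition replicate matrix
#'
#' A gene is selected when it is differentially expressed — between MBEC and
#' KLN205, between MBEC and LN4K1, or both, each comparison requiring the
#' three [differential_flags()] criteria — and follows gradient pattern A or
#' B per [classify_pattern()]. Criterion (c) (range strictly within the top
#' `range_top_frac` of all genes' ranges) is computed genome-wide on this
#' matrix.
#'
#' @param x An expression tibble whose samples are the replicate columns.
#' @param design Named list/vector of replicate counts in condition order
#'   `c(mbec = 4, kln205 = 3, ln4k1 = 3)`; columns are taken in that order.
#' @param mean_diff_min Criterion-(b) threshold (default 0.5).
#' @param range_top_frac Criterion-(c) fraction (default 0.75).
#' @return A `pattern_selection` tibble: per gene the two comparisons'
#'   differential flags, the four sub-pattern flags, and `selected`.
#' @export
select_pattern_genes <- function(x, design = c(mbec = 4, kln205 = 3,
                                               ln4k1 = 3),
                                 mean_diff_min = 0.5, range_top_frac = 0.75) {
  m <- expr_mat(x)
  if (ncol(m) != sum(design))
    stop("matrix has ", ncol(m), " columns; design expects ", sum(design),
         call. = FALSE)
  if (any(design < 2)) stop("each condition needs >= 2 replicates",
                            call. = FALSE)
  idx_mbec <- seq_len(design[[1]])
  idx_kln <- seq_len(design[[2]]) + design[[1]]
  idx_ln <- seq_len(design[[3]]) + design[[1]] + design[[2]]

  ranges <- apply(m, 1, function(v) max(v) - min(v))
  range_pass <- in_top_frac(ranges, range_top_frac)

  per_gene <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    d1 <- differential_flags(v[idx_mbec], v[idx_kln], mean_diff_min,
                             range_pass[i])
    d2 <- differential_flags(v[idx_mbec], v[idx_ln], mean_diff_min,
                             range_pass[i])
    pat <- classify_pattern(v[idx_mbec], v[idx_kln], v[idx_ln])
    dplyr::bind_cols(
      tibble(diff_mbec_kln = d1$differential, diff_mbec_ln4k1 =
               d2$differential, range_pass = range_pass[i]),
      pat)
  })
  out <- dplyr::bind_cols(tibble(symbol = x$symbol, entrez = x$entrez),
                          per_gene)
  out$differential <- out$diff_mbec_kln | out$diff_mbec_ln4k1
  out$selected <- out$differential & (out$pattern_A | out$pattern_B)
  class(out) <- c("pattern_selection", class(out))
  out
}

#' @export
print.pattern_selection <- function(x, ...) {
  cat("Gradient pattern selection:", sum(x$selected), "of", nrow(x),
      "genes selected (A:", sum(x$selected & x$pattern_A),
      ", B:", sum(x$selected & x$pattern_B), ")\n")
  NextMethod()
}

#' Cross-species concordant gene selection
#'
#' Maps mouse-selected genes to human orthologs and keeps those that, in the
#' human cohort, (a) are present (value >= `presence_value`) in more than
#' `presence_frac` of the Classical plus Secretory samples and (b) have a
#' Benjamini-Hochberg FDR on the Classical-versus-Secretory Wilcoxon
#' rank-sum p-values below `fdr_cut`. Survivors are split by the ratio of
#' the Classical to the Secretory median: ratio > 1 genes go to the `up`
#' (Classical-high) list, the rest to `down`. A zero Secretory median makes
#' the ratio infinite (assigned to `up`, with a warning).
#'
#' @param mouse_selected Character vector of selected mouse gene symbols.
#' @param human A human expression tibble.
#' @param labels Per-sample subtype labels for `human`.
#' @param orthomap Tibble with columns `mouse_symbol`, `human_symbol`
#'   (duplicated pairs are an error).
#' @param presence_value,presence_frac Presence filter (defaults 0.5, 0.6).
#' @param fdr_cut BH FDR threshold (default 5e-5).
#' @return A list: `up`/`down` (human gene symbol vectors) and `table`
#'   (per-candidate tibble with the filter columns).
#' @export
cross_species_select <- function(mouse_selected, human, labels, orthomap,
                                 presence_value = 0.5, presence_frac = 0.6,
                                 fdr_cut = 5e-5) {
  if (anyDuplicated(paste(orthomap$mouse_symbol, orthomap$human_symbol)))
    stop("duplicated ortholog pair(s)", call. = FALSE)
  cand <- unique(orthomap$human_symbol[orthomap$mouse_symbol %in%
                                         mouse_selected])
  cand <- intersect(cand, human$symbol)
  empty <- list(up = character(0), down = character(0),
                table = tibble(symbol = character(0)))
  if (length(cand) == 0) return(empty)

  m <- expr_mat(human)
  rows <- match(cand, human$symbol)
  cls <- labels == "Classical"
  sec <- labels == "Secretory"
  if (!any(cls) || !any(sec))
    stop("labels must contain Classical and Secretory samples",
         call. = FALSE)
  sub <- m[rows, cls | sec, drop = FALSE]
  presence <- rowSums(sub >= presence_value, na.rm = TRUE)
  pres_ok <- presence > presence_frac * ncol(sub)

  wp <- vapply(seq_along(cand), function(i) {
    a <- m[rows[i], cls]
    b <- m[rows[i], sec]
    wilcoxon_p(a[!is.na(a)], b[!is.na(b)])
  }, 0)
  fdr <- rep(NA_real_, length(cand))
  test_ok <- pres_ok & !is.na(wp)
  if (any(test_ok)) fdr[test_ok] <- bh_fdr(wp[test_ok])

  med_c <- apply(m[rows, cls, drop = FALSE], 1, stats::median, na.rm = TRUE)
  med_s <- apply(m[rows, sec, drop = FALSE], 1, stats::median, na.rm = TRUE)
  ratio <- med_c / med_s
  if (any(test_ok & med_s == 0 & med_c > 0))
    warning("zero Secretory median gives an infinite ratio for ",
            sum(test_ok & med_s == 0 & med_c > 0), " gene(s)", call. = FALSE)

  keep <- test_ok & !is.na(fdr) & fdr < fdr_cut
  tbl <- tibble(symbol = cand, presence = unname(presence),
                presence_ok = unname(pres_ok), wilcoxon_p = wp, fdr = fdr,
                median_classical = unname(med_c),
                median_secretory = unname(med_s),
                ratio = unname(ratio), kept = unname(keep))
  list(up = cand[keep & ratio > 1],
       down = cand[keep & !(ratio > 1)],
       table = tbl)
}
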