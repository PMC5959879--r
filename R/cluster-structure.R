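#' Log2 transform and center an expression tibble gene-wise
#'
#' Zeros become missing (the log transform of a null normalized value), all
#' remaining values are log2-transformed, and each gene row is centered by its
#' mean or median over the non-missing entries. A gene that is zero everywhere
#' is retained as an all-missing row and flagged.
#'
#' @param x An expression tibble (nonnegative values).
#' @param center `"mean"` (heat-map convention) or `"median"`.
#' @return A list of class `clustered_matrix`: `values` (gene x sample matrix
#'   with `NA` missing), `symbol`, `entrez`, `samples`, `center`,
#'   `all_missing` (logical per gene), plus `row_order`/`col_order` slots
#'   filled by [hierarchical_order()].
#' @export
log_center <- function(x, center = c("mean", "median")) {
  center <- match.arg(center)
  m <- expr_mat(x)
  if (any(is.finite(m) & m < 0)) stop("negative values", call. = FALSE)
  cm <- log2_center_rows(m, center)
  all_missing <- rowSums(!is.na(cm)) == 0
  structure(list(values = cm, symbol = x$symbol, entrez = x$entrez,
                 samples = expr_samples(x), center = center,
                 all_missing = all_missing,
                 row_order = seq_len(nrow(cm)),
                 col_order = seq_len(ncol(cm))),
            class = "clustered_matrix")
}

#' @export
print.clustered_matrix <- function(x, ...) {
  cat("Clustered matrix:", nrow(x$values), "genes x", length(x$samples),
      "samples (", x$center, "-centered log2; ",
      sum(x$all_missing), " all-missing row(s))\n", sep = "")
  invisible(x)
}

# Uncentered correlation (cosine about zero) over pairwise-complete entries.
uncentered_cor <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  den <- sqrt(sum(a[ok]^2) * sum(b[ok]^2))
  if (den == 0) return(0)
  sum(a[ok] * b[ok]) / den
}

uncentered_cor_matrix <- function(m) {
  n <- nrow(m)
  s <- diag(1, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        s[i, j] <- s[j, i] <- uncentered_cor(m[i, ], m[j, ])
      }
    }
  }
  s
}

hier_order_one <- function(m) {
  n <- nrow(m)
  if (n < 2) stop("need at least 2 items to cluster", call. = FALSE)
  s <- uncentered_cor_matrix(m)
  isolated <- vapply(seq_len(n), function(i)
    all(is.na(s[i, -i])), TRUE)
  if (any(isolated))
    warning(sum(isolated), " item(s) with no overlap against any other; ",
            "placed last", call. = FALSE)
  s[is.na(s)] <- -1  # no-overlap pairs are maximally dissimilar
  d <- stats::as.dist(1 - s)
  keep <- which(!isolated)
  if (length(keep) < n) {
    if (length(keep) < 2) return(seq_len(n))
    dk <- stats::as.dist((1 - s)[keep, keep])
    hc <- stats::hclust(dk, method = "average")
    return(c(keep[hc$order], which(isolated)))
  }
  hc <- stats::hclust(d, method = "average")
  hc$order
}

#' Hierarchical ordering by uncentered correlation, average linkage
#'
#' Orders rows and/or columns of a [log_center()] matrix by agglomerative
#' average-linkage clustering on the uncentered-correlation similarity
#' (distance `1 - s`), the convention of the legacy Cluster 3.0 tool.
#' Similarities over missing data use pairwise-complete positions.
#'
#' @param cm A `clustered_matrix`.
#' @param axes `"rows"`, `"cols"` or `"both"`.
#' @return The `clustered_matrix` with `row_order`/`col_order` replaced by
#'   the dendrogram leaf orders.
#' @export
hierarchical_order <- function(cm, axes = c("both", "rows", "cols")) {
  axes <- match.arg(axes)
  if (axes %in% c("rows", "both"))
    cm$row_order <- hier_order_one(cm$values)
  if (axes %in% c("cols", "both"))
    cm$col_order <- hier_order_one(t(cm$values))
  cm
}

#' City-block genomic dissimilarity among subtypes
#'
#' For each gene and subtype computes the mean expression, then the six
#' city-block (L1) distances between the four per-subtype mean vectors,
#' identifying the maximally dissimilar pair.
#'
#' @param x An expression tibble.
#' @param labels Per-sample subtype labels (all four subtypes present).
#' @return A list of class `genomic_dissimilarity`: `means` (gene x 4),
#'   `distances` (4 x 4 symmetric matrix), `max_pair` (character 2-vector),
#'   and `pairs` (tibble of the six distances).
#' @export
genomic_dissimilarity <- function(x, labels) {
  smp <- expr_samples(x)
  stopifnot(length(labels) == length(smp))
  n_s <- table(factor(labels, levels = SUBTYPES))
  if (any(n_s == 0))
    stop("missing subtype(s): ", paste(SUBTYPES[n_s == 0], collapse = ", "),
         call. = FALSE)
  m <- expr_mat(x)
  means <- vapply(SUBTYPES, function(s)
    rowMeans(m[, labels == s, drop = FALSE], na.rm = TRUE), numeric(nrow(m)))
  d <- matrix(0, 4, 4, dimnames = list(SUBTYPES, SUBTYPES))
  cmb <- utils::combn(SUBTYPES, 2)
  dist_vals <- apply(cmb, 2, function(p)
    sum(abs(means[, p[1]] - means[, p[2]]), na.rm = TRUE))
  for (k in seq_len(ncol(cmb)))
    d[cmb[1, k], cmb[2, k]] <- d[cmb[2, k], cmb[1, k]] <- dist_vals[k]
  max_k <- which.max(dist_vals)
  structure(list(means = means, distances = d,
                 max_pair = cmb[, max_k],
                 pairs = tibble(subtype_1 = cmb[1, ], subtype_2 = cmb[2, ],
                                distance = dist_vals)),
            class = "genomic_dissimilarity")
}

#' @export
print.genomic_dissimilarity <- function(x, ...) {
  cat("Maximal genomic dissimilarity:", paste(x$max_pair, collapse = " - "),
      "=", signif(max(x$pairs$distance), 6), "\n")
  invisible(x)
}

# Per-gene per-subtype percentage of samples hyper-expressing the gene
# (value >= the gene's mean over all samples), on the clustered-matrix scale.
hyper_fractions <- function(cm, labels) {
  v <- cm$values[cm$row_order, , drop = FALSE]
  gene_mean <- rowMeans(v, na.rm = TRUE)
  vapply(SUBTYPES, function(s) {
    sub <- v[, labels == s, drop = FALSE]
    rowMeans(sub >= gene_mean, na.rm = TRUE)
  }, numeric(nrow(v)))
}

#' Split a clustered heat map into upper and lower portions
#'
#' Scans a window of the row-ordered matrix with the hyper-expression
#' difference `delta(CB, PS) = mean(%Classical, %Basal) -
#' mean(%Primitive, %Secretory)`, where `%s` is the percentage of subtype-`s`
#' samples at or above the gene's mean. The upper portion ends one gene after
#' the maximal prefix (within the window) on which `delta < 0`, tolerating
#' violation runs of at most `tolerance` consecutive genes (runs reset once
#' the sign returns below zero).
#'
#' @param cm A row-ordered `clustered_matrix` (see [hierarchical_order()]).
#' @param labels Per-sample subtype labels.
#' @param window Integer range (in row-order positions) to scan.
#' @param tolerance Maximum tolerated run of non-negative `delta` (default 3).
#' @return A list of class `hm_split`: `split` (row-order index of the last
#'   upper gene, `NA` when no sign change is found), `delta` (tibble over the
#'   window), `upper`/`lower` (row-order index vectors), `found` (logical).
#' @export
heatmap_split <- function(cm, labels, window = NULL, tolerance = 3) {
  n <- nrow(cm$values)
  if (is.null(window)) window <- seq_len(n)
  if (min(window) < 1 || max(window) > n)
    stop("window out of bounds", call. = FALSE)
  fr <- hyper_fractions(cm, labels)
  delta <- (fr[, "Classical"] + fr[, "Basal"]) / 2 -
    (fr[, "Primitive"] + fr[, "Secretory"]) / 2
  w <- sort(window)
  dw <- delta[w]

  last_neg <- NA_integer_
  run <- 0L
  for (i in seq_along(w)) {
    if (is.na(dw[i])) next
    if (dw[i] < 0) {
      last_neg <- i
      run <- 0L
    } else {
      run <- run + 1L
      if (run > tolerance) break
    }
  }
  # a split requires an actual sign change: some non-negative delta after
  # the last accepted negative position
  found <- !is.na(last_neg) && last_neg < length(w) &&
    any(dw[seq(last_neg + 1, length(w))] >= 0, na.rm = TRUE)
  split <- if (found) w[last_neg] + 1L else NA_integer_
  if (found && split > n) split <- n
  upper <- if (found) seq_len(split) else integer(0)
  lower <- if (found) setdiff(seq_len(n), upper) else seq_len(n)
  structure(list(split = split,
                 delta = tibble(position = w, delta = dw),
                 upper = upper, lower = lower, found = found),
            class = "hm_split")
}

#' @export
print.hm_split <- function(x, ...) {
  if (x$found) {
    cat("Heat-map split after row", x$split, "(upper:", length(x$upper),
        "genes; lower:", length(x$lower), "genes)\n")
  } else {
    cat("No heat-map split found in the scanned window\n")
  }
  invisible(x)
}

#' Detect the first sustained sign change in a sequence
#'
#' A splitting point is a pair of consecutive values with opposite signs such
#' that the sequence does not revert to its previous sign for at least five
#' consecutive-value pairs following the flip. Returns the index of the last
#' element carrying the old sign (the element closing the top portion), or
#' `NA` when no sustained flip exists.
#'
#' @param seq Numeric vector, length at least 7; `NA`s are skipped when
#'   assessing persistence.
#' @param persist Number of following pairs that must hold the new sign
#'   (default 5).
#' @return Integer index or `NA_integer_`.
#' @export
splitting_point <- function(seq, persist = 5) {
  if (length(seq) < 7) stop("sequence shorter than 7", call. = FALSE)
  sgn <- sign(seq)
  n <- length(seq)
  base <- sgn[which(sgn != 0 & !is.na(sgn))[1]]
  if (is.na(base)) return(NA_integer_)
  # moving top to bottom, only flips away from the leading portion's sign
  # count: a flip back to it is the "reversion" the definition excludes
  for (i in seq_len(n - 1)) {
    if (is.na(sgn[i]) || is.na(sgn[i + 1])) next
    if (sgn[i] == base && sgn[i + 1] == -base) {
      tail_idx <- seq(i + 1, min(n, i + 1 + persist))
      if (length(tail_idx) < persist + 1) next
      tail_sgn <- sgn[tail_idx]
      if (!anyNA(tail_sgn) && all(tail_sgn == -base))
        return(i)
    }
  }
  NA_integer_
}

#' Subtype expression gradient across the two matrix halves
#'
#' For each half of a split matrix and each subtype (in the order Classical,
#' Basal, Primitive, Secretory) reports the average, over the half's genes,
#' of the fraction of that subtype's samples at or above the gene mean, and
#' whether the four values are strictly monotone (increasing in the upper
#' half, decreasing in the lower half, for a cohort with the canonical
#' gradient).
#'
#' @param cm A row-ordered `clustered_matrix`.
#' @param labels Per-sample subtype labels.
#' @param split An `hm_split` (or an integer last-upper-row index).
#' @return A tibble: `half`, the four per-subtype mean fractions, and
#'   `increasing`/`decreasing` monotonicity flags.
#' @export
gradient_fractions <- function(cm, labels, split) {
  split_idx <- if (inherits(split, "hm_split")) split$split else split
  n <- nrow(cm$values)
  if (is.na(split_idx) || split_idx < 1 || split_idx >= n)
    stop("invalid split index", call. = FALSE)
  fr <- hyper_fractions(cm, labels)
  halves <- list(upper = seq_len(split_idx),
                 lower = seq(split_idx + 1, n))
  purrr::map_dfr(names(halves), function(h) {
    vals <- colMeans(fr[halves[[h]], , drop = FALSE], na.rm = TRUE)
    out <- as_tibble(as.list(vals))
    dplyr::bind_cols(tibble(half = h), out,
                     tibble(increasing = all(diff(vals) > 0),
                            decreasing = all(diff(vals) < 0)))
  })
}
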