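SUBTYPES <- c("Classical", "Basal", "Primitive", "Secretory")

#' Log2-transform (zeros to missing) and median-center a matrix by row
#' @noRd
log2_center_rows <- function(m, center = c("median", "mean")) {
  center <- match.arg(center)
  m[m == 0] <- NA_real_
  m <- log2(m)
  stat <- if (center == "median") {
    apply(m, 1, stats::median, na.rm = TRUE)
  } else {
    rowMeans(m, na.rm = TRUE)
  }
  sweep(m, 1, stat, "-")
}

#' Nearest-centroid expression subtype assignment
#'
#' Reduces the cohort to genes shared with the centroid table, log2-transforms
#' the expression values (zeros become missing) and median-centers each gene
#' across the cohort, then computes per-sample Pearson correlations against
#' each of the four subtype centroids over the non-missing genes. The label is
#' the subtype with the largest correlation; exact ties fall back to the fixed
#' subtype order Classical, Basal, Primitive, Secretory. Samples with fewer
#' than two usable genes are flagged unassignable.
#'
#' @param x An expression tibble.
#' @param centroids Centroid tibble: `symbol` (optionally `entrez`) plus one
#'   numeric column per subtype (`Classical`, `Basal`, `Primitive`,
#'   `Secretory`), on the centered log2 scale of the published predictor.
#' @return A tibble: `sample`, the four per-subtype correlations
#'   (`cor_Classical`, ...), and `subtype` (`NA` when unassignable).
#' @export
assign_subtypes <- function(x, centroids) {
  stopifnot(all(SUBTYPES %in% names(centroids)))
  key_x <- gene_key(x$symbol, x$entrez)
  idx <- match(centroids$symbol, x$symbol)
  if ("entrez" %in% names(centroids)) {
    miss <- is.na(idx) & !is.na(centroids$entrez)
    idx[miss] <- match(centroids$entrez[miss], x$entrez)
  }
  shared <- !is.na(idx)
  if (sum(shared) < 2)
    stop("fewer than 2 genes shared with the centroid table", call. = FALSE)
  m <- expr_mat(x)[idx[shared], , drop = FALSE]
  cm <- log2_center_rows(m, "median")
  cen <- as.matrix(centroids[shared, SUBTYPES])

  cors <- vapply(seq_len(ncol(cm)), function(j) {
    v <- cm[, j]
    ok <- !is.na(v)
    if (sum(ok) < 2) return(rep(NA_real_, 4))
    vapply(SUBTYPES, function(s) {
      suppressWarnings(stats::cor(v[ok], cen[ok, s]))
    }, 0)
  }, numeric(4))

  label <- apply(cors, 2, function(r) {
    if (all(is.na(r))) return(NA_character_)
    SUBTYPES[which.max(r)]  # which.max takes the first max: fixed-order ties
  })
  out <- tibble(sample = expr_samples(x))
  cor_tbl <- as_tibble(t(cors), .name_repair = "minimal")
  names(cor_tbl) <- paste0("cor_", SUBTYPES)
  out <- dplyr::bind_cols(out, cor_tbl)
  out$subtype <- label
  out
}

#' Aggregate the four subtypes into two correlated pairs
#'
#' Averages the expression of every gene inside each subtype (vectors V_C,
#' V_B, V_P, V_S), computes the six pairwise Pearson correlations, and pairs
#' the subtypes by the two highest mutually exclusive coefficients (greedy:
#' the global maximum pair first, then the forced remaining pair). The display
#' order places the two largest-n subtypes at the flanks, giving the canonical
#' Classical-Basal | Primitive-Secretory layout on cohorts with the reference
#' structure.
#'
#' @param x An expression tibble.
#' @param labels Per-sample subtype labels aligned with `expr_samples(x)`;
#'   all four subtypes must be represented.
#' @return A list of class `subtype_aggregates`: `mean_vectors` (gene x 4
#'   matrix), `pair_correlations` (tibble of the six pairs), `aggregates`
#'   (list of two character pairs), `aggregate_labels` (named per-subtype
#'   aggregate id), `display_order` (4 subtypes), `n_samples` (per subtype).
#' @export
aggregate_subtypes <- function(x, labels) {
  smp <- expr_samples(x)
  stopifnot(length(labels) == length(smp))
  n_s <- table(factor(labels, levels = SUBTYPES))
  if (any(n_s == 0))
    stop("subtype(s) with no samples: ",
         paste(SUBTYPES[n_s == 0], collapse = ", "), call. = FALSE)
  m <- expr_mat(x)
  mv <- vapply(SUBTYPES, function(s)
    rowMeans(m[, labels == s, drop = FALSE], na.rm = TRUE), numeric(nrow(m)))

  pairs <- utils::combn(SUBTYPES, 2)
  pc <- tibble(
    subtype_1 = pairs[1, ], subtype_2 = pairs[2, ],
    correlation = apply(pairs, 2, function(p)
      stats::cor(mv[, p[1]], mv[, p[2]], use = "pairwise.complete.obs")))

  best <- which.max(pc$correlation)
  first <- c(pc$subtype_1[best], pc$subtype_2[best])
  second <- setdiff(SUBTYPES, first)
  aggregates <- list(first, second)

  # flanks: the two largest subtypes, one per aggregate, at the outside
  flank1 <- names(sort(n_s, decreasing = TRUE))[1]
  agg_of <- function(s) if (s %in% first) 1L else 2L
  other_agg <- aggregates[[3L - agg_of(flank1)]]
  flank2 <- other_agg[which.max(n_s[other_agg])]
  left <- aggregates[[agg_of(flank1)]]
  display <- c(flank1, setdiff(left, flank1), setdiff(other_agg, flank2),
               flank2)

  # aggregate ids from the subtype initials in display order (e.g. CB, PS)
  id_of <- function(members)
    paste(substr(display[display %in% members], 1, 1), collapse = "")
  agg_labels <- stats::setNames(
    ifelse(SUBTYPES %in% first, id_of(first), id_of(second)), SUBTYPES)

  structure(list(mean_vectors = mv, pair_correlations = pc,
                 aggregates = aggregates, aggregate_labels = agg_labels,
                 display_order = display,
                 n_samples = as.integer(n_s)[match(SUBTYPES, SUBTYPES)]),
            class = "subtype_aggregates")
}

#' @export
print.subtype_aggregates <- function(x, ...) {
  cat("Subtype aggregates:",
      paste(vapply(x$aggregates, paste, "", collapse = "+"),
            collapse = " | "),
      "\nDisplay order:", paste(x$display_order, collapse = ", "), "\n")
  invisible(x)
}

#' Per-sample aggregate (two-group) class labels
#'
#' @param agg A `subtype_aggregates` object.
#' @param labels Per-sample subtype labels.
#' @return Character vector of aggregate ids (e.g. `"CB"`/`"PS"`).
#' @export
aggregate_classes <- function(agg, labels) {
  unname(agg$aggregate_labels[labels])
}
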