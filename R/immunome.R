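#' Assemble the modified immune cell-type signature
#'
#' Merges a base marker table with explicit additions, matches genes to the
#' expression universe by Entrez identifier (genes without a match are
#' discarded), and validates the one-or-two cell types per gene rule. An
#' addition that would push a gene into a third cell type is an error naming
#' the gene.
#'
#' @param base_lists Signature tibble (`cell_type`, `immunity`, `symbol`,
#'   `entrez`), e.g. from [read_signature_file()].
#' @param additions Optional tibble of the same shape with extra
#'   (cell type, gene) memberships.
#' @param universe Tibble with `symbol`/`entrez` columns (typically the
#'   expression tibble itself) defining the measurable gene universe.
#' @return A signature tibble restricted to the universe, one row per
#'   (gene, cell type) membership, deduplicated.
#' @export
assemble_signature <- function(base_lists, additions = NULL, universe) {
  sig <- dplyr::bind_rows(base_lists, additions)
  sig <- dplyr::distinct(sig, .data$cell_type, .data$symbol, .data$entrez,
                         .keep_all = TRUE)
  key <- gene_key(sig$symbol, sig$entrez)
  n_types <- tapply(sig$cell_type, key, function(x) length(unique(x)))
  bad <- names(n_types)[n_types > 2]
  if (length(bad) > 0)
    stop("gene(s) assigned to more than two cell types: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  matched <- !is.na(sig$entrez) & sig$entrez %in% universe$entrez
  sig[matched, ]
}

#' Rank-based immune cell-type density scores
#'
#' The deconvolution-free infiltrate score: (1) each marker gene's expression
#' is ranked across samples from lowest to highest on the 1..n scale, ties
#' receiving the average of their ranks; (2) per cell type, each sample's
#' ranks are averaged across the cell type's marker genes. Genes belonging to
#' two cell types contribute with full weight to both. The scores depend only
#' on within-gene ranks, so they are invariant under any strictly increasing
#' per-gene transform of expression, and each cell type's scores average to
#' exactly `(n + 1) / 2` across samples.
#'
#' Signature genes are matched to the matrix by Entrez identifier, falling
#' back to the symbol; a cell type with no present marker is omitted with a
#' warning.
#'
#' @param x An expression tibble.
#' @param signature A signature tibble.
#' @return A `density_scores` tibble: `sample` plus one numeric column per
#'   cell type, each score in `[1, n]`.
#' @export
density_scores <- function(x, signature) {
  m <- expr_mat(x)
  row_of <- function(sym, ent) {
    i <- if (!is.na(ent)) match(ent, x$entrez) else NA_integer_
    if (is.na(i) && !is.na(sym)) i <- match(sym, x$symbol)
    i
  }
  sig <- dplyr::distinct(signature, .data$cell_type, .data$symbol,
                         .data$entrez)
  sig$row <- mapply(row_of, sig$symbol, sig$entrez)
  sig <- sig[!is.na(sig$row), ]
  types <- unique(signature$cell_type)
  absent <- setdiff(types, sig$cell_type)
  if (length(absent) > 0) {
    warning("cell type(s) with no present marker omitted: ",
            paste(absent, collapse = ", "), call. = FALSE)
    types <- setdiff(types, absent)
  }
  if (length(types) == 0) stop("no scorable cell type", call. = FALSE)

  ranks <- t(apply(m[unique(sig$row), , drop = FALSE], 1, rank,
                   ties.method = "average"))
  rownames(ranks) <- as.character(unique(sig$row))
  scores <- vapply(types, function(ct) {
    rows <- as.character(sig$row[sig$cell_type == ct])
    colMeans(ranks[rows, , drop = FALSE])
  }, numeric(ncol(m)))
  out <- dplyr::bind_cols(tibble(sample = expr_samples(x)),
                          as_tibble(scores, .name_repair = "minimal"))
  class(out) <- c("density_scores", class(out))
  out
}

score_mat <- function(density) {
  m <- as.matrix(density[, setdiff(names(density), "sample"), drop = FALSE])
  rownames(m) <- density$sample
  m
}

#' CD14 scores and density-based survival for the CD14+ cell types
#'
#' Splits samples into high (>= median, inclusive) and low CD14 expression
#' groups; for each of the nine CD14+ cell types computes the ratio of mean
#' density score in the high versus the low group and ranks the nine ratios
#' (the CD14 score, `y = 9` for the highest ratio, `y = 1` for the lowest;
#' exact ties are broken by the declared cell-type order so the ranks stay a
#' permutation of 1..9). Each cell type additionally gets a median-split
#' survival effect on its own density scores.
#'
#' @param density A `density_scores` tibble.
#' @param cd14 Per-sample CD14 expression aligned with `density$sample`.
#' @param cd14_types Character vector of exactly nine cell-type column names.
#' @param clinical Survival tibble aligned by `sample`.
#' @return A `cd14_scores` tibble: one row per cell type with
#'   `density_ratio`, `cd14_score`, and the survival-effect columns.
#' @export
cd14_scores <- function(density, cd14, cd14_types, clinical) {
  if (length(cd14_types) != 9)
    stop("exactly 9 CD14+ cell types required, got ", length(cd14_types),
         call. = FALSE)
  missing <- setdiff(cd14_types, names(density))
  if (length(missing) > 0)
    stop("cell type(s) not scored: ", paste(missing, collapse = ", "),
         call. = FALSE)
  stopifnot(length(cd14) == nrow(density))
  idx <- match(density$sample, clinical$sample)
  if (anyNA(idx)) stop("clinical table lacks scored sample(s)", call. = FALSE)
  clinical <- clinical[idx, ]

  high <- cd14 >= stats::median(cd14)
  sm <- score_mat(density)[, cd14_types, drop = FALSE]
  ratio <- colMeans(sm[high, , drop = FALSE]) /
    colMeans(sm[!high, , drop = FALSE])
  y <- rank(ratio, ties.method = "first")  # declared order breaks exact ties

  effects <- purrr::map_dfr(cd14_types, function(ct)
    median_split_effect(sm[, ct], clinical))
  out <- dplyr::bind_cols(
    tibble(cell_type = cd14_types, density_ratio = unname(ratio),
           cd14_score = as.integer(unname(y))),
    effects)
  class(out) <- c("cd14_scores", class(out))
  out
}

#' Spearman correlation structure among scored cell types
#'
#' Computes the Spearman correlation matrix over the cell-type density-score
#' columns and hierarchically orders it in both dimensions without any
#' transformation or centering (uncentered-correlation similarity, average
#' linkage, applied to the raw coefficient rows/columns). The colour-scale
#' bounds reported are the matrix minimum and maximum.
#'
#' @param density A `density_scores` tibble (>= 2 cell types).
#' @return A list of class `celltype_correlations`: `spearman` (symmetric
#'   matrix, unit diagonal), `order` (leaf order of the clustering, applied
#'   to both axes), `range` (c(min, max)), `undefined` (cell types with
#'   constant scores, whose entries are `NA`).
#' @export
celltype_correlations <- function(density) {
  sm <- score_mat(density)
  if (ncol(sm) < 2) stop("need at least 2 cell types", call. = FALSE)
  constant <- apply(sm, 2, function(v) stats::sd(v) == 0)
  if (any(constant))
    warning("constant score column(s): ",
            paste(colnames(sm)[constant], collapse = ", "), call. = FALSE)
  rho <- suppressWarnings(stats::cor(sm, method = "spearman"))
  diag(rho) <- 1
  ord <- hier_order_one(rho)
  structure(list(spearman = rho, order = ord,
                 range = range(rho, na.rm = TRUE),
                 undefined = colnames(sm)[constant]),
            class = "celltype_correlations")
}

#' @export
print.celltype_correlations <- function(x, ...) {
  cat("Spearman correlation structure over", nrow(x$spearman),
      "cell types; range [", signif(x$range[1], 3), ",",
      signif(x$range[2], 3), "]\n")
  invisible(x)
}
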