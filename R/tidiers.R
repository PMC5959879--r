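#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the pairwise subtype correlations of an aggregation
#'
#' @param x A `subtype_aggregates` object.
#' @param ... Unused.
#' @return The six-pair correlation tibble with an `aggregated` flag marking
#'   the chosen pairs.
#' @method tidy subtype_aggregates
#' @export
tidy.subtype_aggregates <- function(x, ...) {
  pc <- x$pair_correlations
  in_agg <- function(a, b) any(vapply(x$aggregates, function(p)
    setequal(p, c(a, b)), TRUE))
  pc$aggregated <- mapply(in_agg, pc$subtype_1, pc$subtype_2)
  pc
}

#' @rdname tidy.subtype_aggregates
#' @method glance subtype_aggregates
#' @export
glance.subtype_aggregates <- function(x, ...) {
  tibble(aggregate_1 = paste(x$aggregates[[1]], collapse = "+"),
         aggregate_2 = paste(x$aggregates[[2]], collapse = "+"),
         display_order = paste(x$display_order, collapse = ", "))
}

#' Tidy the six city-block subtype distances
#'
#' @param x A `genomic_dissimilarity` object.
#' @param ... Unused.
#' @return The pairs tibble with an `is_max` flag.
#' @method tidy genomic_dissimilarity
#' @export
tidy.genomic_dissimilarity <- function(x, ...) {
  p <- x$pairs
  p$is_max <- p$distance == max(p$distance)
  p
}

#' @rdname tidy.genomic_dissimilarity
#' @method glance genomic_dissimilarity
#' @export
glance.genomic_dissimilarity <- function(x, ...) {
  tibble(max_pair = paste(x$max_pair, collapse = "-"),
         max_distance = max(x$pairs$distance))
}

#' Tidy the hyper-expression difference sequence of a heat-map split
#'
#' @param x An `hm_split` object.
#' @param ... Unused.
#' @return The per-position `delta` tibble.
#' @method tidy hm_split
#' @export
tidy.hm_split <- function(x, ...) x$delta

#' @rdname tidy.hm_split
#' @method glance hm_split
#' @export
glance.hm_split <- function(x, ...) {
  tibble(found = x$found, split = x$split,
         n_upper = length(x$upper), n_lower = length(x$lower))
}

#' Tidy a cell-type Spearman correlation structure
#'
#' @param x A `celltype_correlations` object.
#' @param ... Unused.
#' @return A long tibble (`cell_type_1`, `cell_type_2`, `spearman`) in
#'   clustered display order.
#' @method tidy celltype_correlations
#' @export
tidy.celltype_correlations <- function(x, ...) {
  m <- x$spearman[x$order, x$order]
  lv <- colnames(m)
  out <- as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE))
  names(out) <- c("cell_type_1", "cell_type_2", "spearman")
  out$cell_type_1 <- factor(out$cell_type_1, levels = lv)
  out$cell_type_2 <- factor(out$cell_type_2, levels = lv)
  out
}

#' @rdname tidy.celltype_correlations
#' @method glance celltype_correlations
#' @export
glance.celltype_correlations <- function(x, ...) {
  tibble(n_cell_types = nrow(x$spearman),
         min = x$range[1], max = x$range[2],
         n_undefined = length(x$undefined))
}
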