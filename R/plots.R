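#' Kaplan-Meier curves for labelled groups
#'
#' @param clinical Survival tibble (`survival_years`, `event`).
#' @param groups Per-sample group labels.
#' @return A ggplot of the stepped survival curves, annotated with the
#'   log-rank p-value.
#' @export
plot_km <- function(clinical, groups) {
  fit <- survival::survfit(surv_obj(clinical) ~ groups)
  strata <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  d <- dplyr::bind_rows(
    tibble(time = 0, surv = 1, group = unique(strata)),
    tibble(time = fit$time, surv = fit$surv, group = strata))
  lr <- logrank_groups(clinical, groups)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$surv,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Years", y = "Overall survival",
                  colour = NULL,
                  subtitle = sprintf("log-rank p = %.3g (df = %d)",
                                     lr$p, lr$df)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of a survival screen
#'
#' @param object A `survival_screen` tibble.
#' @param p_cut Significance line (default 0.05).
#' @param ... Unused.
#' @return A ggplot of log2 hazard ratio against -log10 log-rank p.
#' @method autoplot survival_screen
#' @export
autoplot.survival_screen <- function(object, p_cut = 0.05, ...) {
  d <- object[!object$untestable, ]
  d$significant <- d$logrank_p < p_cut
  ggplot2::ggplot(d, ggplot2::aes(log2(.data$hazard_ratio),
                                  -log10(.data$logrank_p),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(p_cut), linetype = 2) +
    ggplot2::labs(x = "log2 HR (high vs low)", y = "-log10 log-rank p",
                  colour = sprintf("p < %.3g", p_cut)) +
    ggplot2::theme_minimal()
}

#' Heat map of immune cell-type density scores
#'
#' @param object A `density_scores` tibble.
#' @param order_by Optional per-sample numeric vector (e.g. CD14 expression)
#'   ordering the columns.
#' @param ... Unused.
#' @return A ggplot tile heat map (cell types x samples).
#' @method autoplot density_scores
#' @export
autoplot.density_scores <- function(object, order_by = NULL, ...) {
  d <- tidyr::pivot_longer(object, -"sample", names_to = "cell_type",
                           values_to = "score")
  lv <- if (is.null(order_by)) unique(object$sample) else
    object$sample[order(order_by)]
  d$sample <- factor(d$sample, levels = lv)
  ggplot2::ggplot(d, ggplot2::aes(.data$sample, .data$cell_type,
                                  fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Density\nscore") +
    ggplot2::labs(x = "Sample", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' CD14 score versus survival hazard for the CD14+ cell types
#'
#' @param object A `cd14_scores` tibble.
#' @param ... Unused.
#' @return A ggplot of the hazard ratio (with 95% CI) against the CD14
#'   score rank.
#' @method autoplot cd14_scores
#' @export
autoplot.cd14_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$cd14_score, .data$hazard_ratio,
                                       label = .data$cell_type)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.1) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::scale_x_continuous(breaks = 1:9) +
    ggplot2::labs(x = "CD14 score (rank of high/low density ratio)",
                  y = "Hazard ratio (high vs low density)") +
    ggplot2::theme_minimal()
}

#' Hyper-expression difference profile around a heat-map split
#'
#' @param object An `hm_split` object.
#' @param ... Unused.
#' @return A ggplot of the delta(CB, PS) sequence over the scanned window
#'   with the split position marked.
#' @method autoplot hm_split
#' @export
autoplot.hm_split <- function(object, ...) {
  p <- ggplot2::ggplot(object$delta,
                       ggplot2::aes(.data$position, .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Gene position (clustered order)",
                  y = expression(Delta * "(CB, PS)")) +
    ggplot2::theme_minimal()
  if (object$found)
    p <- p + ggplot2::geom_vline(xintercept = object$split, linetype = 2,
                                 colour = "red")
  p
}

#' Clustered Spearman correlation heat map of cell types
#'
#' @param object A `celltype_correlations` object.
#' @param ... Unused.
#' @return A ggplot tile map in clustered order, colour bounds at the matrix
#'   min/max.
#' @method autoplot celltype_correlations
#' @export
autoplot.celltype_correlations <- function(object, ...) {
  d <- tidy.celltype_correlations(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$cell_type_1, .data$cell_type_2,
                                  fill = .data$spearman)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = object$range, name = "Spearman") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
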