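#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis with its
#' default. Any field can be overridden through `...`.
#'
#' @param seed Master RNG seed for the synthetic stages.
#' @param out_dir Optional directory; when set, every intermediate result is
#'   written there as TSV.
#' @param ... Overrides for the defaults listed below.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL, ...) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    # synthetic cohort
    n_samples = 348, n_genes = 2000, noise_sd = 0.5, zero_rate = 0.02,
    # survival generator
    planted_hr = 2, censor_rate = 0.3,
    # signature generator
    n_celltypes = 9, markers_per_type = 5, coupling = 0.9,
    # selection cascade
    p_cut = 0.01, q_cut = 0.01, presence_value = 0.5, presence_frac = 0.6,
    # heat-map split
    split_window = NULL, split_tolerance = 3,
    # batch survival screen
    screen_p_cut = 0.05,
    # stage toggles
    run_mouse = FALSE,
    mouse_n_genes = 1000, mouse_planted_A = 50, mouse_planted_B = 50,
    mouse_effect = 6)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

write_stage <- function(cfg, name, tbl) {
  if (!is.null(cfg$out_dir)) {
    if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
    readr::write_tsv(tbl, file.path(cfg$out_dir, paste0(name, ".tsv")),
                     progress = FALSE)
  }
  invisible(NULL)
}

#' Run the full synthetic end-to-end analysis
#'
#' Generates a synthetic cohort and executes, in order: subtype assignment
#' and aggregation, the hybrid gene-selection cascade, log-centering with
#' hierarchical row ordering and the gradient heat-map split, the batch
#' median-split survival screen on the upper portion (keeping genes with
#' log-rank p below `screen_p_cut`), immune signature construction with
#' density scoring and CD14 scores, and optionally the mouse gradient-pattern
#' stage. Identical configurations produce identical results.
#'
#' @param config A [pipeline_config()] list.
#' @return A list of class `pipeline_report`: per-stage results, a `stages`
#'   tibble with status and timing, and the effective `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list(config = config)
  log <- list()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- fun()
    log[[length(log) + 1]] <<- tibble(
      stage = name, status = "completed",
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }

  res$cohort <- stage("simulate_cohort", function()
    generate_cohort(n_samples = config$n_samples, n_genes = config$n_genes,
                    noise_sd = config$noise_sd, zero_rate = config$zero_rate,
                    seed = config$seed))
  sig_cohort <- stage("simulate_signature", function()
    generate_signature_cohort(res$cohort, n_celltypes = config$n_celltypes,
                              markers_per_type = config$markers_per_type,
                              coupling = config$coupling,
                              seed = config$seed + 1))
  res$expr <- sig_cohort$expr
  res$signature <- sig_cohort$signature

  cd14_row <- which(res$expr$symbol == "CD14")
  cd14 <- as.numeric(expr_mat(res$expr)[cd14_row, ])
  res$clinical <- stage("simulate_survival", function()
    generate_survival(stats::setNames(cd14, expr_samples(res$expr)),
                      hr = config$planted_hr,
                      censor_rate = config$censor_rate,
                      seed = config$seed + 2))

  res$assignment <- stage("assign_subtypes", function()
    assign_subtypes(res$expr, res$cohort$centroids))
  labels <- res$cohort$labels
  res$aggregates <- stage("aggregate_subtypes", function()
    aggregate_subtypes(res$expr, labels))
  classes <- aggregate_classes(res$aggregates, labels)
  smp <- expr_samples(res$expr)

  res$selection <- stage("hybrid_select", function()
    hybrid_select(res$expr, smp[classes == unique(classes)[1]],
                  smp[classes == unique(classes)[2]],
                  p_cut = config$p_cut, q_cut = config$q_cut,
                  presence_value = config$presence_value,
                  presence_frac = config$presence_frac))
  write_stage(config, "gene_selection", res$selection)

  sel_expr <- res$expr[res$selection$selected, ]
  res$clustered <- stage("cluster", function()
    hierarchical_order(log_center(sel_expr, "mean"), axes = "rows"))
  res$split <- stage("heatmap_split", function()
    heatmap_split(res$clustered, labels, window = config$split_window,
                  tolerance = config$split_tolerance))

  upper_rows <- if (res$split$found) {
    res$clustered$row_order[res$split$upper]
  } else {
    seq_len(nrow(sel_expr))
  }
  upper_keys <- gene_key(sel_expr$symbol, sel_expr$entrez)[upper_rows]
  res$screen <- stage("batch_survival", function()
    batch_gene_survival(sel_expr, res$clinical, upper_keys))
  write_stage(config, "survival_screen", as_tibble(res$screen))
  res$survival_genes <- res$screen$gene[
    !res$screen$untestable & res$screen$logrank_p < config$screen_p_cut]

  res$density <- stage("density_scores", function()
    density_scores(res$expr, res$signature))
  write_stage(config, "density_scores", as_tibble(res$density))
  res$cd14 <- stage("cd14_scores", function()
    cd14_scores(res$density, cd14,
                intersect(names(res$density), CD14_TYPES),
                res$clinical))
  write_stage(config, "cd14_scores", as_tibble(res$cd14))
  res$correlations <- stage("celltype_correlations", function()
    celltype_correlations(res$density))

  if (isTRUE(config$run_mouse)) {
    mouse <- stage("simulate_mouse", function()
      generate_mouse_arrays(n_genes = config$mouse_n_genes,
                            n_planted_A = config$mouse_planted_A,
                            n_planted_B = config$mouse_planted_B,
                            effect = config$mouse_effect,
                            seed = config$seed + 3))
    res$mouse <- mouse
    res$mouse_selection <- stage("mouse_patterns", function()
      select_pattern_genes(mouse$expr, design = mouse$design))
    write_stage(config, "mouse_selection", as_tibble(res$mouse_selection))
  }

  res$stages <- dplyr::bind_rows(log)
  class(res) <- "pipeline_report"
  res
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$config$seed, "): ",
      nrow(x$stages), " stages completed\n", sep = "")
  cat(" - selected genes:", sum(x$selection$selected), "\n")
  if (x$split$found)
    cat(" - heat-map split after row", x$split$split, "\n")
  cat(" - survival genes (p <", x$config$screen_p_cut, "):",
      length(x$survival_genes), "\n")
  top <- x$cd14$cell_type[x$cd14$cd14_score == 9]
  cat(" - top CD14-score cell type:", top, "\n")
  invisible(x)
}
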