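CD14_TYPES <- c("IM", "aDC", "DC", "iDC", "M1", "M2", "Macrophages",
                "MDSC", "Neutrophils")

#' Generate a synthetic four-subtype expression cohort
#'
#' Draws four subtype centroids on the log2 scale with the correlation
#' structure the downstream analysis assumes: a shared per-gene baseline, a
#' pair-level module shift shared inside the Classical/Basal and the
#' Primitive/Secretory pair, and a subtype-specific shift. Sample expression
#' is `2^(centroid + Gaussian noise)` (log-normal noise on the normalized
#' RSEM-like scale) with a `zero_rate` fraction of entries zeroed to exercise
#' the null-to-missing path. Identical seeds give bit-identical output.
#'
#' @param n_samples Cohort size (>= 40; default 348, a TCGA-scale cohort).
#' @param n_genes Number of genes (default 2000).
#' @param subtype_props Named proportions over the four subtypes summing to 1
#'   (default approximates the reference cohort's 208/140 CB/PS balance).
#' @param noise_sd Per-value Gaussian noise on the log2 scale (default 0.5).
#' @param zero_rate Fraction of zeroed entries (default 0.02).
#' @param seed Integer RNG seed.
#' @param sd_base,sd_pair,sd_subtype Standard deviations of the baseline,
#'   pair-shared and subtype-specific centroid components.
#' @return A list: `expr` (expression tibble), `labels` (per-sample subtype),
#'   `centroids` (tibble on the centered log2 scale for
#'   [assign_subtypes()]), `truth` (generator parameters and seeds).
#' @export
generate_cohort <- function(n_samples = 348, n_genes = 2000,
                            subtype_props = c(Classical = 0.36, Basal = 0.24,
                                              Primitive = 0.15,
                                              Secretory = 0.25),
                            noise_sd = 0.5, zero_rate = 0.02, seed = 1,
                            sd_base = 1.2, sd_pair = 0.8, sd_subtype = 0.4) {
  stopifnot(n_samples >= 40, n_genes >= 8)
  subtype_props <- subtype_props[SUBTYPES]
  if (anyNA(subtype_props) || abs(sum(subtype_props) - 1) > 1e-8 ||
      any(subtype_props <= 0))
    stop("subtype_props must be positive over the four subtypes and sum to 1",
         call. = FALSE)
  withr::local_seed(seed)

  base <- stats::rnorm(n_genes, mean = 6, sd = sd_base)
  shift_cb <- stats::rnorm(n_genes, 0, sd_pair)
  shift_ps <- stats::rnorm(n_genes, 0, sd_pair)
  cent <- vapply(SUBTYPES, function(s) {
    pair <- if (s %in% c("Classical", "Basal")) shift_cb else shift_ps
    base + pair + stats::rnorm(n_genes, 0, sd_subtype)
  }, numeric(n_genes))

  counts <- floor(subtype_props * n_samples)
  rem <- n_samples - sum(counts)
  if (rem > 0) {
    o <- order(subtype_props * n_samples - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }
  labels <- rep(SUBTYPES, counts)
  samples <- sprintf("S%03d", seq_len(n_samples))

  logval <- cent[, labels, drop = FALSE] +
    matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd), n_genes)
  vals <- 2^logval
  if (zero_rate > 0) {
    zero <- stats::runif(length(vals)) < zero_rate
    vals[zero] <- 0
  }
  symbols <- sprintf("G%05d", seq_len(n_genes))
  expr <- new_expr_tbl(symbols, seq_len(n_genes) + 100000L, vals, samples)

  cent_centered <- cent - apply(cent, 1, stats::median)
  centroids <- dplyr::bind_cols(
    tibble(symbol = symbols, entrez = seq_len(n_genes) + 100000L),
    as_tibble(cent_centered, .name_repair = "minimal"))

  list(expr = expr, labels = labels, centroids = centroids,
       truth = list(seed = seed, noise_sd = noise_sd, zero_rate = zero_rate,
                    counts = stats::setNames(as.integer(counts), SUBTYPES),
                    centroid_log2 = cent))
}

#' Generate survival data with a planted marker-driven hazard
#'
#' Event times are exponential with a baseline yearly rate multiplied by the
#' planted hazard ratio for samples at or above the marker median; censoring
#' times are independent exponentials calibrated so that roughly
#' `censor_rate` of baseline samples are censored. Times are on the years
#' scale.
#'
#' @param marker Per-sample numeric marker values (names become sample ids;
#'   unnamed markers get `S001`...).
#' @param hr Planted hazard ratio of the high (>= median) group (> 0).
#' @param censor_rate Approximate censoring fraction in `[0, 1)`; 0 means
#'   every sample has an event.
#' @param base_rate Baseline events per year (default 0.35).
#' @param seed Integer RNG seed.
#' @return A survival tibble (`sample`, `survival_years`, `event`, `stage`).
#' @export
generate_survival <- function(marker, hr = 2, censor_rate = 0.3,
                              base_rate = 0.35, seed = 1) {
  stopifnot(hr > 0)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)", call. = FALSE)
  withr::local_seed(seed)
  n <- length(marker)
  ids <- names(marker)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  high <- marker >= stats::median(marker)
  rate <- base_rate * ifelse(high, hr, 1)
  t_event <- stats::rexp(n, rate)
  if (censor_rate > 0) {
    c_rate <- base_rate * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(n, c_rate)
    tibble(sample = ids, survival_years = pmin(t_event, t_cens),
           event = as.integer(t_event <= t_cens), stage = NA_character_)
  } else {
    tibble(sample = ids, survival_years = t_event, event = 1L,
           stage = NA_character_)
  }
}

#' Add immune cell-type marker modules to a synthetic cohort
#'
#' Appends per-cell-type marker gene modules to a base expression tibble.
#' Markers of one cell type share a latent per-sample activity; the first
#' cell type's activity is correlated (strength `coupling`) with the latent
#' driving a designated CD14-like gene, emulating the coupling between a
#' CD14-high microenvironment and one infiltrate population. A fraction of
#' markers carries a second cell-type membership.
#'
#' @param cohort A list from [generate_cohort()] (or any list with an `expr`
#'   tibble).
#' @param n_celltypes Number of cell types (default 9, the CD14+ set; extra
#'   types get generic labels).
#' @param markers_per_type Markers per cell type (default 5).
#' @param coupling Correlation in `[0, 1]` between the first module's
#'   activity and the CD14-like latent (default 0.9).
#' @param dual_frac Fraction of markers given a second cell type (default
#'   0.04, the composition scale of the curated signature).
#' @param activity_sd Marker loading on the module activity, log2 scale
#'   (default 1).
#' @param noise_sd Marker-level residual noise, log2 scale (default 0.5).
#' @param seed Integer RNG seed.
#' @return A list: `expr` (base plus marker genes plus the CD14 gene),
#'   `signature` (signature tibble), `truth` (coupled cell type, latents,
#'   marker map).
#' @export
generate_signature_cohort <- function(cohort, n_celltypes = 9,
                                      markers_per_type = 5, coupling = 0.9,
                                      dual_frac = 0.04, activity_sd = 1,
                                      noise_sd = 0.5, seed = 1) {
  stopifnot(coupling >= 0, coupling <= 1, n_celltypes >= 2)
  withr::local_seed(seed)
  expr <- cohort$expr
  smp <- expr_samples(expr)
  n <- length(smp)

  types <- if (n_celltypes <= length(CD14_TYPES)) {
    CD14_TYPES[seq_len(n_celltypes)]
  } else {
    c(CD14_TYPES, sprintf("CT%02d", seq_len(n_celltypes - length(CD14_TYPES))))
  }

  z_cd14 <- stats::rnorm(n)
  activity <- matrix(stats::rnorm(n * n_celltypes), n, n_celltypes)
  activity[, 1] <- coupling * z_cd14 +
    sqrt(1 - coupling^2) * stats::rnorm(n)

  n_mark <- n_celltypes * markers_per_type
  mark_type <- rep(seq_len(n_celltypes), each = markers_per_type)
  logval <- matrix(0, n_mark, n)
  for (i in seq_len(n_mark)) {
    logval[i, ] <- 6 + activity_sd * activity[, mark_type[i]] +
      stats::rnorm(n, 0, noise_sd)
  }
  cd14_log <- 6 + z_cd14 + stats::rnorm(n, 0, 0.1)

  mark_sym <- sprintf("MK%04d", seq_len(n_mark))
  mark_ent <- 500000L + seq_len(n_mark)
  add_expr <- new_expr_tbl(c(mark_sym, "CD14"), c(mark_ent, 929L),
                           2^rbind(logval, cd14_log), smp)
  expr_out <- dplyr::bind_rows(expr, add_expr)

  sig <- tibble(cell_type = types[mark_type], immunity = "innate",
                symbol = mark_sym, entrez = mark_ent)
  n_dual <- round(dual_frac * n_mark)
  if (n_dual > 0) {
    di <- seq_len(n_dual)
    second <- types[(mark_type[di] %% n_celltypes) + 1L]
    sig <- dplyr::bind_rows(sig, tibble(
      cell_type = second, immunity = "innate",
      symbol = mark_sym[di], entrez = mark_ent[di]))
  }
  list(expr = expr_out, signature = sig,
       truth = list(coupled_type = types[1], coupling = coupling,
                    types = types, cd14_latent = z_cd14,
                    marker_types = stats::setNames(types[mark_type],
                                                   mark_sym),
                    seed = seed))
}

#' Generate a three-condition replicate microarray matrix
#'
#' Emulates the normal -> primary -> metastatic design (4 + 3 + 3 replicate
#' columns, RMA-like log2 scale): null genes vary around per-gene baselines,
#' planted pattern-A genes carry strictly increasing condition means and
#' planted pattern-B genes the mirrored decreasing means, with the smallest
#' between-condition gap equal to `effect` noise standard deviations.
#'
#' @param n_genes Total genes (default 1000).
#' @param n_planted_A,n_planted_B Planted monotone gene counts (defaults 50).
#' @param effect Gap size in units of the replicate noise standard deviation
#'   (default 6).
#' @param noise_sd Replicate noise on the log2-like scale (default 0.4).
#' @param design Replicate counts per condition.
#' @param seed Integer RNG seed.
#' @return A list: `expr` (expression tibble with replicate columns), `truth`
#'   (per-gene `"A"`/`"B"`/`"null"` labels).
#' @export
generate_mouse_arrays <- function(n_genes = 1000, n_planted_A = 50,
                                  n_planted_B = 50, effect = 6,
                                  noise_sd = 0.4,
                                  design = c(mbec = 4, kln205 = 3,
                                             ln4k1 = 3), seed = 1) {
  stopifnot(n_planted_A + n_planted_B <= n_genes)
  withr::local_seed(seed)
  n_rep <- sum(design)
  cond <- rep(seq_along(design), design)
  gap <- effect * noise_sd
  # multiplicative condition means (ratio 1.6 per step) so the relative
  # mean-difference criterion clears its 50% threshold whenever the absolute
  # gap is separable; effect = 0 collapses planted genes onto a flat profile
  means_A <- if (gap > 0) {
    (gap / 0.6) * 1.6^(seq_along(design) - 1)
  } else {
    rep(7, length(design))
  }
  means_B <- rev(means_A)

  truth <- rep("null", n_genes)
  truth[seq_len(n_planted_A)] <- "A"
  truth[n_planted_A + seq_len(n_planted_B)] <- "B"

  base_null <- stats::runif(n_genes, 5, 9)
  vals <- matrix(0, n_genes, n_rep)
  for (i in seq_len(n_genes)) {
    mu <- switch(truth[i], A = means_A[cond], B = means_B[cond],
                 rep(base_null[i], n_rep))
    vals[i, ] <- mu + stats::rnorm(n_rep, 0, noise_sd)
  }
  vals <- pmax(vals, 0)
  cols <- unlist(mapply(function(nm, k) sprintf("%s_%d", nm, seq_len(k)),
                        names(design), design, SIMPLIFY = FALSE))
  expr <- new_expr_tbl(sprintf("Mg%04d", seq_len(n_genes)),
                       700000L + seq_len(n_genes), vals, cols)
  list(expr = expr, truth = truth, design = design,
       params = list(effect = effect, noise_sd = noise_sd, seed = seed))
}

#' Write the packaged synthetic immune signature file
#'
#' Builds a deterministic synthetic stand-in for a curated immune cell-type
#' marker signature with the composition of the modified immunome signature:
#' 598 distinct genes over 29 cell types (the 9 CD14+ types among them), 572
#' genes with a unique cell type and 26 carrying a second one, each gene
#' tagged innate or adaptive. Gene identifiers are synthetic
#' (`IMM0001`..., Entrez 600001...), except the six canonical inflammatory
#' monocyte markers (CD14, CCL2, CCR2, CCL3, CSF1R, CSF1) which keep their
#' real symbols and Entrez ids under the IM label.
#'
#' @param path Output path for the GMT-like file.
#' @param n_genes,n_dual,n_types Composition (defaults 598, 26, 29).
#' @return The signature tibble, invisibly; the file is written to `path`.
#' @export
generate_signature_file <- function(path, n_genes = 598, n_dual = 26,
                                    n_types = 29) {
  im_sym <- c("CD14", "CCL2", "CCR2", "CCL3", "CSF1R", "CSF1")
  im_ent <- c(929L, 6347L, 729230L, 6348L, 1436L, 1435L)
  n_syn <- n_genes - length(im_sym)
  sym <- c(im_sym, sprintf("IMM%04d", seq_len(n_syn)))
  ent <- c(im_ent, 600000L + seq_len(n_syn))

  extra <- sprintf("CT%02d", seq_len(max(0, n_types - length(CD14_TYPES))))
  types <- c(CD14_TYPES, extra)[seq_len(n_types)]
  innate <- c(CD14_TYPES, extra[seq_len(floor(length(extra) / 2))])

  # round-robin primary membership; IM markers pinned to IM
  primary <- c(rep("IM", length(im_sym)),
               types[(seq_len(n_syn) - 1) %% n_types + 1])
  sig <- tibble(cell_type = primary,
                immunity = ifelse(primary %in% innate, "innate", "adaptive"),
                symbol = sym, entrez = ent)
  if (n_dual > 0) {
    di <- length(im_sym) + seq_len(n_dual)  # synthetic genes only
    second <- types[(match(primary[di], types) + 6) %% n_types + 1]
    sig <- dplyr::bind_rows(sig, tibble(
      cell_type = second,
      immunity = ifelse(second %in% innate, "innate", "adaptive"),
      symbol = sym[di], entrez = ent[di]))
  }
  sig <- sig[order(match(sig$cell_type, types)), ]
  write_signature_file(sig, path)
  invisible(sig)
}
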