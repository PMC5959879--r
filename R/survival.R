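#' Preprocess raw clinical records into an analysis-ready survival table
#'
#' Applies the cohort survival-curation rules:
#' (i) records with a negative days-to-last-follow-up are discarded;
#' (ii) the event indicator is 1 for vital status `"dead"`, 0 for `"alive"`;
#' (iii) for dead patients the survival time is days-to-death;
#' (iv) for alive patients it is the maximum of days-to-last-follow-up and
#' days-to-last-known-alive over the fields present;
#' (v) years = days / 365.
#'
#' An alive record carrying a positive days-to-death is flagged as a conflict
#' (such records need manual resolution against the clinical source); by
#' default the vital-status label wins and the record is kept as alive, unless
#' `conflict_override` reassigns it. Alive records with no follow-up field at
#' all are dropped with a warning.
#'
#' @param raw Tibble of raw clinical records from [read_clinical_table()].
#' @param conflict_override Optional named character vector
#'   (sample -> `"alive"`/`"dead"`) resolving flagged conflicts.
#' @return A list with `clinical` (tibble: `sample`, `survival_years`,
#'   `event`, `stage`, `conflict`) and `discarded` (tibble of dropped raw
#'   records plus a `reason` column).
#' @export
preprocess_survival <- function(raw, conflict_override = NULL) {
  vs <- tolower(raw$vital_status)
  unknown <- !vs %in% c("dead", "alive")
  if (any(unknown))
    stop("unknown vital status label(s): ",
         paste(unique(raw$vital_status[unknown]), collapse = ", "),
         call. = FALSE)

  conflict <- vs == "alive" & !is.na(raw$days_to_death) & raw$days_to_death > 0
  if (!is.null(conflict_override)) {
    hit <- raw$sample %in% names(conflict_override) & conflict
    vs[hit] <- tolower(conflict_override[raw$sample[hit]])
  }

  neg_fu <- !is.na(raw$days_to_last_followup) & raw$days_to_last_followup < 0
  alive_max <- pmax(raw$days_to_last_followup, raw$days_to_last_known_alive,
                    na.rm = TRUE)
  alive_max[is.na(raw$days_to_last_followup) &
              is.na(raw$days_to_last_known_alive)] <- NA_real_
  days <- ifelse(vs == "dead", raw$days_to_death, alive_max)
  no_time <- is.na(days)

  keep <- !neg_fu & !no_time
  if (any(no_time & !neg_fu))
    warning(sum(no_time & !neg_fu),
            " record(s) without a usable survival time dropped", call. = FALSE)

  discarded <- dplyr::bind_rows(
    dplyr::mutate(raw[neg_fu, ], reason = "negative days_to_last_followup"),
    dplyr::mutate(raw[no_time & !neg_fu, ], reason = "no survival time"))

  clinical <- tibble(
    sample = raw$sample[keep],
    survival_years = days[keep] / 365,
    event = as.integer(vs[keep] == "dead"),
    stage = raw$stage[keep],
    conflict = conflict[keep])
  list(clinical = clinical, discarded = discarded)
}

surv_obj <- function(clinical) {
  survival::Surv(clinical$survival_years, clinical$event)
}

#' Log-rank (Mantel-Cox) test across labelled groups
#'
#' @param clinical Survival tibble with `survival_years` and `event`.
#' @param groups Per-sample group labels aligned with `clinical` rows.
#' @return One-row tibble: `chisq`, `df` (number of groups minus one), `p`.
#' @export
logrank_groups <- function(clinical, groups) {
  groups <- as.character(groups)
  if (length(groups) != nrow(clinical) || anyNA(groups))
    stop("every sample needs a group label", call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups", call. = FALSE)
  if (any(tab == 0)) stop("empty group", call. = FALSE)
  sd <- survival::survdiff(surv_obj(clinical) ~ groups)
  df <- length(tab) - 1L
  tibble(chisq = unname(sd$chisq), df = df,
         p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Median-split survival effect for one continuous variable
#'
#' Splits samples into a high group (value >= median, inclusive) and a low
#' group (value < median), fits a proportional-hazards model on the binary
#' indicator, and runs a log-rank test on the same split. The hazard ratio is
#' high versus low with a Wald 95% confidence interval on the log scale.
#'
#' Because the split depends only on ranks, the effect is invariant under any
#' strictly increasing transform of `values`.
#'
#' @param values Per-sample finite numeric vector aligned with `clinical`.
#' @param clinical Survival tibble (`survival_years`, `event`).
#' @param ties Tie handling of the partial likelihood, `"efron"` (default) or
#'   `"breslow"`.
#' @return One-row tibble: `hazard_ratio`, `ci_low`, `ci_high`, `logrank_p`,
#'   `n_high`, `n_low`, `untestable`.
#' @export
median_split_effect <- function(values, clinical, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(values) != nrow(clinical))
    stop("values and clinical are not aligned", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  if (length(values) < 10) stop("need at least 10 samples", call. = FALSE)
  high <- values >= stats::median(values)
  if (all(high) || !any(high)) {
    return(tibble(hazard_ratio = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, logrank_p = NA_real_,
                  n_high = sum(high), n_low = sum(!high), untestable = TRUE))
  }
  fit <- survival::coxph(surv_obj(clinical) ~ high, ties = ties)
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))[1]
  sd <- survival::survdiff(surv_obj(clinical) ~ high)
  tibble(hazard_ratio = exp(beta),
         ci_low = exp(beta - 1.959964 * se),
         ci_high = exp(beta + 1.959964 * se),
         logrank_p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
         n_high = sum(high), n_low = sum(!high), untestable = FALSE)
}

#' Quartile-split log-rank test
#'
#' Cuts the samples into four groups at the lower, middle and upper quartile
#' dividing points of `values` (each cut is inclusive on the high side, as in
#' the median split) and runs a 3-degree-of-freedom log-rank test.
#'
#' @inheritParams median_split_effect
#' @return One-row tibble: `chisq`, `df` (= 3), `p`, `n1`..`n4`.
#' @export
quartile_split_logrank <- function(values, clinical) {
  if (length(values) != nrow(clinical))
    stop("values and clinical are not aligned", call. = FALSE)
  if (length(values) < 20) stop("need at least 20 samples", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  grp <- findInterval(values, q, left.open = FALSE) + 1L
  tab <- tabulate(grp, 4)
  if (any(tab == 0))
    stop("quartile cut at ", paste(signif(q, 6), collapse = "/"),
         " leaves an empty group", call. = FALSE)
  res <- logrank_groups(clinical, grp)
  tibble(chisq = res$chisq, df = res$df, p = res$p,
         n1 = tab[1], n2 = tab[2], n3 = tab[3], n4 = tab[4])
}

#' Batch per-gene median-split survival screen
#'
#' Runs [median_split_effect()] for every gene of a subset, collecting hazard
#' ratios, confidence intervals and log-rank p-values, and adds a
#' Benjamini-Hochberg FDR across the testable genes of the batch.
#'
#' @param x An expression tibble whose samples align with `clinical$sample`.
#' @param clinical Survival tibble.
#' @param gene_subset Character vector of gene keys (see [gene_key()]) to
#'   screen; must all be rows of `x`.
#' @param ties Passed to [median_split_effect()].
#' @return A `survival_screen` tibble: one row per gene with the effect
#'   columns plus `fdr` (`NA` for untestable genes).
#' @export
batch_gene_survival <- function(x, clinical, gene_subset,
                                ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(gene_subset) == 0) stop("empty gene subset", call. = FALSE)
  m <- expr_mat(x)
  missing <- setdiff(gene_subset, rownames(m))
  if (length(missing) > 0)
    stop("gene(s) not in the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  smp <- expr_samples(x)
  if (!identical(smp, clinical$sample)) {
    idx <- match(smp, clinical$sample)
    if (anyNA(idx))
      stop("clinical table lacks sample(s): ",
           paste(utils::head(smp[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    clinical <- clinical[idx, ]
  }
  res <- purrr::map_dfr(gene_subset, function(g)
    median_split_effect(m[g, ], clinical, ties = ties))
  res <- dplyr::bind_cols(tibble(gene = gene_subset), res)
  res$fdr <- NA_real_
  testable <- !res$untestable
  res$fdr[testable] <- bh_fdr(res$logrank_p[testable])
  class(res) <- c("survival_screen", class(res))
  res
}

#' @export
print.survival_screen <- function(x, ...) {
  cat("Median-split survival screen over", nrow(x), "genes;",
      sum(!x$untestable), "testable,",
      sum(x$logrank_p < 0.05, na.rm = TRUE), "with log-rank p < 0.05\n")
  NextMethod()
}

#' @rdname batch_gene_survival
#' @param path Output TSV path.
#' @param screen A `survival_screen` tibble.
#' @export
write_survival_screen <- function(screen, path) {
  readr::write_tsv(
    screen[, c("gene", "hazard_ratio", "ci_low", "ci_high", "logrank_p",
               "fdr", "n_high", "n_low")], path, progress = FALSE)
  invisible(path)
}
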