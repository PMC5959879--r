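#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

GENE_COLS <- c("symbol", "entrez")

#' Sample (column) identifiers of an expression tibble
#'
#' An expression tibble is a wide tibble with one row per gene, the gene
#' identifier columns `symbol` (character) and `entrez` (integer), and one
#' numeric column per sample holding nonnegative normalized expression values
#' (RSEM or RMA scale). `NA` cells are missing values, distinct from zero.
#'
#' @param x An expression tibble.
#' @return Character vector of sample identifiers.
#' @export
expr_samples <- function(x) setdiff(names(x), GENE_COLS)

#' Extract the numeric value matrix of an expression tibble
#'
#' @param x An expression tibble.
#' @return A numeric gene x sample matrix; row names are gene keys
#'   (`"SYMBOL|ENTREZ"` where both identifiers exist).
#' @export
expr_mat <- function(x) {
  m <- as.matrix(x[, expr_samples(x), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gene_key(x$symbol, x$entrez)
  m
}

#' Combined gene key from symbol and Entrez identifier
#'
#' @param symbol Character vector of gene symbols (`NA` allowed).
#' @param entrez Integer vector of Entrez ids (`NA` allowed).
#' @return Character keys: `"SYMBOL|ENTREZ"` when both present, otherwise the
#'   one present identifier.
#' @export
gene_key <- function(symbol, entrez) {
  dplyr::case_when(
    !is.na(symbol) & !is.na(entrez) ~ paste0(symbol, "|", entrez),
    !is.na(symbol) ~ as.character(symbol),
    TRUE ~ as.character(entrez)
  )
}

new_expr_tbl <- function(symbol, entrez, values, samples) {
  stopifnot(length(symbol) == nrow(values), length(samples) == ncol(values))
  out <- tibble(symbol = as.character(symbol),
                entrez = as.integer(entrez))
  vals <- as_tibble(as.data.frame(values, optional = TRUE),
                    .name_repair = "minimal")
  names(vals) <- samples
  dplyr::bind_cols(out, vals)
}

validate_expr <- function(x, context = "expression table") {
  smp <- expr_samples(x)
  if (anyDuplicated(smp))
    stop(context, ": duplicate sample identifier(s): ",
         paste(unique(smp[duplicated(smp)]), collapse = ", "), call. = FALSE)
  m <- expr_mat(x)
  neg <- which(is.finite(m) & m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(context, ": negative value at gene '", rownames(m)[neg[1, 1]],
         "', sample '", smp[neg[1, 2]], "'", call. = FALSE)
  no_id <- is.na(x$symbol) & is.na(x$entrez)
  if (any(no_id))
    stop(context, ": ", sum(no_id), " gene row(s) with neither symbol nor ",
         "Entrez identifier", call. = FALSE)
  invisible(x)
}

#' Read a gene x sample normalized expression table
#'
#' Reads a TSV with a header row of sample identifiers and one row per gene.
#' In the `tcga_level3` dialect (TCGA RNA-seq V2 level-3 RSEM files) the first
#' column holds `"SYMBOL|ENTREZ"` row keys which are split into the two
#' identifier columns; an unknown symbol (`"?"`) becomes `NA`. In the `plain`
#' dialect the first column is taken as the gene symbol.
#'
#' Values must be finite and nonnegative or `NA` (missing). Zero is a valid
#' expression value and is never converted to missing at read time.
#'
#' @param path Path to a tab-separated file.
#' @param dialect `"tcga_level3"` or `"plain"`.
#' @return An expression tibble (see [expr_samples()]).
#' @export
read_expression_table <- function(path, dialect = c("tcga_level3", "plain")) {
  dialect <- match.arg(dialect)
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(hdr[-1]))
    stop(path, ": duplicate sample identifier(s): ",
         paste(unique(hdr[-1][duplicated(hdr[-1])]), collapse = ", "),
         call. = FALSE)
  spec <- readr::cols(.default = readr::col_double())
  spec$cols[[hdr[1]]] <- readr::col_character()
  raw <- readr::read_tsv(path, col_types = spec, progress = FALSE,
                         name_repair = "minimal")
  key <- as.character(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (dialect == "tcga_level3") {
    parts <- strsplit(key, "|", fixed = TRUE)
    symbol <- vapply(parts, `[`, "", 1)
    entrez <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2) p[2] else NA_character_, "")))
    symbol[symbol %in% c("?", "")] <- NA_character_
  } else {
    symbol <- key
    entrez <- rep(NA_integer_, length(key))
  }
  out <- new_expr_tbl(symbol, entrez, vals, colnames(raw)[-1])
  validate_expr(out, context = path)
}

#' Write an expression tibble as TSV
#'
#' Inverse of [read_expression_table()]: the gene key column is the
#' `"SYMBOL|ENTREZ"` join in `tcga_level3` dialect, the symbol in `plain`.
#'
#' @inheritParams read_expression_table
#' @param x An expression tibble.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path,
                                   dialect = c("tcga_level3", "plain")) {
  dialect <- match.arg(dialect)
  key <- if (dialect == "tcga_level3") {
    paste0(ifelse(is.na(x$symbol), "?", x$symbol), "|",
           ifelse(is.na(x$entrez), "", x$entrez))
  } else x$symbol
  out <- dplyr::bind_cols(tibble(gene_id = key),
                          x[, expr_samples(x), drop = FALSE])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a raw clinical survival table
#'
#' Extracts, per sample, the four survival fields (days to death, days to last
#' follow-up, days to last known alive, vital status) plus an optional stage
#' label. Missing cells and `"NA"` tokens become `NA`; an unparseable day
#' value triggers a record-level warning and becomes `NA`. No filtering or
#' consistency resolution happens here — raw records, including negative day
#' values, are passed through for [preprocess_survival()] to act on.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param col_map Named character vector mapping the canonical field names
#'   (`sample`, `days_to_death`, `days_to_last_followup`,
#'   `days_to_last_known_alive`, `vital_status`, `stage`) to the file's column
#'   names. Defaults to the canonical names themselves; `stage` is optional.
#' @return A tibble of raw clinical records, one row per sample.
#' @export
read_clinical_table <- function(path, col_map = NULL) {
  canonical <- c(sample = "sample",
                 days_to_death = "days_to_death",
                 days_to_last_followup = "days_to_last_followup",
                 days_to_last_known_alive = "days_to_last_known_alive",
                 vital_status = "vital_status",
                 stage = "stage")
  if (!is.null(col_map)) canonical[names(col_map)] <- col_map
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  need <- canonical[setdiff(names(canonical), "stage")]
  missing_cols <- setdiff(unname(need), names(raw))
  if (length(missing_cols) > 0)
    stop("clinical table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  parse_days <- function(x, field) {
    x[x %in% c("NA", "")] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    if (any(bad))
      warning(sum(bad), " unparseable ", field, " value(s) set to NA",
              call. = FALSE)
    out
  }
  tibble(
    sample = raw[[canonical["sample"]]],
    days_to_death = parse_days(raw[[canonical["days_to_death"]]],
                               "days_to_death"),
    days_to_last_followup = parse_days(
      raw[[canonical["days_to_last_followup"]]], "days_to_last_followup"),
    days_to_last_known_alive = parse_days(
      raw[[canonical["days_to_last_known_alive"]]], "days_to_last_known_alive"),
    vital_status = tolower(raw[[canonical["vital_status"]]]),
    stage = if (canonical["stage"] %in% names(raw))
      raw[[canonical["stage"]]] else NA_character_
  )
}

#' Read an immune cell-type marker signature (GMT-like)
#'
#' One line per cell type: cell-type label, immunity tag (`innate` or
#' `adaptive`), then tab-separated gene tokens in `SYMBOL|ENTREZ` form
#' (either half may be absent). A gene may belong to one or two cell types;
#' three or more is a validation error.
#'
#' @param path Path to the signature file.
#' @return A signature tibble with columns `cell_type`, `immunity`, `symbol`,
#'   `entrez` — one row per (gene, cell type) membership.
#' @export
read_signature_file <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::map_dfr(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("signature line with fewer than 3 fields: ", substr(ln, 1, 40),
           call. = FALSE)
    toks <- f[-(1:2)]
    toks <- toks[nzchar(toks)]
    parts <- strsplit(toks, "|", fixed = TRUE)
    tibble(
      cell_type = f[1],
      immunity = f[2],
      symbol = vapply(parts, function(p)
        if (nzchar(p[1])) p[1] else NA_character_, ""),
      entrez = suppressWarnings(as.integer(vapply(parts, function(p)
        if (length(p) >= 2) p[2] else NA_character_, "")))
    )
  })
  validate_signature(rows)
}

validate_signature <- function(sig) {
  key <- gene_key(sig$symbol, sig$entrez)
  n_types <- tapply(sig$cell_type, key, function(x) length(unique(x)))
  bad <- names(n_types)[n_types > 2]
  if (length(bad) > 0)
    stop("signature gene(s) assigned to more than two cell types: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  sig
}

#' Write a signature tibble in the GMT-like format
#'
#' @param sig A signature tibble (see [read_signature_file()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_file <- function(sig, path) {
  by_type <- split(sig, factor(sig$cell_type, levels = unique(sig$cell_type)))
  lines <- vapply(by_type, function(d) {
    toks <- paste0(ifelse(is.na(d$symbol), "", d$symbol), "|",
                   ifelse(is.na(d$entrez), "", d$entrez))
    toks <- sub("\\|$", "", toks)
    paste(c(d$cell_type[1], d$immunity[1], toks), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Summarise signature composition
#'
#' @param sig A signature tibble.
#' @return One-row tibble: total distinct genes, genes with a unique cell
#'   type, genes with a second cell type, and the number of cell types.
#' @export
signature_summary <- function(sig) {
  key <- gene_key(sig$symbol, sig$entrez)
  n_types <- tapply(sig$cell_type, key, function(x) length(unique(x)))
  tibble(n_genes = length(n_types),
         n_single_type = sum(n_types == 1),
         n_dual_type = sum(n_types == 2),
         n_cell_types = length(unique(sig$cell_type)))
}

#' Export expression and class files for external gene-set tools
#'
#' Writes a GCT v1.2 expression file and a two-class categorical CLS file,
#' the input pair consumed by gene-set enrichment tools. Class counts and
#' sample order are preserved.
#'
#' @param x An expression tibble.
#' @param classes Per-sample class labels (character or factor), aligned with
#'   `expr_samples(x)`, or a named vector keyed by sample; exactly two
#'   distinct classes, no sample unlabelled.
#' @param gct_path,cls_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
export_gene_set_inputs <- function(x, classes, gct_path, cls_path) {
  smp <- expr_samples(x)
  if (!is.null(names(classes))) {
    missing <- setdiff(smp, names(classes))
    if (length(missing) > 0)
      stop("class missing for sample(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    classes <- classes[smp]
  }
  if (length(classes) != length(smp) || anyNA(classes))
    stop("every sample needs a class label", call. = FALSE)
  classes <- as.character(classes)
  lev <- unique(classes)
  if (length(lev) != 2)
    stop("expected exactly two classes, got ", length(lev), call. = FALSE)

  m <- expr_mat(x)
  header <- c("#1.2", paste(nrow(m), ncol(m), sep = "\t"))
  body <- dplyr::bind_cols(
    tibble(NAME = rownames(m),
           Description = ifelse(is.na(x$symbol), "na", x$symbol)),
    as_tibble(as.data.frame(m), .name_repair = "minimal"))
  names(body)[-(1:2)] <- smp
  readr::write_lines(header, gct_path)
  suppressMessages(readr::write_tsv(body, gct_path, append = TRUE,
                                    col_names = TRUE, progress = FALSE))
  cls <- c(paste(length(smp), 2, 1),
           paste(c("#", lev), collapse = " "),
           paste(match(classes, lev) - 1L, collapse = " "))
  readr::write_lines(cls, cls_path)
  invisible(list(gct = gct_path, cls = cls_path))
}

#' Read a GCT v1.2 expression file
#'
#' @param path Path to a GCT file.
#' @return An expression tibble; the GCT `NAME` column is re-split into
#'   symbol/Entrez when it has the `"SYMBOL|ENTREZ"` form.
#' @export
read_gct <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  if (lines[1] != "#1.2") stop("not a GCT v1.2 file: ", path, call. = FALSE)
  tab <- readr::read_tsv(I(paste(lines[-(1:2)], collapse = "\n")),
                         col_types = readr::cols(
                           NAME = readr::col_character(),
                           Description = readr::col_character(),
                           .default = readr::col_double()),
                         progress = FALSE)
  parts <- strsplit(tab$NAME, "|", fixed = TRUE)
  symbol <- vapply(parts, `[`, "", 1)
  entrez <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 2) p[2] else NA_character_, "")))
  symbol[symbol %in% c("?", "")] <- NA_character_
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  new_expr_tbl(symbol, entrez, vals, colnames(tab)[-(1:2)])
}
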