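# In-code fixture builders shared across the suite.

make_expr <- function(values, symbols = NULL, entrez = NULL,
                      samples = NULL) {
  values <- as.matrix(values)
  if (is.null(symbols)) symbols <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(entrez)) entrez <- seq_len(nrow(values)) + 1000L
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  out <- tibble::tibble(symbol = symbols, entrez = as.integer(entrez))
  vals <- tibble::as_tibble(as.data.frame(values), .name_repair = "minimal")
  names(vals) <- samples
  dplyr::bind_cols(out, vals)
}

make_clinical <- function(years, event, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("S%02d", seq_along(years))
  tibble::tibble(sample = samples, survival_years = years,
                 event = as.integer(event), stage = NA_character_)
}

# exponential survival fixture with optional rate ratio between two halves
make_exp_clinical <- function(n, rate = 0.5, rate2 = NULL, seed = 1) {
  withr::local_seed(seed)
  if (is.null(rate2)) {
    years <- stats::rexp(n, rate)
  } else {
    years <- c(stats::rexp(n %/% 2, rate), stats::rexp(n - n %/% 2, rate2))
  }
  make_clinical(years, rep(1L, n))
}
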