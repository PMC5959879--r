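base_sig <- function() {
  tibble::tibble(
    cell_type = c("IM", "MDSC", "Treg"),
    immunity = c("innate", "innate", "adaptive"),
    symbol = c("CCL2", "S100A8", "FOXP3"),
    entrez = c(6347L, 6279L, 50943L))
}

test_that("signature assembly merges, matches by Entrez, enforces limits", {
  universe <- tibble::tibble(
    symbol = c("CCL2", "S100A8", "FOXP3", "CD14", "CCR2", "CCL3", "CSF1R",
               "CSF1", "OTHER"),
    entrez = c(6347L, 6279L, 50943L, 929L, 729230L, 6348L, 1436L, 1435L,
               999L))
  # empty additions: signature = base list intersected with the universe
  plain <- assemble_signature(base_sig(), universe = universe)
  expect_equal(sort(plain$symbol), sort(base_sig()$symbol))
  # canonical inflammatory monocyte additions all land under IM
  adds <- tibble::tibble(
    cell_type = "IM", immunity = "innate",
    symbol = c("CD14", "CCL2", "CCR2", "CCL3", "CSF1R", "CSF1"),
    entrez = c(929L, 6347L, 729230L, 6348L, 1436L, 1435L))
  merged <- assemble_signature(base_sig(), adds, universe)
  im <- merged$symbol[merged$cell_type == "IM"]
  expect_true(all(c("CD14", "CCL2", "CCR2", "CCL3", "CSF1R", "CSF1") %in% im))
  # a gene without an Entrez match in the universe is discarded
  uni2 <- universe[universe$symbol != "CD14", ]
  m2 <- assemble_signature(base_sig(), adds, uni2)
  expect_false("CD14" %in% m2$symbol)
  # a third cell type for one gene is an error naming the gene
  third <- tibble::tibble(cell_type = c("MDSC", "aDC"), immunity = "innate",
                          symbol = "CCL2", entrez = 6347L)
  expect_error(assemble_signature(base_sig(), third, universe), "CCL2")
})

test_that("density scores are tie-averaged ranks averaged over markers", {
  # 4 samples; g1 ascending, g2 descending: every sample averages to 2.5
  x <- make_expr(rbind(c(1, 2, 3, 4), c(4, 3, 2, 1)),
                 symbols = c("g1", "g2"), entrez = c(11L, 12L))
  sig <- tibble::tibble(cell_type = "CT", immunity = "innate",
                        symbol = c("g1", "g2"), entrez = c(11L, 12L))
  ds <- density_scores(x, sig)
  expect_equal(ds$CT, rep(2.5, 4))
  # one-gene signature: scores are exactly that gene's tie-averaged ranks
  one <- density_scores(x, sig[1, ])
  expect_equal(one$CT, rank(c(1, 2, 3, 4)))
  tied <- make_expr(matrix(c(5, 5, 1, 9), 1), symbols = "g1", entrez = 11L)
  ds_t <- density_scores(tied, sig[1, ])
  expect_equal(ds_t$CT, c(2.5, 2.5, 1, 4))
})

test_that("scores conserve the rank sum and respect rank-only dependence", {
  withr::local_seed(5)
  n <- 30
  x <- make_expr(matrix(stats::rgamma(20 * n, 2, 0.4), 20))
  sig <- tibble::tibble(
    cell_type = rep(c("A", "B", "C"), c(7, 7, 6)),
    immunity = "innate", symbol = x$symbol, entrez = x$entrez)
  # dual membership: the first two A genes also belong to B
  sig2 <- dplyr::bind_rows(sig, tibble::tibble(
    cell_type = "B", immunity = "innate",
    symbol = x$symbol[1:2], entrez = x$entrez[1:2]))
  ds <- density_scores(x, sig2)
  for (ct in c("A", "B", "C"))
    expect_equal(mean(ds[[ct]]), (n + 1) / 2)
  expect_true(all(as.matrix(ds[, -1]) >= 1 & as.matrix(ds[, -1]) <= n))
  # strictly inside (1, n) for imperfectly concordant multi-marker types
  expect_true(all(ds$A > 1 & ds$A < n))
  # invariant under strictly increasing per-gene transforms
  m <- expr_mat(x)
  warped <- make_expr(t(apply(m, 1, function(v) exp(v / max(v)))),
                      symbols = x$symbol, entrez = x$entrez)
  expect_equal(density_scores(warped, sig2)[, -1], ds[, -1],
               ignore_attr = TRUE)
  # a cell type with no measurable marker is dropped with a warning
  sig3 <- dplyr::bind_rows(sig, tibble::tibble(
    cell_type = "GHOST", immunity = "innate", symbol = "nope",
    entrez = 9999999L))
  expect_warning(ds3 <- density_scores(x, sig3), "GHOST")
  expect_false("GHOST" %in% names(ds3))
})

test_that("CD14 scores rank the nine density ratios into a permutation", {
  withr::local_seed(6)
  n <- 60
  types <- c("IM", "aDC", "DC", "iDC", "M1", "M2", "Macrophages", "MDSC",
             "Neutrophils")
  ds <- tibble::tibble(sample = sprintf("S%02d", 1:n))
  for (ct in types) ds[[ct]] <- sample.int(n)
  class(ds) <- c("density_scores", class(ds))
  cd14 <- stats::rnorm(n)
  cl <- make_exp_clinical(n, rate = 0.4)
  res <- cd14_scores(ds, cd14, types, cl)
  expect_setequal(res$cd14_score, 1:9)
  expect_equal(res$cell_type, types)
  # duplicated columns tie their ratios; declared order breaks the tie and
  # the ranks stay a permutation
  ds2 <- ds
  for (ct in types) ds2[[ct]] <- ds$IM
  res2 <- cd14_scores(ds2, cd14, types, cl)
  expect_setequal(res2$cd14_score, 1:9)
  expect_equal(res2$cd14_score, seq_len(9))
  expect_error(cd14_scores(ds, cd14, types[1:5], cl), "exactly 9")
})

test_that("a module coupled to CD14 earns the top CD14 score", {
  hits <- vapply(1:20, function(s) {
    co <- generate_cohort(n_samples = 80, n_genes = 40, seed = s,
                          zero_rate = 0)
    sc <- generate_signature_cohort(co, coupling = 0.9, seed = s + 100)
    ds <- density_scores(sc$expr, sc$signature)
    cd14 <- as.numeric(expr_mat(sc$expr)[sc$expr$symbol == "CD14", ])
    cl <- generate_survival(stats::setNames(cd14, ds$sample), hr = 2,
                            seed = s + 200)
    res <- cd14_scores(ds, cd14, intersect(names(ds), sc$truth$types), cl)
    res$cell_type[res$cd14_score == 9] == sc$truth$coupled_type
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("cell-type correlation structure is symmetric and clustered", {
  withr::local_seed(7)
  n <- 40
  ds <- tibble::tibble(sample = sprintf("S%02d", 1:n))
  # two planted modules among 8 synthetic types
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  for (i in 1:4) ds[[paste0("M1_", i)]] <- rank(z1 + stats::rnorm(n, 0, 0.3))
  for (i in 1:4) ds[[paste0("M2_", i)]] <- rank(z2 + stats::rnorm(n, 0, 0.3))
  class(ds) <- c("density_scores", class(ds))
  cc <- celltype_correlations(ds)
  expect_identical(cc$spearman, t(cc$spearman))
  expect_equal(unname(diag(cc$spearman)), rep(1, 8))
  # module members end up adjacent in the clustered leaf order
  lab <- substr(colnames(cc$spearman)[cc$order], 1, 2)
  expect_equal(length(rle(lab)$lengths), 2)
  # duplicated cell-type columns correlate at exactly 1
  ds$M1_dup <- ds$M1_1
  cc2 <- celltype_correlations(ds)
  expect_equal(cc2$spearman["M1_1", "M1_dup"], 1)
  expect_equal(cc2$range[2], 1)
  # constant columns are flagged
  ds$flat <- 1
  ws <- capture_warnings(cc3 <- celltype_correlations(ds))
  expect_match(ws, "constant", all = FALSE)
  expect_true("flat" %in% cc3$undefined)
})
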