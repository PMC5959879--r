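test_that("probe collapsing keeps the max-SD entry per symbol", {
  x <- make_expr(rbind(c(1, 2, 3), c(1, 2, 3), c(5, 5, 6), c(1, 9, 1)),
                 symbols = c("A", "A", "B", "B"))
  out <- collapse_probes(x)
  expect_equal(nrow(out), 2)
  expect_equal(unname(expr_mat(out)["A|1001", ]), c(1, 2, 3))
  expect_equal(unname(expr_mat(out)[out$symbol == "B", ]), c(1, 9, 1))
  # symbol-less rows are dropped
  x2 <- make_expr(rbind(c(1, 1, 1), c(2, 2, 2)),
                  symbols = c(NA, "C"))
  expect_equal(collapse_probes(x2)$symbol, "C")
  # brute-force argmax-SD oracle over a random duplicated fixture
  withr::local_seed(1)
  syms <- sample(LETTERS[1:8], 30, replace = TRUE)
  vals <- matrix(stats::rgamma(30 * 5, 2, 0.4), 30)
  xf <- make_expr(vals, symbols = syms)
  got <- collapse_probes(xf)
  for (s in unique(syms)) {
    idx <- which(syms == s)
    best <- idx[which.max(apply(vals[idx, , drop = FALSE], 1, stats::sd))]
    expect_equal(unname(expr_mat(got)[got$symbol == s, ]),
                 unname(vals[best, ]))
  }
})

test_that("separation probability matches exhaustive enumeration", {
  expect_equal(round(separation_p(4, 3), 4), 0.0286)
  expect_equal(separation_p(1, 1), 0.5)
  expect_equal(separation_p(3, 3), 1 / 20)
  # enumeration oracle for all n1 + n2 <= 10
  for (n1 in 1:5) {
    for (n2 in 1:(10 - n1)) {
      n <- n1 + n2
      picks <- utils::combn(n, n2)
      # group-2 occupies the top n2 positions in exactly one arrangement
      hits <- sum(apply(picks, 2, function(p) all(p > n1)))
      expect_equal(separation_p(n1, n2), hits / ncol(picks))
    }
  }
})

test_that("differential criteria evaluate separation and mean difference", {
  d <- differential_flags(c(5, 6, 7, 8), c(9, 10, 11))
  expect_true(d$flag_a)
  d2 <- differential_flags(c(1, 3, 5, 7), c(2, 4, 6))
  expect_false(d2$flag_a)
  # boundary of the 50% relative mean difference (vs the smaller mean)
  expect_false(differential_flags(c(10, 10), c(14, 14))$flag_b)
  expect_true(differential_flags(c(10, 10), c(15, 15))$flag_b)
  # nonpositive mean degenerates the denominator
  d3 <- differential_flags(c(0, 0), c(1, 2))
  expect_true(d3$indeterminate)
  expect_true(is.na(d3$flag_b))
})

test_that("pattern classification follows the A/B requirement lists", {
  p <- classify_pattern(c(1, 1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  expect_true(p$A1)
  # grand mean 1.9: LN4K1 (3) sits above it, but KLN205 (2) does not sit
  # strictly below, so the stricter grand-mean sub-pattern fails
  expect_false(p$A2)
  expect_false(p$B1 || p$B2)
  p2 <- classify_pattern(c(1, 1, 1, 1), c(1.5, 1.5, 1.5), c(3, 3, 3))
  expect_true(p2$A2)  # grand mean 1.75: KLN and MBEC below, LN4K1 above
  pm <- classify_pattern(c(3, 3, 3, 3), c(2, 2, 2), c(1, 1, 1))
  expect_true(pm$B1)
  expect_false(pm$B2)  # mirror of the A-2 grand-mean failure above
  expect_false(pm$A1 || pm$A2)
  # broken MBEC/KLN separation kills A-1 but leaves A-2 to the grand mean
  pb <- classify_pattern(c(1, 5, 1, 1), c(2, 2, 2), c(3, 3, 3))
  expect_false(pb$A1)
  expect_equal(pb$A2, all(c(3, 3, 3) > 2) && all(c(2, 2, 2) < 2))
  # negation swaps the A and B families exactly
  withr::local_seed(2)
  for (i in 1:50) {
    m <- stats::rnorm(4); k <- stats::rnorm(3); l <- stats::rnorm(3)
    a <- classify_pattern(m, k, l)
    b <- classify_pattern(-m, -k, -l)
    expect_equal(a$A1, b$B1); expect_equal(a$A2, b$B2)
    expect_equal(a$B1, b$A1); expect_equal(a$B2, b$A2)
    expect_false((a$A1 || a$A2) && (a$B1 || a$B2))
  }
})

test_that("planted gradient genes are selected, nulls mostly are not", {
  ma <- generate_mouse_arrays(n_genes = 1000, n_planted_A = 50,
                              n_planted_B = 50, effect = 6, seed = 3)
  sel <- select_pattern_genes(ma$expr)
  expect_true(all(sel$selected[ma$truth == "A"]))
  expect_true(all(sel$selected[ma$truth == "B"]))
  expect_true(all(sel$pattern_A[ma$truth == "A"]))
  expect_true(all(sel$pattern_B[ma$truth == "B"]))
  # false positives bounded: complete separation alone has p = 1/35 per
  # comparison; the joint criteria keep the null rate well below that
  fp <- mean(sel$selected[ma$truth == "null"])
  expect_lt(fp, 2 * separation_p(4, 3))
  # an all-constant matrix selects nothing
  flat <- make_expr(matrix(5, 20, 10))
  expect_equal(sum(select_pattern_genes(flat)$selected), 0)
  expect_error(select_pattern_genes(make_expr(matrix(1, 5, 8))),
               "design expects")
})

test_that("selection is invariant to gene and replicate order", {
  ma <- generate_mouse_arrays(n_genes = 120, seed = 4)
  sel <- select_pattern_genes(ma$expr)
  perm_g <- sample.int(120)
  # permute genes; permute replicates inside each condition block
  cols <- c(1, 2, 2 + c(sample(1:4), 4 + sample(1:3), 7 + sample(1:3)))
  sel_p <- select_pattern_genes(ma$expr[perm_g, cols])
  expect_equal(sel_p$selected, sel$selected[perm_g])
})

test_that("cross-species selection keeps planted concordant genes", {
  withr::local_seed(5)
  n_c <- 20; n_s <- 20
  labels <- rep(c("Classical", "Secretory"), c(n_c, n_s))
  # concordant genes: strong Classical/Secretory shift; decoys: none
  conc <- t(vapply(1:5, function(i)
    c(stats::rgamma(n_c, 20, 2), stats::rgamma(n_s, 2, 2) + 12),
    numeric(40)))
  decoy <- matrix(stats::rgamma(5 * 40, 8, 1), 5)
  human <- make_expr(rbind(conc, decoy),
                     symbols = c(paste0("HC", 1:5), paste0("HD", 1:5)))
  orthomap <- tibble::tibble(
    mouse_symbol = paste0("Mm", 1:10),
    human_symbol = c(paste0("HC", 1:5), paste0("HD", 1:5)))
  res <- cross_species_select(paste0("Mm", 1:10), human, labels, orthomap,
                              fdr_cut = 0.001)
  expect_setequal(res$table$symbol[res$table$kept], paste0("HC", 1:5))
  expect_setequal(res$down, paste0("HC", 1:5))  # Secretory-high: ratio < 1
  expect_length(res$up, 0)
  # empty ortholog map yields empty lists
  empty <- cross_species_select(
    "Mm1", human, labels,
    tibble::tibble(mouse_symbol = character(0),
                   human_symbol = character(0)))
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)
  expect_error(cross_species_select(
    "Mm1", human, labels,
    tibble::tibble(mouse_symbol = c("Mm1", "Mm1"),
                   human_symbol = c("HC1", "HC1"))), "duplicated")
})
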