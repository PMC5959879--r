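test_that("log-centering maps zeros to missing and centers the rest", {
  x <- make_expr(rbind(c(1, 2, 4), c(0, 8, 8)))
  cm <- log_center(x, "mean")
  expect_equal(unname(cm$values[1, ]), c(-1, 0, 1))
  expect_equal(unname(cm$values[2, ]), c(NA, 0, 0))
  # an all-zero gene survives as an all-missing flagged row
  x0 <- make_expr(rbind(c(1, 2, 4), c(0, 0, 0)))
  cm0 <- log_center(x0, "mean")
  expect_true(cm0$all_missing[2])
  expect_true(all(is.na(cm0$values[2, ])))
})

test_that("each non-missing row re-centers to zero under its statistic", {
  withr::local_seed(4)
  vals <- matrix(stats::rgamma(200, 2, 0.5), 20)
  vals[stats::runif(200) < 0.15] <- 0
  x <- make_expr(vals)
  for (mode in c("mean", "median")) {
    cm <- log_center(x, mode)
    stat <- apply(cm$values, 1, function(v)
      if (mode == "mean") mean(v, na.rm = TRUE) else
        stats::median(v, na.rm = TRUE))
    expect_true(all(abs(stat[!cm$all_missing]) < 1e-9))
  }
  # median mode on odd-length complete rows: exactly one centered zero
  odd <- make_expr(matrix(stats::rgamma(25, 3, 0.3), 5))
  cmo <- log_center(odd, "median")
  expect_true(all(apply(cmo$values, 1, function(v) sum(v == 0)) == 1))
})

test_that("identical rows merge before a sign-flipped row", {
  x <- make_expr(rbind(c(1, 2, 4, 8), c(1, 2, 4, 8), c(8, 4, 2, 1)))
  cm <- log_center(x, "mean")
  ord <- hierarchical_order(cm, "rows")$row_order
  expect_true(abs(diff(match(1:2, ord))) == 1)  # the identical pair adjacent
})

naive_average_linkage <- function(d) {
  # O(n^3) agglomeration oracle; returns the list of merged cluster sets
  clusters <- as.list(seq_len(nrow(d)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

hclust_cluster_sets <- function(hc) {
  n <- nrow(hc$merge) + 1
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    members <- function(v) if (v < 0) -v else sets[[v]]
    sets[[k]] <- sort(c(members(hc$merge[k, 1]), members(hc$merge[k, 2])))
  }
  sets
}

test_that("ordering agrees with a brute-force average-linkage oracle", {
  withr::local_seed(6)
  vals <- matrix(stats::rgamma(6 * 8, 2, 0.4), 6)
  x <- make_expr(vals)
  cm <- log_center(x, "mean")
  # reproduce the engine's distance, then compare merge structures
  v <- cm$values
  d <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    if (i != j)
      d[i, j] <- 1 - sum(v[i, ] * v[j, ]) /
        sqrt(sum(v[i, ]^2) * sum(v[j, ]^2))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  expect_identical(hclust_cluster_sets(hc), naive_average_linkage(d))
  # and the package's leaf order comes from that same hierarchy
  ord <- hierarchical_order(cm, "rows")$row_order
  expect_identical(sort(ord), 1:6)
  expect_identical(ord, hc$order)
})

test_that("no-overlap rows are placed last with a warning", {
  vals <- rbind(c(1, 2, 0, 0), c(2, 4, 0, 0), c(0, 0, 3, 9))
  vals2 <- rbind(vals, c(1, 1, 1, 1))
  cm <- log_center(make_expr(vals2), "mean")
  cm$values[3, ] <- c(NA, NA, NA, 0.5)
  cm$values[1:2, 4] <- NA
  cm$values[4, ] <- c(0.1, -0.1, 0.2, NA)
  expect_warning(ord <- hierarchical_order(cm, "rows")$row_order,
                 "placed last")
  expect_equal(ord[4], 3)
})

test_that("city-block dissimilarity matches brute force and metric axioms", {
  withr::local_seed(8)
  vals <- matrix(stats::rgamma(10 * 13, 3, 0.4), 10)
  labels <- rep(c("Classical", "Basal", "Primitive", "Secretory"),
                c(4, 3, 3, 3))
  x <- make_expr(vals)
  gd <- genomic_dissimilarity(x, labels)
  # naive per-gene summation oracle
  for (a in colnames(gd$distances)) {
    for (b in colnames(gd$distances)) {
      ma <- rowMeans(vals[, labels == a, drop = FALSE])
      mb <- rowMeans(vals[, labels == b, drop = FALSE])
      expect_equal(gd$distances[a, b], sum(abs(ma - mb)))
    }
  }
  d <- gd$distances
  expect_true(all(diag(d) == 0))
  expect_identical(d, t(d))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  # identical mean vectors give distance zero
  x2 <- make_expr(cbind(vals[, 1:4], vals[, 1:4], vals[, 1:3],
                        vals[, c(5, 6, 7)]))
  gd2 <- genomic_dissimilarity(
    x2, rep(c("Classical", "Basal", "Primitive", "Secretory"),
            c(4, 4, 3, 3)))
  expect_equal(gd2$distances["Classical", "Basal"], 0)
  expect_error(genomic_dissimilarity(x, rep("Classical", 13)), "missing")
})

make_split_cm <- function(delta_signs, labels, flip_block = 4) {
  # build a clustered_matrix whose per-gene delta(CB, PS) sign is planted:
  # negative rows have PS above the gene mean, positive rows have CB above
  n_g <- length(delta_signs)
  cb <- labels %in% c("Classical", "Basal")
  vals <- matrix(1, n_g, length(labels))
  for (i in seq_len(n_g)) {
    if (delta_signs[i] < 0) vals[i, !cb] <- 4 else vals[i, cb] <- 4
  }
  cm <- log_center(make_expr(vals), "mean")
  cm
}

test_that("heat-map split lands on a planted clean sign flip", {
  labels <- rep(c("Classical", "Basal", "Primitive", "Secretory"), each = 5)
  k <- 12
  signs <- c(rep(-1, k - 1), rep(1, 30 - k + 1))
  cm <- make_split_cm(signs, labels)
  sp <- heatmap_split(cm, labels, tolerance = 3)
  expect_true(sp$found)
  expect_equal(sp$split, k)
  expect_equal(sp$upper, 1:k)
  expect_equal(sort(c(sp$upper, sp$lower)), 1:30)
})

test_that("a violation run longer than the tolerance moves the split", {
  labels <- rep(c("Classical", "Basal", "Primitive", "Secretory"), each = 5)
  signs <- c(rep(-1, 9), rep(1, 4), rep(-1, 7), rep(1, 10))
  cm <- make_split_cm(signs, labels)
  # tolerance 3: the 4-long positive run at 10..13 ends the prefix at 9
  sp3 <- heatmap_split(cm, labels, tolerance = 3)
  expect_equal(sp3$split, 10)
  # tolerance 4 rides through the run; the prefix extends to position 20
  sp4 <- heatmap_split(cm, labels, tolerance = 4)
  expect_equal(sp4$split, 21)
  # a window with no sign change yields a flagged no-split result
  sp_none <- heatmap_split(cm, labels, window = 21:30)
  expect_false(sp_none$found)
  expect_true(is.na(sp_none$split))
  expect_error(heatmap_split(cm, labels, window = 25:40), "out of bounds")
})

test_that("splitting-point detection matches its definition and an oracle", {
  expect_equal(splitting_point(c(1, 1, 1, -1, -1, -1, -1, -1, -1)), 3)
  expect_true(is.na(splitting_point(c(1, -1, 1, 1, 1, 1, 1, 1))))
  expect_error(splitting_point(c(1, -1, 1)), "shorter than 7")

  oracle <- function(s, persist = 5) {
    sg <- sign(s)
    base <- sg[which(sg != 0)[1]]
    for (i in seq_len(length(s) - 1)) {
      if (sg[i] == base && sg[i + 1] == -base &&
          i + 1 + persist <= length(s) &&
          all(sg[(i + 1):(i + 1 + persist)] == -base)) return(i)
    }
    NA_integer_
  }
  withr::local_seed(10)
  for (rep in 1:200) {
    s <- stats::rnorm(sample(7:100, 1))
    expect_identical(splitting_point(s), oracle(s))
  }
})

test_that("gradient fractions recover planted monotone structure", {
  labels <- rep(c("Classical", "Basal", "Primitive", "Secretory"), each = 6)
  # planted hyper-expression fractions: per upper gene, (1,2,4,5) of the 6
  # samples of C,B,P,S sit above the gene mean (strictly increasing); the
  # lower genes carry the mirrored pattern
  above <- function(k) c(rep(2, k), rep(0.5, 6 - k))  # log2 = +1 / -1
  up_row <- unlist(lapply(c(1, 2, 4, 5), above))
  dn_row <- unlist(lapply(c(5, 4, 2, 1), above))
  cm <- log_center(make_expr(rbind(
    matrix(rep(up_row, each = 10), 10, 24),
    matrix(rep(dn_row, each = 10), 10, 24))), "mean")
  gf <- gradient_fractions(cm, labels, 10)
  upr <- as.numeric(gf[gf$half == "upper",
                       c("Classical", "Basal", "Primitive", "Secretory")])
  expect_true(all(diff(upr) > 0))
  expect_true(gf$increasing[gf$half == "upper"])
  expect_true(gf$decreasing[gf$half == "lower"])
  # identical subtype distributions: fractions ~ 0.5, no monotone flags
  withr::local_seed(12)
  flat <- log_center(make_expr(matrix(stats::rgamma(50 * 24, 3, 1), 50)),
                     "mean")
  gflat <- gradient_fractions(flat, labels, 25)
  frs <- as.matrix(gflat[, c("Classical", "Basal", "Primitive", "Secretory")])
  expect_true(all(abs(frs - 0.5) < 0.15))
  expect_false(any(gflat$increasing))
  expect_error(gradient_fractions(cm, labels, 25), "invalid split")
})
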