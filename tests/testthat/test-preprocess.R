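test_that("knee selection recovers planted mixtures and degenerate shapes", {
  sel <- vapply(1:10, function(s)
    knee_select(simulate_barcode_mixture(500, 50000, seed = s)$totals),
    integer(1))
  expect_true(all(sel >= 400 & sel <= 600))
  expect_identical(knee_select(c(rep(1000, 10), rep(1, 90))), 10L)
  m <- simulate_barcode_mixture(10, 0, seed = 1)
  expect_identical(knee_select(m$totals), 10L)
  expect_error(knee_select(c(1, 5, 2)), "decreasing")
  expect_error(knee_select(c(5, 3)), "at least 3")
  ## scale invariance
  tot <- simulate_barcode_mixture(500, 50000, seed = 2)$totals
  expect_identical(knee_select(tot), knee_select(tot * 7))
})

test_that("QC thresholds read literally at their boundaries", {
  n_genes <- 1100
  mito <- c(TRUE, rep(FALSE, n_genes - 1))    # gene 1 is mitochondrial
  cell <- function(...) { v <- numeric(n_genes); vals <- list(...)
    v[seq_along(vals[[1]])] <- vals[[1]]; v }
  cts <- cbind(
    cell(c(0, rep(1, 99))),                   # 99 detected genes, no mito
    cell(c(0, rep(1, 100))),                  # 100 detected genes
    cell(c(15, rep(1, 85))),                  # mito_frac 15/100 = 0.15
    cell(c(149, rep(1, 851))))                # mito_frac 149/1000 = 0.149
  r <- qc_filter(cts, mito, min_genes = 100)
  expect_false(r$keep[1])                     # "at least 100" is >=: 99 fails
  expect_true(r$keep[2])
  r2 <- qc_filter(cts, mito, min_genes = 50)
  expect_false(r2$keep[3])                    # "less than 15%" is strict
  expect_true(r2$keep[4])
  ## idempotence
  kept <- cts[, r$keep, drop = FALSE]
  expect_true(all(qc_filter(kept, mito, min_genes = 100)$keep))
  ## max_genes is a strict upper bound
  r3 <- qc_filter(cts, mito, min_genes = 50, max_genes = 100)
  expect_identical(r3$keep[1:2], c(TRUE, FALSE))
  ## no mito flags: warning, criterion skipped
  expect_warning(r4 <- qc_filter(cts, rep(FALSE, n_genes), min_genes = 50),
                 "skipped")
  expect_true(all(r4$keep))
})

test_that("normalization matches hand computation and conserves depth", {
  cts <- matrix(c(2, 0, 2), 3, 1)
  e <- normalize_log(cts, scale_factor = 100)
  expect_equal(as.numeric(e), c(log1p(50), 0, log1p(50)))
  set.seed(1)
  cts2 <- matrix(rpois(200, 3) + 1, 20, 10)
  e2 <- normalize_log(cts2, scale_factor = 1e4)
  expect_equal(unname(Matrix::colSums(expm1(e2))), rep(1e4, 10))
  ## identical cells give identical columns; zero-depth is an error
  cts3 <- cbind(c(1, 2, 3), c(1, 2, 3))
  e3 <- normalize_log(cts3, 100)
  expect_equal(e3[, 1], e3[, 2])
  expect_error(normalize_log(cbind(c(1, 1), c(0, 0))), "zero total")
  ## constant covariate leaves values unchanged
  e4 <- normalize_log(cts2, 1e4, regress_covariates = data.frame(x = rep(2, 10)))
  expect_equal(as.matrix(e4), as.matrix(e2), tolerance = 1e-12)
})

test_that("HVG selection finds planted bimodal genes deterministically", {
  set.seed(9)
  n_cells <- 200
  flat <- matrix(runif(1950 * n_cells, 0.9, 1.1), 1950)
  bim <- matrix(rep(c(0.1, 3), each = n_cells / 2), 50, n_cells, byrow = TRUE)
  expr <- rbind(bim, flat)
  top <- select_hvg(expr, 50)
  expect_gte(sum(top <= 50), 45)
  expect_identical(top, select_hvg(expr, 50))
  expect_identical(select_hvg(expr, nrow(expr)), seq_len(nrow(expr)))
  expect_error(select_hvg(expr * 0, 10), "expressed")
})

test_that("PCA has fixed signs, correct rank behavior, and separates groups", {
  set.seed(2)
  base <- matrix(rnorm(6 * 50), 6, 50)
  X <- rbind(base[1, ] + 2 * base[2, ], base[1, ] - base[2, ],
             3 * base[2, ], base[1, ], 0.5 * base[1, ] + base[2, ],
             base[2, ] - base[1, ])          # rank 2, genes x cells
  p <- pca_embed(X, 4)
  expect_lt(sum(p$var_explained[3:4]), 1e-10)
  ## rotation invariance of explained variance
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  p2 <- pca_embed(Q %*% X, 4)
  expect_equal(p$var_explained, p2$var_explained, tolerance = 1e-8)
  ## two populations: PC1 point-biserial
  g <- rep(0:1, each = 40)
  expr <- matrix(rnorm(30 * 80, sd = 0.2), 30, 80) +
    outer(rnorm(30), g * 3)
  s <- pca_embed(expr, 2)$scores
  expect_gt(abs(cor(s[, 1], g)), 0.9)
  expect_error(pca_embed(X, 10), "n_pcs")
})

test_that("significant component count is 0 on noise and finds planted signal", {
  set.seed(1)
  noise <- matrix(rnorm(200 * 300), 200, 300)
  zeros <- vapply(1:5, function(s)
    significant_pcs(noise, n_pcs = 5, seed = s), integer(1))
  expect_gte(sum(zeros == 0L), 4)
  sig <- matrix(0, 200, 300)
  for (j in 1:3) sig[(j * 20):(j * 20 + 10), ] <- outer(rep(1, 11), rnorm(300)) * 3
  expect_identical(significant_pcs(noise + sig, n_pcs = 5, seed = 1), 3L)
  expect_identical(significant_pcs(noise, n_pcs = 5, alpha = 1), 5L)
  expect_error(significant_pcs(noise, n_perm = 5), "at least 20")
})

test_that("graph clustering recovers separated blobs and is deterministic", {
  b <- make_blobs()
  cl <- cluster_graph(b$coords, k_neighbors = 15, resolution = 0.1, seed = 1)
  tab <- table(cl, b$labels)
  expect_identical(length(unique(cl)), 3L)
  expect_true(all(rowSums(tab > 0) == 1))      # ARI = 1 up to relabeling
  expect_identical(cl, cluster_graph(b$coords, 15, 0.1, seed = 1))
  one <- matrix(rnorm(400), 200, 2)
  expect_identical(length(unique(cluster_graph(one, 15, 0.05, 1))), 1L)
  expect_error(cluster_graph(one, 300, 1, 1), "smaller")
})

test_that("2D embedding separates blobs, is deterministic, keeps duplicates", {
  b <- make_blobs()
  e <- embed_2d(b$coords, seed = 1)
  cent <- apply(e, 2, function(v) tapply(v, b$labels, mean))
  spread <- mean(vapply(1:3, function(k)
    mean(sqrt(rowSums(sweep(e[b$labels == k, ], 2, cent[k, ])^2))), numeric(1)))
  d12 <- sqrt(sum((cent[1, ] - cent[2, ])^2))
  expect_gt(d12, 5 * spread)
  expect_identical(e, embed_2d(b$coords, seed = 99))
  dup <- rbind(b$coords, b$coords[1, , drop = FALSE])
  e2 <- embed_2d(dup, seed = 1)
  expect_lt(sqrt(sum((e2[1, ] - e2[nrow(e2), ])^2)),
            1e-6 * max(apply(e2, 2, function(v) diff(range(v)))))
  expect_error(embed_2d(matrix(rnorm(10), 5, 2)), "at least 10")
})

test_that("label merging collapses the requested clusters only", {
  lab <- c("ac1", "ac2", "duct", "ac1")
  out <- merge_labels(lab, list(acinar = c("ac1", "ac2")))
  expect_identical(out, c("acinar", "acinar", "duct", "acinar"))
})
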