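test_that("pseudobulk pooling sums exactly and ignores cell order", {
  cts <- cbind(c(1, 2), c(0, 3), c(5, 1))
  rownames(cts) <- c("g1", "g2"); colnames(cts) <- paste0("c", 1:3)
  md <- data.frame(sample = c("s1", "s1", "s2"), cluster = c("k", "k", "k"))
  pb <- aggregate_pseudobulk(cts, md, "cluster")
  expect_equal(unname(pb$counts[, "s1||k"]), c(1, 5))
  expect_equal(sum(pb$counts), sum(cts))
  expect_equal(pb$coldata$n_cells, c(2L, 1L))
  perm <- c(3, 1, 2)
  pb2 <- aggregate_pseudobulk(cts[, perm], md[perm, ], "cluster")
  expect_equal(pb$counts, pb2$counts[, colnames(pb$counts)])
})

test_that("size factors follow median-of-ratios with total-count fallback", {
  a <- c(10, 20, 30, 40)
  expect_equal(size_factors(cbind(a, a)), c(1, 1))
  sf <- size_factors(cbind(a, 2 * a))
  expect_equal(sf[2] / sf[1], 2)
  expect_equal(exp(mean(log(sf))), 1)
  expect_equal(size_factors(cbind(a, 2 * a) * 5), sf)
  ## no all-nonzero gene: fallback
  expect_message(sf2 <- size_factors(cbind(c(0, 5), c(5, 0))), "total-count")
  expect_equal(sf2, c(1, 1))
})

test_that("expression fraction filter is inclusive at its bound", {
  cts <- matrix(0, 3, 100)
  cts[1, 1:5] <- 1        # 5%
  cts[2, 1:4] <- 1        # 4%
  cts[3, ] <- 1
  keep <- expression_fraction_filter(cts, 1:100, 0.05)
  expect_identical(keep, c(TRUE, FALSE, TRUE))
  expect_false(expression_fraction_filter(cts, 1:100, 1)[1])
  expect_error(expression_fraction_filter(cts, integer(0)), "empty")
})

test_that("NB Wald excludes all-zero genes and reports coherent q-values", {
  pb <- make_pseudobulk(21, n_genes = 60, lfc2_genes = 1:10)
  pb$counts[60, ] <- 0
  de <- nb_wald_test(pb, "genotype")
  expect_identical(de$status[60], "excluded")
  expect_true(is.na(de$p[60]))
  tested <- !is.na(de$p)
  expect_true(all(de$q[tested] >= de$p[tested]))
  o <- order(de$p[tested])
  expect_true(!is.unsorted(de$q[tested][o]))
  ## BH reproduces the step-up procedure on the first 10 tested p-values
  p10 <- de$p[tested][1:10]
  m <- length(p10); o10 <- order(p10)
  q_oracle <- numeric(m); prev <- 1
  for (i in m:1) {
    prev <- min(prev, p10[o10[i]] * m / i)
    q_oracle[o10[i]] <- prev
  }
  expect_equal(p.adjust(p10, "BH"), q_oracle, tolerance = 1e-12)
})

test_that("Wald and LRT agree on large two-group designs", {
  pb <- make_pseudobulk(31, n_genes = 150, lfc2_genes = 1:50)
  de_w <- nb_wald_test(pb, "genotype")
  cd <- pb$coldata; cd$group <- cd$genotype
  pb2 <- structure(list(counts = pb$counts, coldata = cd),
                   class = "pseudobulk")
  de_l <- nb_lrt_test(pb2, "group")
  ok <- !is.na(de_w$p) & !is.na(de_l$p)
  expect_gt(cor(-log10(de_w$p[ok]), -log10(de_l$p[ok])), 0.95)
})

test_that("LRT ranks a single-group gene first and is flat on identical columns", {
  pb <- make_pseudobulk(41, n_genes = 300)
  cd <- pb$coldata; cd$group <- rep(c("a", "b", "c", "d"), each = 3)
  cts <- pb$counts
  set.seed(8)
  cts[1, cd$group == "b"] <- rnbinom(3, mu = 10 * mean(cts[1, ]), size = 20)
  cts[2, ] <- rep(100L, 12)                    # identical columns
  pb2 <- structure(list(counts = cts, coldata = cd), class = "pseudobulk")
  lr <- nb_lrt_test(pb2, "group", sf = rep(1, 12))
  expect_identical(which.min(lr$q), 1L)
  expect_lt(lr$stat[2], 0.5)
})

test_that("composition test flags separation and respects the sample floor", {
  d <- make_composition(5)
  comp <- d$comp
  ## cluster present in only one sample: separation flag on genotype
  comp[, "target"] <- 0L
  comp[1, "target"] <- 40L
  r <- composition_test(comp, d$design, "target")
  expect_true(any(r$separation))
  expect_true(all(is.na(r$p[r$separation])))
  des2 <- d$design; des2$sex <- c("F", rep("M", 25))
  expect_error(composition_test(d$comp, des2, "target"), "fewer than 3")
})

test_that("pooled-vs-bulk correlation applies the strict abundance filter", {
  set.seed(6)
  pooled <- matrix(rpois(5000 * 2, 20), 5000, 2,
                   dimnames = list(sprintf("g%04d", 1:5000), c("p1", "p2")))
  bulk <- sweep(pooled, 2, colSums(pooled), "/") * 1e6
  R <- pooled_vs_bulk_correlation(pooled, bulk)
  expect_equal(unname(diag(R)), c(1, 1), tolerance = 1e-12)
  ## independent profiles decorrelate
  bulk2 <- matrix(rexp(5000) * 200, 5000, 1,
                  dimnames = list(rownames(pooled), "b"))
  R2 <- pooled_vs_bulk_correlation(pooled, bulk2)
  expect_lt(max(abs(R2)), 0.1)
  ## exact 1e-4 is excluded (strict >)
  pooled3 <- matrix(c(1e4, 1:9), 10, 1,
                    dimnames = list(paste0("g", 1:10), "p"))
  bulk3 <- matrix(c(1e-4, 100 * (9:1)), 10, 1,
                  dimnames = list(paste0("g", 1:10), "b"))
  expect_warning(R3 <- pooled_vs_bulk_correlation(pooled3, bulk3), "fewer than 50")
  expect_equal(attr(R3, "n_genes"), 9L)
})
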