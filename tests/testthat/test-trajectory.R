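## noisy 1D arc embedded in 5 dimensions
make_arc <- function(n = 400, noise = 0.05, seed = 1) {
  set.seed(seed)
  t <- sort(runif(n))
  X <- rbind(cos(pi * t), sin(pi * t), t, t^2, sqrt(t)) +
    matrix(rnorm(5 * n, sd = noise), 5, n)
  list(expr = X, t = t)
}

test_that("diffusion map is stochastic, ordered, and rejects disconnection", {
  arc <- make_arc()
  dm <- diffusion_map(arc$expr, n_comps = 5, k_kernel = 10,
                      distance = "euclidean")
  expect_lt(abs(dm$trivial_eigenvalue - 1), 1e-8)
  expect_true(all(diff(dm$eigenvalues) <= 1e-12))
  expect_true(all(dm$eigenvalues <= 1))
  expect_gte(abs(cor(dm$coords[, 1], arc$t, method = "spearman")), 0.95)
  two <- cbind(matrix(rnorm(100, sd = 0.1), 2, 50),
               matrix(rnorm(100, 50, sd = 0.1), 2, 50))
  expect_error(diffusion_map(two, n_comps = 3, k_kernel = 10,
                             distance = "euclidean"),
               "component sizes")
  expect_error(diffusion_map(arc$expr[, 1:5], n_comps = 5), "cells")
})

test_that("pseudotime is zero at the root and recovers the arc ordering", {
  arc <- make_arc()
  dm <- diffusion_map(arc$expr, n_comps = 5, k_kernel = 10,
                      distance = "euclidean")
  dpt <- diffusion_pseudotime(dm, root_cell = which.min(arc$t))
  expect_identical(dpt$pseudotime[which.min(arc$t)], 0)
  expect_true(all(dpt$pseudotime >= 0 & dpt$pseudotime <= 1))
  expect_gte(abs(cor(dpt$pseudotime, arc$t, method = "spearman")), 0.9)
  ## root cluster designation gives the cluster the lowest median pseudotime
  lab <- cut(arc$t, c(0, 0.3, 0.7, 1), labels = c("start", "mid", "end"))
  dpt2 <- diffusion_pseudotime(dm, root_cluster = "start", labels = lab)
  med <- tapply(dpt2$pseudotime, lab, median)
  expect_identical(names(which.min(med)), "start")
  expect_error(diffusion_pseudotime(dm), "root")
})

test_that("trajectory recovery on simulated tumors meets ground truth", {
  s <- sim_tumor(101)
  expr <- normalize_log(s$counts)
  hvg <- select_hvg(expr, 500)
  dm <- diffusion_map(expr[hvg, ], n_comps = 10, k_kernel = 15)
  dpt <- diffusion_pseudotime(dm, root_cluster = "basal_tumor",
                              labels = s$truth$population)
  expect_gte(abs(cor(dpt$pseudotime, s$truth$t, method = "spearman")), 0.8)
  med <- tapply(dpt$pseudotime, s$truth$population, median)
  expect_true(!is.unsorted(med[c("basal_tumor", "CSC1", "CSC2", "luminal_Clu")]))
})

test_that("trajectory curve interpolates noiseless input and denoises", {
  set.seed(2)
  t <- sort(runif(500))
  coords <- cbind(2 * t - 1, 0.5 - t)          # noiseless monotone
  cv <- fit_trajectory_curve(coords, t, span = 0.3)
  truth <- cbind(2 * cv$pseudotime - 1, 0.5 - cv$pseudotime)
  expect_lt(sqrt(mean((as.matrix(cv[, -1]) - truth)^2)), 1e-6)
  ## noisy coords: curve closer to truth than the noise floor
  sigma <- 0.2
  noisy <- coords + matrix(rnorm(1000, sd = sigma), 500, 2)
  cv2 <- fit_trajectory_curve(noisy, t, span = 0.5)
  truth2 <- cbind(2 * cv2$pseudotime - 1, 0.5 - cv2$pseudotime)
  expect_lt(sqrt(mean((as.matrix(cv2[, -1]) - truth2)^2)), sigma / 2)
  cv3 <- fit_trajectory_curve(coords, t, n_grid = 1)
  expect_identical(nrow(cv3), 1L)
  expect_equal(cv3$pseudotime, median(t))
})

test_that("LOESS smoothing recovers planted programs with shrinking bands", {
  set.seed(3)
  t <- runif(800)
  ## identity on noiseless input
  sm0 <- smooth_over_pseudotime(t, t, span = 0.5)
  expect_lt(max(abs(sm0$fit - sm0$pseudotime)), 1e-6)
  ## planted Gaussian bump: peak located within 0.05
  bump <- exp(-(t - 0.45)^2 / (2 * 0.07^2))
  y <- bump + rnorm(800, sd = 0.3)
  sm <- smooth_over_pseudotime(y, t, span = 0.3)
  expect_lt(abs(sm$pseudotime[which.max(sm$fit)] - 0.45), 0.05)
  ## bands shrink with n
  mean_se <- function(n, seed) {
    set.seed(seed)
    tt <- runif(n); yy <- tt + rnorm(n, sd = 0.3)
    mean(smooth_over_pseudotime(yy, tt)$se)
  }
  expect_lt(mean(vapply(1:5, function(s) mean_se(800, s), numeric(1))),
            mean(vapply(1:5, function(s) mean_se(100, s), numeric(1))))
  expect_error(smooth_over_pseudotime(rnorm(50), rep(0.5, 50)), "constant")
  expect_error(smooth_over_pseudotime(rnorm(5), runif(5)), "at least 10")
})

test_that("per-sample trajectories reproduce the global ordering", {
  s <- sim_tumor(103)
  expr <- normalize_log(s$counts)
  hvg <- select_hvg(expr, 500)
  dm <- diffusion_map(expr[hvg, ], n_comps = 10, k_kernel = 15)
  dpt <- diffusion_pseudotime(dm, root_cluster = "basal_tumor",
                              labels = s$truth$population)
  rep_tab <- per_sample_reproducibility(expr[hvg, ], s$meta$sample,
                                        dpt$pseudotime)
  expect_gte(median(rep_tab$rho, na.rm = TRUE), 0.7)
  ## strictly-more-than filter: a 10-cell sample is excluded
  small <- c(rep("s1", 10), rep("s2", 40))
  rt <- per_sample_reproducibility(expr[hvg, 1:50], small,
                                   dpt$pseudotime[1:50])
  expect_false("s1" %in% rt$sample)
})

test_that("stage-shift test detects the planted shift and filters small samples", {
  s <- sim_tumor(105)
  expr <- normalize_log(s$counts)
  hvg <- select_hvg(expr, 500)
  dm <- diffusion_map(expr[hvg, ], n_comps = 10, k_kernel = 15)
  dpt <- diffusion_pseudotime(dm, root_cluster = "basal_tumor",
                              labels = s$truth$population)
  md <- s$meta; md$genotype <- "double_mutant"
  r <- stage_shift_test(dpt$pseudotime, md)
  expect_gt(r$slope, 0)                        # P90 sits later
  expect_lt(r$p, 0.01)
  ## a sample with 4 trajectory cells is excluded
  md2 <- data.frame(sample = c(rep("a", 4), rep("b", 30), rep("c", 30)),
                    stage = c(rep("P40", 34), rep("P90", 30)),
                    genotype = "double_mutant")
  set.seed(1)
  r2 <- stage_shift_test(rbeta(64, 2, 2), md2, min_cells = 5)
  expect_identical(r2$n_samples, 2L)
  expect_identical(r2$n_cells, 60L)
  expect_error(stage_shift_test(runif(34), md2[1:34, ]), "both stages")
})

test_that("neighbor smoothing reduces within-blob variance and keeps constants", {
  set.seed(4)
  coords <- rbind(matrix(rnorm(100), 50, 2), matrix(rnorm(100, 10), 50, 2))
  nn <- knn_graph(coords, 10)
  checker <- rep(c(0, 1), 50)
  expr <- rbind(checker, rep(3, 100))
  sm <- neighbor_smooth(expr, nn)
  expect_lt(var(as.numeric(sm[1, 1:50])), var(checker[1:50]))
  expect_equal(as.numeric(sm[2, ]), rep(3, 100))
  ## zero-column neighbor matrix: identity
  expect_identical(neighbor_smooth(expr, matrix(integer(0), 100, 0)), expr)
})
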