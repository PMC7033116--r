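test_that("kNN graph matches brute force, excludes self, breaks ties by index", {
  nn <- knn_graph(matrix(c(0, 1, 2, 10)), k = 2)
  expect_identical(sort(nn[1, ]), c(2L, 3L))
  ## k = n-1: every other cell
  nn2 <- knn_graph(matrix(c(0, 1, 2, 10)), k = 3)
  for (i in 1:4) expect_identical(sort(nn2[i, ]), setdiff(1:4, i))
  ## duplicated points: deterministic tie-break by index
  nn3 <- knn_graph(matrix(c(0, 0, 0, 0)), k = 2)
  expect_identical(nn3[1, ], c(2L, 3L))
  expect_identical(nn3[4, ], c(1L, 2L))
  expect_error(knn_graph(matrix(1:3), k = 3), "smaller")
})

test_that("divergence matches closed forms and its bounds", {
  ## 8 cells, two groups; neighborhoods constructed explicitly
  labels <- rep(c("A", "B"), each = 4)
  nbrs <- rbind(c(2, 3), c(1, 3), c(1, 2), c(5, 6),
                c(4, 6), c(4, 5), c(1, 5), c(7, 5))
  m <- mixing_divergence(nbrs, labels)
  expect_equal(unname(m$q0), c(0.5, 0.5))
  ## pure-A neighborhood with q0 = (.5,.5): D = ln 2
  expect_equal(m$D[1], log(2))
  ## mixed (0.5, 0.5) neighborhood equals q0: D = 0 exactly
  expect_identical(m$D[7], 0)
  ## closed form: q=(0.5,0.5), q0=(0.9,0.1)
  m2 <- mixing_divergence(rbind(c(2, 3)), c("A", "A", "B"),
                          q0 = c(A = 0.9, B = 0.1))
  expect_equal(m2$D[1], 0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1))
  expect_equal(round(m2$D[1], 4), 0.5108)
  ## upper bound attained by a pure neighborhood of the rarest group
  lab3 <- c(rep("A", 9), "B", "B", "B")
  nb3 <- matrix(rep(c(10L, 11L, 12L), each = 12), 12, 3)
  m3 <- mixing_divergence(nb3, lab3)
  expect_equal(max(m3$D), log(1 / unname(m3$q0["B"])))
  expect_true(all(m3$D >= 0 & m3$D <= max(log(1 / m3$q0)) + 1e-12))
  ## permutation invariance under group relabeling
  m4 <- mixing_divergence(nb3, c(rep("zz", 9), "aa", "aa", "aa"))
  expect_equal(sort(m4$D), sort(m3$D))
  expect_error(mixing_divergence(nb3, lab3, q0 = c(A = 1)), "absent")
})

test_that("shuffle null covers iid labels and flags planted separation", {
  set.seed(2)
  coords <- matrix(rnorm(600 * 5), 600)
  nn <- knn_graph(coords, 30)
  inside <- vapply(1:10, function(s) {
    set.seed(100 + s)
    labs <- sample(rep(c("a", "b", "c"), 200))
    sn <- shuffle_null(nn, labs, n_perm = 60, seed = s)
    qs <- quantile(sn$null_means, c(0.025, 0.975))
    sn$observed_mean >= qs[1] && sn$observed_mean <= qs[2]
  }, logical(1))
  expect_gte(sum(inside), 9)
  ## block-separated samples: observed exceeds every permutation
  coords2 <- rbind(matrix(rnorm(300 * 2), 300), matrix(rnorm(300 * 2, 20), 300))
  nn2 <- knn_graph(coords2, 30)
  sn2 <- shuffle_null(nn2, rep(c("s1", "s2"), each = 300), n_perm = 99, seed = 1)
  expect_equal(sn2$p, 1 / 100)
  expect_true(all(sn2$null_means < sn2$observed_mean))
  expect_error(shuffle_null(nn2, rep("a", 600), n_perm = 0), "at least 1")
})

test_that("chain-rule decomposition is exact and separates structure levels", {
  set.seed(3)
  ## replicates exchangeable within separated biological groups
  grp_centers <- c(0, 20, 40)
  coords <- do.call(rbind, lapply(grp_centers, function(ct)
    matrix(rnorm(400 * 3, ct), 400)))
  reps <- unlist(lapply(1:3, function(g)
    sample(rep(paste0("g", g, "_r", 1:2), each = 200))))
  fm <- setNames(rep(paste0("G", 1:3), each = 2),
                 paste0(rep(paste0("g", 1:3), each = 2), "_r", 1:2))
  nn <- knn_graph(coords, 30)
  dec <- decompose_mixing(nn, reps, fm)
  add_err <- max(abs(dec$per_cell$D_total - dec$per_cell$D_between -
                       dec$per_cell$D_within))
  expect_lt(add_err, 1e-12)
  expect_gte(dec$fraction_between, 0.9)
  ## converse: biological groups identical, replicates block-separated
  coords2 <- rbind(matrix(rnorm(200 * 2), 200), matrix(rnorm(200 * 2, 20), 200))
  reps2 <- rep(c("r1", "r2"), each = 200)
  dec2 <- decompose_mixing(knn_graph(coords2, 30), reps2,
                           c(r1 = "G", r2 = "G"))
  expect_lt(dec2$fraction_between, 0.05)
  expect_error(decompose_mixing(nn, reps, fm[-1]), "missing")
})

test_that("mean divergence under iid labels matches the chi-square approximation", {
  set.seed(4)
  coords <- matrix(rnorm(1200 * 5), 1200)
  labs <- sample(rep(paste0("g", 1:4), 300))
  nn <- knn_graph(coords, 30)
  m <- mixing_divergence(nn, labs)
  sn <- shuffle_null(nn, labs, n_perm = 200, seed = 9)
  se <- sd(sn$null_means)
  expect_lt(abs(mean(m$D) - mean(sn$null_means)), 3 * se)
  expect_lt(abs(mean(m$D) - (4 - 1) / (2 * 30)), 3 * se + 0.01)
})
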