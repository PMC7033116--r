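## shared fixtures, built in code

## three well-separated 2D Gaussian blobs with labels
make_blobs <- function(n = 100, centers = list(c(0, 0), c(8, 8), c(16, 0)),
                       sd = 1, seed = 5) {
  set.seed(seed)
  coords <- do.call(rbind, lapply(centers, function(ct)
    cbind(rnorm(n, ct[1], sd), rnorm(n, ct[2], sd))))
  list(coords = coords, labels = rep(seq_along(centers), each = n))
}

## small tumor-only simulation for trajectory tests: 12 samples x ~67 cells
sim_tumor <- function(seed, cells_per_sample = 67) {
  cfg <- sim_config(n_samples_control = 0, n_samples_mutant = 12,
                    cells_per_sample = cells_per_sample,
                    base_tumor_prop = 0.999, genotype_effect = 0, seed = seed)
  d <- simulate_dataset(cfg)
  tum <- which(!is.na(d$truth$population))
  counts <- d$counts[, tum]
  meta <- d$metadata[tum, , drop = FALSE]
  truth <- d$truth[tum, , drop = FALSE]
  qc <- qc_filter(counts, d$genes$mito)
  list(counts = counts[, qc$keep], meta = meta[qc$keep, , drop = FALSE],
       truth = truth[qc$keep, , drop = FALSE], genes = d$genes)
}

## pseudobulk table from NB draws: 6 control vs 6 mutant columns
make_pseudobulk <- function(seed, n_genes = 2000, dispersion = 0.05,
                            lfc2_genes = integer(0), mu_log = log(500)) {
  set.seed(seed)
  ns <- 12
  mu0 <- exp(rnorm(n_genes, mu_log, 1))
  sf <- exp(rnorm(ns, 0, 0.2)); sf <- sf / exp(mean(log(sf)))
  ncells <- round(runif(ns, 50, 200))
  cts <- t(vapply(seq_len(n_genes), function(g)
    rnbinom(ns, mu = mu0[g] * sf, size = 1 / dispersion), numeric(ns)))
  if (length(lfc2_genes))
    cts[lfc2_genes, 7:12] <- t(vapply(lfc2_genes, function(g)
      rnbinom(6, mu = 2 * mu0[g] * sf[7:12], size = 1 / dispersion),
      numeric(6)))
  rownames(cts) <- sprintf("g%04d", seq_len(n_genes))
  structure(list(
    counts = cts,
    coldata = data.frame(sample = paste0("s", 1:ns), group = "all",
                         n_cells = ncells,
                         genotype = rep(c("control", "double_mutant"), each = 6),
                         stringsAsFactors = FALSE)),
    class = "pseudobulk")
}

## samples x 2 composition counts under a sample-level random intercept
make_composition <- function(seed, odds_ratio = 1, base_prop = 0.1,
                             re_sd = 0.3) {
  set.seed(seed)
  ns <- 26
  design <- data.frame(
    genotype = rep(c("control", "double_mutant"), c(12, 14)),
    sex = rep(c("F", "M"), 13),
    stage = rep(c("P40", "P90"), each = 13)[sample(26)],
    stringsAsFactors = FALSE)
  n <- round(runif(ns, 80, 160))
  lo <- qlogis(base_prop) + rnorm(ns, 0, re_sd) +
    log(odds_ratio) * (design$genotype == "double_mutant")
  y <- rbinom(ns, n, plogis(lo))
  list(comp = cbind(target = y, rest = n - y), design = design)
}
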