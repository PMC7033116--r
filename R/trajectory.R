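#' Diffusion-map embedding of cells
#'
#' Builds a Gaussian kernel with per-cell local scale (the distance to each
#' cell's `k_kernel`-th neighbor), applies anisotropic normalization with
#' exponent `alpha` (removing the sampling-density bias at `alpha = 1`),
#' symmetrizes and row-normalizes to a stochastic transition operator, and
#' returns the nontrivial right eigenvectors 2..(n_comps+1) scaled by their
#' eigenvalues as diffusion coordinates. The trivial eigenvalue 1 is
#' verified and dropped. A disconnected kernel graph (at the `k_kernel`
#' neighborhood scale) is an error reporting the component sizes.
#'
#' @param expr genes x cells expression matrix, typically restricted to
#'   highly variable genes.
#' @param n_comps number of diffusion components (default 10).
#' @param k_kernel neighbor index used for the local kernel scale and for
#'   the kernel's neighborhood support (default 15).
#' @param alpha density-normalization exponent (default 1).
#' @param distance `"cosine"` (default; cells scaled to unit norm, robust
#'   to residual depth differences) or `"euclidean"`.
#' @return object of class `diffusion_map`: list with `coords` (cells x
#'   n_comps, columns DC1..), `eigenvalues` (nontrivial, nonincreasing),
#'   `psi` (right eigenvectors incl. the trivial one), `params`.
#' @export
diffusion_map <- function(expr, n_comps = 10L, k_kernel = 15L, alpha = 1,
                          distance = c("cosine", "euclidean")) {
  distance <- match.arg(distance)
  X <- t(.as_dense(expr))                        # cells x features
  n <- nrow(X)
  if (n < n_comps + 2L) stop("need at least n_comps + 2 cells")
  if (k_kernel >= n) stop("k_kernel must be smaller than the number of cells")
  if (distance == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    X <- X / pmax(nrm, 1e-12)
  }
  sq <- rowSums(X^2)
  d2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(X), 0)

  ## kernel support: symmetric k-NN graph; it must be connected
  nn <- .knn_index(X, k_kernel)
  g <- igraph::graph_from_edgelist(
    cbind(rep(seq_len(n), k_kernel), as.vector(nn)), directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop("disconnected kernel graph: component sizes ",
         paste(sort(comp$csize, decreasing = TRUE), collapse = ", "))

  sigma <- sqrt(d2[cbind(seq_len(n), nn[, k_kernel])])
  sigma[sigma <= 0] <- min(sigma[sigma > 0], 1e-8)
  ## Gaussian weights with local scales, truncated to the k-NN support so
  ## the walk is local and the nontrivial spectrum stays close to 1
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- nn[i, ]
    K[i, j] <- exp(-d2[i, j] / (sigma[i] * sigma[j]))
  }
  K <- pmax(K, t(K))
  diag(K) <- 1
  ## anisotropic normalization: remove density to the power alpha
  if (alpha > 0) {
    dd <- rowSums(K)^alpha
    K <- K / outer(dd, dd)
  }
  d1 <- rowSums(K)
  A <- K / outer(sqrt(d1), sqrt(d1))             # symmetric conjugate of P
  A <- (A + t(A)) / 2
  eg <- eigen(A, symmetric = TRUE)
  m <- n_comps + 1L
  lam <- eg$values[seq_len(m)]
  if (abs(lam[1] - 1) > 1e-8)
    stop("leading eigenvalue deviates from 1: ", format(lam[1]))
  psi <- eg$vectors[, seq_len(m), drop = FALSE] / sqrt(d1)
  ## normalize so the trivial eigenvector is the constant 1
  psi <- psi / psi[1, 1]
  ## deterministic signs: largest-magnitude entry positive
  for (j in 2:m) {
    s <- sign(psi[which.max(abs(psi[, j])), j])
    if (s < 0) psi[, j] <- -psi[, j]
  }
  coords <- sweep(psi[, -1, drop = FALSE], 2, lam[-1], "*")
  colnames(coords) <- paste0("DC", seq_len(n_comps))
  structure(list(coords = coords, eigenvalues = lam[-1], psi = psi,
                 trivial_eigenvalue = lam[1],
                 params = list(n_comps = n_comps, k_kernel = k_kernel,
                               alpha = alpha)),
            class = "diffusion_map")
}

#' @export
print.diffusion_map <- function(x, ...) {
  cat("Diffusion map:", nrow(x$coords), "cells,",
      ncol(x$coords), "components\n")
  cat("  eigenvalues:", paste(format(utils::head(x$eigenvalues, 5), digits = 3),
                              collapse = " "), "...\n")
  invisible(x)
}

#' Diffusion pseudotime from a root cell or root cluster
#'
#' Pseudotime of a cell is its diffusion distance to the root,
#' sqrt(sum_i [lambda_i/(1-lambda_i) (psi_i(x) - psi_i(root))]^2) over the
#' retained components, min-max scaled to [0, 1]. With a root cluster, the
#' root cell is that cluster's extreme cell on DC1, picking the extreme
#' that gives the root cluster the lowest median pseudotime (the
#' biology-motivated orientation: the origin population starts the
#' trajectory). Components whose weight lambda/(1-lambda) falls below 1%
#' of the leading retained weight are dropped.
#'
#' @param dmap a [diffusion_map()] object.
#' @param root_cell index of the root cell, or NULL to use `root_cluster`.
#' @param root_cluster cluster name designating the origin population;
#'   requires `labels`.
#' @param labels per-cell cluster labels (needed with `root_cluster`).
#' @return list of class `dpt_result`: `pseudotime` (in [0,1], root = 0),
#'   `root_cell`, `weights`, `n_components_used`.
#' @export
diffusion_pseudotime <- function(dmap, root_cell = NULL, root_cluster = NULL,
                                 labels = NULL) {
  lam <- dmap$eigenvalues
  if (any(lam >= 1)) stop("retained eigenvalue >= 1; operator not contracting")
  w <- lam / (1 - lam)
  keep <- w >= 0.01 * max(w)
  psi <- dmap$psi[, -1, drop = FALSE][, keep, drop = FALSE]
  wk <- w[keep]
  dpt_from <- function(root) {
    d <- sweep(psi, 2, psi[root, ], "-")
    sqrt(rowSums(sweep(d, 2, wk, "*")^2))
  }
  if (is.null(root_cell)) {
    if (is.null(root_cluster) || is.null(labels))
      stop("supply either root_cell or root_cluster together with labels")
    in_cl <- which(labels == root_cluster)
    if (!length(in_cl)) stop("root cluster '", root_cluster, "' has no cells")
    dc1 <- dmap$coords[, 1]
    cand <- unique(c(in_cl[which.min(dc1[in_cl])], in_cl[which.max(dc1[in_cl])]))
    med <- vapply(cand, function(rc) {
      pt <- dpt_from(rc)
      stats::median(pt[in_cl]) / max(pt)
    }, numeric(1))
    root_cell <- cand[which.min(med)]
  }
  pt <- dpt_from(root_cell)
  rng <- range(pt)
  pt <- (pt - rng[1]) / (rng[2] - rng[1])
  structure(list(pseudotime = pt, root_cell = root_cell, weights = wk,
                 n_components_used = sum(keep)),
            class = "dpt_result")
}

#' Smoothed trajectory curve in diffusion space
#'
#' Locally-weighted regression of each diffusion coordinate on pseudotime,
#' evaluated on an even pseudotime grid, giving the ordered curve drawn
#' through the cloud of cells.
#'
#' @param coords cells x components diffusion coordinates.
#' @param pseudotime per-cell pseudotime.
#' @param span LOESS span (default 0.5).
#' @param n_grid number of grid points (default 100); 1 gives the single
#'   fit at the median pseudotime.
#' @return data.frame: pseudotime grid plus one smoothed column per
#'   coordinate, ordered by pseudotime.
#' @export
fit_trajectory_curve <- function(coords, pseudotime, span = 0.5,
                                 n_grid = 100L) {
  coords <- as.matrix(coords)
  grid <- if (n_grid == 1L) stats::median(pseudotime)
          else seq(min(pseudotime), max(pseudotime), length.out = n_grid)
  out <- data.frame(pseudotime = grid)
  for (j in seq_len(ncol(coords))) {
    fit <- tryCatch(
      stats::loess(coords[, j] ~ pseudotime, span = span, degree = 1,
                   family = "gaussian",
                   control = stats::loess.control(surface = "direct")),
      error = function(e)
        stop("LOESS failed (span may be too small for n = ",
             length(pseudotime), "; try span >= ",
             format(10 / length(pseudotime), digits = 2), "): ",
             conditionMessage(e)))
    out[[colnames(coords)[j] %||% paste0("V", j)]] <-
      stats::predict(fit, newdata = data.frame(pseudotime = grid))
  }
  out
}

#' LOESS smoothing of a per-cell quantity over pseudotime
#'
#' First-degree locally weighted regression with tricube weights and a
#' pointwise 95% confidence band from the local standard errors; used for
#' gene expression and module scores (EMT, Wnt, stemness) along the
#' trajectory.
#'
#' @param values per-cell values.
#' @param pseudotime per-cell pseudotime (non-constant; >= 10 cells).
#' @param span LOESS span (default 0.5).
#' @param n_grid grid size (default 100).
#' @return data.frame: pseudotime, fit, se, lower, upper.
#' @export
smooth_over_pseudotime <- function(values, pseudotime, span = 0.5,
                                   n_grid = 100L) {
  if (length(values) < 10L) stop("need at least 10 cells")
  if (diff(range(pseudotime)) == 0) stop("pseudotime is constant")
  fit <- stats::loess(values ~ pseudotime, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(pseudotime), max(pseudotime), length.out = n_grid)
  pr <- stats::predict(fit, newdata = data.frame(pseudotime = grid), se = TRUE)
  data.frame(pseudotime = grid, fit = pr$fit, se = pr$se.fit,
             lower = pr$fit - 1.96 * pr$se.fit,
             upper = pr$fit + 1.96 * pr$se.fit)
}

#' Per-sample reproducibility of the trajectory
#'
#' Re-runs the diffusion map and pseudotime on each sample with more than
#' `min_cells` cells in the relevant subpopulations (strictly more), using
#' the sample's cell of lowest global pseudotime as root, and reports the
#' absolute Spearman correlation with the global pseudotime on the
#' sample's cells.
#'
#' @param expr genes x cells expression matrix (HVG-restricted), aligned
#'   with `sample` and `global_pseudotime`.
#' @param sample per-cell sample labels.
#' @param global_pseudotime per-cell global pseudotime.
#' @param min_cells qualification threshold (default 10; strict).
#' @param n_comps,k_kernel diffusion-map parameters; `k_kernel` is capped
#'   at the sample size minus 2.
#' @return data.frame: sample, n_cells, rho (absolute Spearman; NA when
#'   the per-sample map fails, e.g. disconnected).
#' @export
per_sample_reproducibility <- function(expr, sample, global_pseudotime,
                                       min_cells = 10L, n_comps = 5L,
                                       k_kernel = 15L) {
  tab <- table(sample)
  qual <- names(tab)[tab > min_cells]
  if (!length(qual)) {
    message("no sample qualifies (> ", min_cells, " cells)")
    return(data.frame(sample = character(), n_cells = integer(),
                      rho = numeric()))
  }
  rows <- lapply(qual, function(s) {
    cells <- which(sample == s)
    nc <- length(cells)
    rho <- tryCatch({
      sub <- expr[, cells, drop = FALSE]
      dm <- diffusion_map(sub, n_comps = min(n_comps, nc - 2L),
                          k_kernel = min(k_kernel, nc - 2L))
      root <- which.min(global_pseudotime[cells])
      pt <- diffusion_pseudotime(dm, root_cell = root)$pseudotime
      abs(stats::cor(pt, global_pseudotime[cells], method = "spearman"))
    }, error = function(e) NA_real_)
    data.frame(sample = s, n_cells = nc, rho = rho, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stage-shift test of pseudotime
#'
#' Tests whether cells from the later stage sit further along the
#' trajectory: ordinary least squares of pseudotime on the stage indicator
#' over double-mutant cells from samples with at least `min_cells` cells in
#' the trajectory populations, with standard errors clustered by sample
#' (CR0 sandwich, t reference with n_samples - 1 degrees of freedom).
#'
#' @param pseudotime per-cell pseudotime (trajectory populations only).
#' @param metadata per-cell data.frame with `sample`, `stage` and
#'   optionally `genotype` (non-double-mutant cells are dropped when
#'   present).
#' @param min_cells per-sample retention threshold (default 5, inclusive).
#' @return list of class `stage_shift`: slope (later minus earlier stage),
#'   se, p, n_cells, n_samples.
#' @export
stage_shift_test <- function(pseudotime, metadata, min_cells = 5L) {
  keep <- rep(TRUE, length(pseudotime))
  if ("genotype" %in% names(metadata))
    keep <- metadata$genotype == "double_mutant"
  tab <- table(metadata$sample[keep])
  ok_samples <- names(tab)[tab >= min_cells]
  keep <- keep & metadata$sample %in% ok_samples
  stg <- factor(metadata$stage[keep])
  if (nlevels(stg) < 2L)
    stop("both stages must be represented after the sample filter")
  pt <- pseudotime[keep]
  cl <- factor(metadata$sample[keep])
  fit <- stats::lm(pt ~ stg)
  vc <- sandwich::vcovCL(fit, cluster = cl)
  slope <- stats::coef(fit)[2]
  se <- sqrt(vc[2, 2])
  df <- nlevels(droplevels(cl)) - 1L
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  structure(list(slope = unname(slope), se = unname(se), p = unname(p),
                 n_cells = sum(keep), n_samples = nlevels(droplevels(cl)),
                 stages = levels(stg)),
            class = "stage_shift")
}

#' @export
print.stage_shift <- function(x, ...) {
  cat("Stage shift in pseudotime (", x$stages[2], " - ", x$stages[1], ")\n",
      sep = "")
  cat("  slope:", format(x$slope, digits = 3),
      " p:", format(x$p, digits = 3),
      " (", x$n_cells, "cells,", x$n_samples, "samples )\n")
  invisible(x)
}

#' Neighbor-average expression smoothing
#'
#' Replaces every cell's expression by the mean over the cell and its k
#' nearest neighbors. This is a simple neighborhood-average smoother used
#' before module scoring and heatmap display; it is off by default
#' throughout the pipeline.
#'
#' @param expr genes x cells expression matrix.
#' @param neighbors cells x k neighbor index matrix (from [knn_graph()]);
#'   zero columns give the identity.
#' @return smoothed genes x cells matrix.
#' @export
neighbor_smooth <- function(expr, neighbors) {
  n <- ncol(expr)
  k <- ncol(neighbors)
  if (k == 0L) return(expr)
  W <- Matrix::sparseMatrix(
    i = c(seq_len(n), as.vector(neighbors)),
    j = c(seq_len(n), rep(seq_len(n), k)),
    x = 1 / (k + 1), dims = c(n, n))
  out <- expr %*% W
  dimnames(out) <- dimnames(expr)
  out
}
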