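#' Knee-point selection of real-cell barcodes
#'
#' Finds the cutoff rank on the barcode rank vs. cumulative UMI fraction
#' curve that separates real cells from the ambient tail. The knee is the
#' point of maximum (concave) curvature of the cumulative curve with rank
#' on a log scale, located by second differences: the sharp corner where
#' the per-barcode contribution collapses from real-cell to ambient level.
#' For long barcode lists the curve is interpolated onto an even log-rank
#' grid and lightly smoothed before differencing, which makes the rule
#' scale-invariant and robust to the broad shoulder that the ambient tail
#' itself produces further down the curve. When the curve has no concave
#' bend (all barcodes alike) every barcode is selected.
#'
#' @param barcode_totals numeric vector of total UMIs per barcode, sorted in
#'   decreasing order (length >= 3).
#' @param n_grid grid size for the interpolated curve (default 512; curves
#'   with fewer barcodes are used as is).
#' @param smooth_w running-mean window applied on the interpolated grid
#'   (default 5).
#' @return integer cutoff rank; barcodes at rank <= cutoff are selected.
#' @export
knee_select <- function(barcode_totals, n_grid = 512L, smooth_w = 5L) {
  n <- length(barcode_totals)
  if (n < 3L) stop("need at least 3 barcodes to locate a knee")
  if (is.unsorted(rev(barcode_totals)))
    stop("barcode_totals must be sorted in decreasing order")
  x <- log10(seq_len(n))
  y <- cumsum(as.numeric(barcode_totals)) / sum(as.numeric(barcode_totals))
  if (n > n_grid) {
    grid <- seq(x[1], x[n], length.out = n_grid)
    yg <- stats::approx(x, y, grid)$y
    if (smooth_w > 1L) {
      yg <- stats::filter(yg, rep(1 / smooth_w, smooth_w), sides = 2)
      ok <- !is.na(yg)
      grid <- grid[ok]; yg <- as.numeric(yg[ok])
    }
  } else { grid <- x; yg <- y }
  m <- length(yg)
  d1 <- diff(yg) / diff(grid)
  xm <- (grid[-1] + grid[-m]) / 2
  d2 <- diff(d1) / diff(xm)
  kappa <- d2 / (1 + ((d1[-1] + d1[-(m - 1)])^2 / 4))^1.5
  i <- which.min(kappa)
  if (kappa[i] >= 0) return(n)       # no concave bend: keep everything
  max(1L, as.integer(round(10^grid[i + 1])))
}

#' Quality-control filtering of cells
#'
#' Keeps a cell iff it has at least `min_genes` detected genes, fewer than
#' `max_genes` when that bound is set, and a mitochondrial read fraction
#' strictly below `max_mito_frac`. Thresholds are read literally: the gene
#' floor is inclusive, the gene ceiling and the mitochondrial bound strict.
#'
#' @param counts genes x cells count matrix (sparse or dense).
#' @param gene_mito logical vector flagging mitochondrial genes, aligned
#'   with rows of `counts`. If no gene is flagged, the mitochondrial
#'   criterion is skipped with a warning.
#' @param min_genes minimum detected genes per cell (inclusive, default 100).
#' @param max_genes optional upper bound on detected genes (strict).
#' @param max_mito_frac maximum mitochondrial fraction (strict, default 0.15).
#' @return list with `keep` (logical per cell) and `qc` (data.frame with
#'   detected_genes, total_umis, mito_frac per cell).
#' @export
qc_filter <- function(counts, gene_mito, min_genes = 100L, max_genes = NULL,
                      max_mito_frac = 0.15) {
  stopifnot(min_genes >= 1L, max_mito_frac > 0, max_mito_frac <= 1)
  if (!is.null(max_genes) && max_genes <= min_genes)
    stop("max_genes must exceed min_genes")
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  if (!any(gene_mito)) {
    warning("no mitochondrial genes flagged; mitochondrial criterion skipped")
    mito_frac <- rep(0, ncol(counts))
    use_mito <- FALSE
  } else {
    mito_frac <- Matrix::colSums(counts[gene_mito, , drop = FALSE]) / pmax(total, 1)
    use_mito <- TRUE
  }
  keep <- detected >= min_genes
  if (!is.null(max_genes)) keep <- keep & detected < max_genes
  if (use_mito) keep <- keep & mito_frac < max_mito_frac
  qc <- data.frame(cell = colnames(counts) %||% as.character(seq_len(ncol(counts))),
                   detected_genes = as.integer(detected),
                   total_umis = as.numeric(total),
                   mito_frac = as.numeric(mito_frac),
                   stringsAsFactors = FALSE)
  list(keep = as.logical(keep), qc = qc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Depth normalization and log transform
#'
#' Scales every cell to `scale_factor` total counts and applies log1p.
#' Optionally regresses given per-cell covariates out of every gene
#' (linear model residuals with the gene-wise intercept restored), as is
#' done for UMI depth and mitochondrial/ribosomal content in
#' epitope-profiled runs.
#'
#' @param counts genes x cells count matrix after QC.
#' @param scale_factor target total per cell (default 1e4).
#' @param regress_covariates optional data.frame/matrix of per-cell
#'   covariates to regress out.
#' @return genes x cells expression matrix (dense when regressing,
#'   otherwise sparse-capable).
#' @export
normalize_log <- function(counts, scale_factor = 1e4, regress_covariates = NULL) {
  depth <- Matrix::colSums(counts)
  if (any(depth == 0)) {
    bad <- which(depth == 0)[1]
    nm <- colnames(counts)[bad] %||% as.character(bad)
    stop("cell '", nm, "' has zero total counts; remove before normalization")
  }
  expr <- counts %*% Matrix::Diagonal(x = scale_factor / depth)
  expr <- log1p(expr)
  dimnames(expr) <- dimnames(counts)
  if (is.null(regress_covariates)) return(expr)
  X <- as.matrix(regress_covariates)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ## drop constant covariates (centered to exactly zero)
  nz <- apply(Xc, 2, function(v) any(abs(v) > 1e-12))
  if (!any(nz)) return(expr)
  Xc <- Xc[, nz, drop = FALSE]
  Y <- t(.as_dense(expr))                      # cells x genes
  beta <- solve(crossprod(Xc), crossprod(Xc, Y))
  out <- t(Y - Xc %*% beta)                    # intercept (gene mean) retained
  dimnames(out) <- dimnames(counts)
  out
}

#' Highly variable gene selection by binned standardized dispersion
#'
#' Ranks genes by their dispersion (variance/mean of expression)
#' standardized within bins of mean expression, and returns the top
#' `n_top`. Deterministic: ties are broken by gene index.
#'
#' @param expr genes x cells expression matrix.
#' @param n_top number of genes to return.
#' @param n_bins number of mean-expression bins (default 20).
#' @return integer vector of gene indices (sorted increasing).
#' @export
select_hvg <- function(expr, n_top, n_bins = 20L) {
  m <- Matrix::rowMeans(expr)
  ex2 <- Matrix::rowMeans(expr^2)
  v <- pmax(ex2 - m^2, 0) * ncol(expr) / max(1, ncol(expr) - 1)
  expressed <- m > 0
  if (n_top > sum(expressed))
    stop("n_top (", n_top, ") exceeds the number of genes expressed anywhere (",
         sum(expressed), ")")
  disp <- ifelse(expressed, v / pmax(m, 1e-12), NA_real_)
  bins <- cut(rank(m, ties.method = "first")[expressed], breaks = n_bins, labels = FALSE)
  z <- rep(NA_real_, length(m))
  de <- disp[expressed]
  ## floor each bin's spread at 1% of the global spread so near-constant
  ## bins cannot inflate their members' standardized dispersion
  sd_floor <- 0.01 * stats::sd(de)
  for (b in unique(bins)) {
    in_b <- bins == b
    mu <- mean(de[in_b])
    sd_ <- max(stats::sd(de[in_b]), sd_floor, na.rm = TRUE)
    z[which(expressed)[in_b]] <- if (is.na(sd_) || sd_ == 0) 0 else (de[in_b] - mu) / sd_
  }
  o <- order(-z, seq_along(z), na.last = TRUE)
  sort(o[seq_len(n_top)])
}

#' Principal component embedding
#'
#' Centers each gene and returns the leading principal-component scores of
#' the cells. Component signs follow the convention that the
#' largest-magnitude gene loading of each component is positive, so results
#' are reproducible across platforms.
#'
#' @param expr genes x cells expression matrix.
#' @param n_pcs number of components.
#' @return list with `scores` (cells x n_pcs), `loadings`, `var_explained`
#'   (fraction of total variance per component) and `sdev`.
#' @export
pca_embed <- function(expr, n_pcs = 10L) {
  X <- t(.as_dense(expr))                       # cells x genes
  if (n_pcs > min(dim(X))) stop("n_pcs exceeds min(cells, genes)")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  tot <- sum(apply(X, 2, stats::var))
  list(scores = scores, loadings = loadings,
       var_explained = pc$sdev[seq_len(n_pcs)]^2 / tot,
       sdev = pc$sdev)
}

## top eigenvalues of the cell-covariance spectrum (PCA eigenvalues)
.pca_eigenvalues <- function(expr, n_pcs) {
  X <- t(.as_dense(expr))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(tcrossprod(Xc), symmetric = TRUE, only.values = TRUE)$values
  pmax(ev[seq_len(n_pcs)], 0) / (nrow(X) - 1)
}

#' Count significant principal components by permutation
#'
#' A jackstraw-style test: for each permutation a small fraction of every
#' gene's values is shuffled across cells and the leading eigenvalues are
#' recomputed, giving a null spectrum that preserves almost all of the
#' data's structure. A component is significant while its observed
#' eigenvalue exceeds the (1-alpha) quantile of its null eigenvalues; the
#' count stops at the first non-significant component (prefix rule).
#'
#' @param expr genes x cells expression matrix.
#' @param n_pcs maximum number of components examined (default 10).
#' @param n_perm number of permutations (>= 20).
#' @param alpha significance level; `alpha >= 1` declares all components
#'   significant.
#' @param perm_frac fraction of cells shuffled per gene (default 0.01).
#' @param seed integer seed.
#' @return integer count of leading significant components.
#' @export
significant_pcs <- function(expr, n_pcs = 10L, n_perm = 20L, alpha = 0.05,
                            perm_frac = 0.01, seed = 1L) {
  if (n_perm < 20L) stop("n_perm must be at least 20")
  if (alpha >= 1) return(as.integer(n_pcs))
  set.seed(as.integer(seed))
  X <- .as_dense(expr)
  n <- ncol(X)
  obs <- .pca_eigenvalues(X, n_pcs)
  m <- max(2L, ceiling(perm_frac * n))
  null_ev <- matrix(NA_real_, n_perm, n_pcs)
  for (p in seq_len(n_perm)) {
    Xp <- X
    for (g in seq_len(nrow(X))) {
      pos <- sample.int(n, m)
      Xp[g, pos] <- Xp[g, sample(pos)]
    }
    null_ev[p, ] <- .pca_eigenvalues(Xp, n_pcs)
  }
  thr <- apply(null_ev, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  sig <- obs > thr
  if (!sig[1]) return(0L)
  as.integer(which(c(!sig, TRUE))[1] - 1L)
}

#' Graph-based clustering of cells
#'
#' Builds a shared-nearest-neighbor graph (Jaccard overlap of k-NN sets) in
#' PCA space and partitions it by modularity community detection at the
#' given resolution. Labels are arbitrary integers but stable for a given
#' seed.
#'
#' @param pca_coords cells x PCs matrix.
#' @param k_neighbors neighborhood size (default 20).
#' @param resolution modularity resolution; larger gives more clusters.
#' @param seed integer seed.
#' @param prune minimum Jaccard weight retained (default 1/15).
#' @return integer vector of cluster labels.
#' @export
cluster_graph <- function(pca_coords, k_neighbors = 20L, resolution = 1,
                          seed = 1L, prune = 1 / 15) {
  n <- nrow(pca_coords)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the number of cells")
  nn <- .knn_index(pca_coords, k_neighbors)
  ## neighbor sets including self, for Jaccard overlap
  sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  ii <- rep(seq_len(n), each = k_neighbors)
  jj <- as.vector(t(nn))
  keep <- ii < jj
  pr <- unique(rbind(cbind(ii[keep], jj[keep]), cbind(jj[!keep], ii[!keep])))
  w <- vapply(seq_len(nrow(pr)), function(r) {
    a <- sets[[pr[r, 1]]]; b <- sets[[pr[r, 2]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  ok <- w >= prune
  g <- igraph::graph_from_edgelist(pr[ok, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(g, weights = w[ok], resolution = resolution)
  as.integer(igraph::membership(cl))
}

#' Two-dimensional embedding of cells
#'
#' Returns deterministic 2D coordinates for visualization and for the
#' embedding-space operations (density contrasts, refinement filters). The
#' implementation projects onto the two leading principal axes of the
#' supplied PCA coordinates; any seeded neighbor-preserving embedding
#' satisfies the same contract and downstream code treats the coordinates
#' as opaque.
#'
#' @param pca_coords cells x PCs matrix (>= 10 cells).
#' @param seed integer seed (accepted for interface stability; the linear
#'   projection is deterministic).
#' @return cells x 2 coordinate matrix.
#' @export
embed_2d <- function(pca_coords, seed = 1L) {
  pca_coords <- as.matrix(pca_coords)
  if (nrow(pca_coords) < 10L) stop("need at least 10 cells to embed")
  if (ncol(pca_coords) == 1L) pca_coords <- cbind(pca_coords, 0)
  out <- pca_coords[, 1:2, drop = FALSE]
  colnames(out) <- c("dim1", "dim2")
  out
}

#' Merge cluster labels
#'
#' Explicit utility for collapsing clusters that are not distinguishable by
#' their marker genes (e.g. acinar subclusters); no automation is attempted.
#'
#' @param labels vector of cluster labels.
#' @param merge named list: each element a vector of labels to collapse into
#'   the element's name.
#' @return relabeled vector.
#' @export
merge_labels <- function(labels, merge) {
  out <- as.character(labels)
  for (nm in names(merge)) out[out %in% as.character(merge[[nm]])] <- nm
  out
}
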