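## Gaussian product-kernel density of `pts` evaluated at `eval`.
## Auto bandwidth is an isotropic Scott rule (root mean per-axis variance),
## so the estimate is exactly invariant under rotations and translations.
.kde2d_at <- function(pts, eval, bandwidth = NULL) {
  n <- nrow(pts)
  if (is.null(bandwidth)) {
    h0 <- sqrt(mean(apply(pts, 2, stats::var))) * n^(-1 / 6)
    span <- max(apply(eval, 2, function(v) diff(range(v))), 1)
    if (!is.finite(h0) || h0 <= 0) h0 <- 1e-8 * span
    h <- c(h0, h0)
  } else h <- rep(bandwidth, length.out = 2)
  z1 <- outer(eval[, 1], pts[, 1], "-") / h[1]
  z2 <- outer(eval[, 2], pts[, 2], "-") / h[2]
  k <- exp(-0.5 * (z1^2 + z2^2)) / (2 * pi * h[1] * h[2])
  list(f = rowMeans(k), h = h)
}

#' Relative log2 density of two sample groups on a 2D embedding
#'
#' Estimates a separate Gaussian kernel density for each group (each
#' normalized to integrate to one, bandwidths by Scott's rule per group),
#' evaluates both at every cell's coordinates, and returns
#' log2((f_A + eps)/(f_B + eps)). The regularizer eps keeps ratios finite
#' where one group's density vanishes; swapping the groups negates every
#' value exactly.
#'
#' @param embed2d cells x 2 coordinate matrix.
#' @param labels two-level per-cell grouping; the first factor level is the
#'   numerator group A.
#' @param bandwidth `NULL` for Scott's rule per group, or a numeric
#'   bandwidth used for both axes.
#' @param eps regularizer; default 1e-3 x the maximum estimated density.
#' @return object of class `density_contrast`: list with `log2_ratio`
#'   (per cell), `f_a`, `f_b`, `bandwidths`, `eps`, `groups`.
#' @export
relative_log_density <- function(embed2d, labels, bandwidth = NULL, eps = NULL) {
  embed2d <- as.matrix(embed2d)
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly two levels")
  a <- which(f == levels(f)[1]); b <- which(f == levels(f)[2])
  if (!length(a) || !length(b))
    stop("both groups must be non-empty (group '",
         levels(f)[if (!length(a)) 1 else 2], "' is empty)")
  ka <- .kde2d_at(embed2d[a, , drop = FALSE], embed2d, bandwidth)
  kb <- .kde2d_at(embed2d[b, , drop = FALSE], embed2d, bandwidth)
  if (is.null(eps)) eps <- 1e-3 * max(ka$f, kb$f)
  structure(list(log2_ratio = log2((ka$f + eps) / (kb$f + eps)),
                 f_a = ka$f, f_b = kb$f,
                 bandwidths = list(a = ka$h, b = kb$h),
                 eps = eps, groups = levels(f)),
            class = "density_contrast")
}

#' @export
print.density_contrast <- function(x, ...) {
  cat("Embedding density contrast: log2 f(", x$groups[1], ") / f(",
      x$groups[2], ")\n", sep = "")
  cat("  cells:", length(x$log2_ratio),
      "  mean |log2 ratio|:", format(mean(abs(x$log2_ratio)), digits = 3), "\n")
  invisible(x)
}

#' Filter cells far from their cluster center on the embedding
#'
#' Removes cells lying more than `n_sd` standard deviations away from their
#' cluster's coordinate centroid, where the SD is taken over that cluster's
#' center distances. Singleton clusters are kept with a warning; clusters of
#' coincident points have SD 0 and keep all members (the strict `>` never
#' fires).
#'
#' @param embed2d cells x 2 coordinate matrix.
#' @param cluster_labels per-cell cluster labels.
#' @param n_sd removal threshold in SD units (default 3).
#' @return logical keep mask.
#' @export
centroid_outlier_filter <- function(embed2d, cluster_labels, n_sd = 3) {
  embed2d <- as.matrix(embed2d)
  keep <- rep(TRUE, nrow(embed2d))
  for (cl in unique(cluster_labels)) {
    in_cl <- which(cluster_labels == cl)
    if (length(in_cl) < 2L) {
      warning("cluster '", cl, "' is a singleton; kept")
      next
    }
    ctr <- colMeans(embed2d[in_cl, , drop = FALSE])
    d <- sqrt(rowSums(sweep(embed2d[in_cl, , drop = FALSE], 2, ctr)^2))
    s <- stats::sd(d)
    keep[in_cl] <- !(d > n_sd * s)
  }
  keep
}

#' Filter cells disagreeing with their embedding neighborhood
#'
#' Removes a cell iff a strict majority (more than k/2) of its k nearest
#' embedding neighbors carries one single label different from the cell's
#' own; ties and plurality-without-majority keep the cell. The vote is
#' computed once on the input labels, so the filter is deterministic but
#' deliberately not idempotent (a second pass would vote on a changed
#' neighbor base and is not applied by default).
#'
#' @param embed2d cells x 2 coordinate matrix.
#' @param cluster_labels per-cell cluster labels.
#' @param k number of neighbors (default 10).
#' @return logical keep mask.
#' @export
knn_majority_filter <- function(embed2d, cluster_labels, k = 10L) {
  embed2d <- as.matrix(embed2d)
  n <- nrow(embed2d)
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- .knn_index(embed2d, as.integer(k))
  lab <- as.character(cluster_labels)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    votes <- table(lab[nn[i, ]])
    top <- names(votes)[which.max(votes)]
    if (top != lab[i] && max(votes) > k / 2) keep[i] <- FALSE
  }
  keep
}
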