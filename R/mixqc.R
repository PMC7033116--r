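#' k-nearest-neighbor graph in PCA space
#'
#' Euclidean k-NN per cell with self excluded; ties are broken
#' deterministically by cell index.
#'
#' @param pca_coords cells x PCs matrix.
#' @param k neighborhood size (default 30); must be < number of cells.
#' @return cells x k integer matrix of neighbor indices.
#' @export
knn_graph <- function(pca_coords, k = 30L) {
  .knn_index(pca_coords, as.integer(k))
}

## per-cell neighborhood composition over integer-coded groups
.neighborhood_props <- function(neighbors, codes, n_groups) {
  n <- nrow(neighbors)
  k <- ncol(neighbors)
  q <- matrix(0, n, n_groups)
  lab <- matrix(codes[neighbors], n, k)
  for (g in seq_len(n_groups)) q[, g] <- rowSums(lab == g) / k
  q
}

.kl_rows <- function(q, q0) {
  ## sum_i q_i log(q_i/q0_i), with 0 log 0 := 0; q0 strictly positive
  lr <- log(sweep(q, 2, q0, "/"))
  lr[q == 0] <- 0
  rowSums(q * lr)
}

#' Neighborhood sample-mixing divergence
#'
#' For each cell j, the Kullback-Leibler divergence (natural log)
#' D_j = sum_i q_i log(q_i / q0_i) between the composition q of its k-NN
#' neighborhood over sample groups and the global composition q0. D_j = 0
#' when the neighborhood mirrors the data set; large D_j marks cells whose
#' neighborhoods are dominated by particular samples or factors.
#'
#' @param neighbors cells x k neighbor index matrix from [knn_graph()].
#' @param labels per-cell group labels (factor or character); groups absent
#'   from the data are dropped.
#' @param q0 optional named global proportions; computed from `labels` when
#'   missing. Every observed label must have q0 > 0.
#' @return object of class `mixing_result`: list with `D` (per-cell, nats),
#'   `q0`, `k`, `groups`.
#' @export
mixing_divergence <- function(neighbors, labels, q0 = NULL) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (is.null(q0)) {
    q0 <- as.vector(table(factor(labels, levels = groups))) / length(labels)
    names(q0) <- groups
  } else {
    if (!all(groups %in% names(q0)))
      stop("label(s) absent from q0: ",
           paste(setdiff(groups, names(q0)), collapse = ", "))
    q0 <- q0[groups]
    if (any(q0 <= 0)) stop("q0 must be strictly positive for every observed group")
    q0 <- q0 / sum(q0)
  }
  codes <- match(labels, groups)
  q <- .neighborhood_props(neighbors, codes, length(groups))
  D <- .kl_rows(q, q0)
  structure(list(D = D, q0 = q0, k = ncol(neighbors), groups = groups),
            class = "mixing_result")
}

#' @export
print.mixing_result <- function(x, ...) {
  cat("Neighborhood mixing divergence (KL, nats)\n")
  cat("  cells:", length(x$D), "  k:", x$k, "  groups:", length(x$groups), "\n")
  cat("  mean D:", format(mean(x$D), digits = 4),
      "  upper bound:", format(max(log(1 / x$q0)), digits = 4), "\n")
  invisible(x)
}

#' Permutation null for the mixing divergence
#'
#' Controls are obtained by randomly shuffling the group assignment between
#' cells; the divergence is recomputed against the unchanged global
#' composition. Returns the permuted mean divergences and a one-sided
#' empirical p-value for the observed mean exceeding the null.
#'
#' @param neighbors cells x k neighbor index matrix.
#' @param labels per-cell group labels.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return list with `observed_mean`, `null_means`, `p`.
#' @export
shuffle_null <- function(neighbors, labels, n_perm = 100L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  labels <- as.character(labels)
  obs <- mixing_divergence(neighbors, labels)
  set.seed(as.integer(seed))
  groups <- obs$groups
  codes <- match(labels, groups)
  null_means <- vapply(seq_len(n_perm), function(p) {
    perm <- sample(codes)
    q <- .neighborhood_props(neighbors, perm, length(groups))
    mean(.kl_rows(q, obs$q0))
  }, numeric(1))
  observed <- mean(obs$D)
  list(observed_mean = observed,
       null_means = null_means,
       p = (1 + sum(null_means >= observed)) / (n_perm + 1))
}

#' Chain-rule decomposition of the mixing divergence
#'
#' Splits the replicate-level divergence of every cell into a
#' biological-group component and a within-group (replicate) component via
#' the exact chain rule of the KL divergence over nested groupings:
#' D_total = D_between + sum_b q_b D(q_rep|b || q0_rep|b). The summary
#' fraction mean(D_between)/mean(D_total) measures how much of the local
#' sample structure is explained by the biological factors (e.g. genotype,
#' sex, stage) rather than replicate identity.
#'
#' @param neighbors cells x k neighbor index matrix.
#' @param replicate_labels per-cell replicate (sample) labels.
#' @param factor_map named vector mapping every replicate to its biological
#'   group.
#' @return list with `per_cell` (data.frame: D_total, D_between, D_within)
#'   and `fraction_between` = mean(D_between)/mean(D_total).
#' @export
decompose_mixing <- function(neighbors, replicate_labels, factor_map) {
  rep_lab <- as.character(replicate_labels)
  reps <- sort(unique(rep_lab))
  missing <- setdiff(reps, names(factor_map))
  if (length(missing))
    stop("replicate(s) missing from factor_map: ", paste(missing, collapse = ", "))
  grp_of_rep <- as.character(factor_map[reps])
  groups <- sort(unique(grp_of_rep))

  q0r <- as.vector(table(factor(rep_lab, levels = reps))) / length(rep_lab)
  codes <- match(rep_lab, reps)
  qr <- .neighborhood_props(neighbors, codes, length(reps))

  agg <- t(vapply(groups, function(g) as.numeric(grp_of_rep == g),
                  numeric(length(reps))))        # groups x reps indicator
  qb <- qr %*% t(agg)
  q0b <- as.vector(agg %*% q0r)

  D_total <- .kl_rows(qr, q0r)
  D_between <- .kl_rows(qb, q0b)
  ## within-group terms: q_b * KL(q_rep|b || q0_rep|b)
  D_within <- numeric(nrow(qr))
  for (gi in seq_along(groups)) {
    in_g <- which(grp_of_rep == groups[gi])
    q0_cond <- q0r[in_g] / q0b[gi]
    qb_g <- qb[, gi]
    q_cond <- qr[, in_g, drop = FALSE] / ifelse(qb_g > 0, qb_g, 1)
    kl <- .kl_rows(q_cond, q0_cond)
    kl[qb_g == 0] <- 0
    D_within <- D_within + qb_g * kl
  }
  data_frame <- data.frame(D_total = D_total, D_between = D_between,
                           D_within = D_within)
  list(per_cell = data_frame,
       fraction_between = mean(D_between) / mean(D_total))
}
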