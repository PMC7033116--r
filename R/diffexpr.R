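#' Pool single-cell counts into pseudobulk columns
#'
#' Sums counts over all cells from one sample and one group (e.g. a
#' subcluster), producing replicate-level count columns to which standard
#' negative-binomial count models apply. Columns with zero cells are
#' dropped; summation is exact integer arithmetic.
#'
#' @param counts genes x cells count matrix.
#' @param metadata per-cell data.frame; must contain `sample_field` and
#'   `group_field`, and may carry per-sample design columns (genotype, sex,
#'   stage) which are propagated to the output.
#' @param group_field metadata column defining the group.
#' @param sample_field metadata column defining the sample (default
#'   "sample").
#' @return list of class `pseudobulk`: `counts` (genes x columns),
#'   `coldata` (sample, group, n_cells + design columns).
#' @export
aggregate_pseudobulk <- function(counts, metadata, group_field,
                                 sample_field = "sample") {
  for (f in c(sample_field, group_field))
    if (!f %in% names(metadata)) stop("metadata lacks column '", f, "'")
  key <- interaction(metadata[[sample_field]], metadata[[group_field]],
                     drop = TRUE, sep = "||")
  idx <- split(seq_len(ncol(counts)), key)
  pooled <- vapply(idx, function(i)
    as.numeric(Matrix::rowSums(counts[, i, drop = FALSE])),
    numeric(nrow(counts)))
  pooled <- matrix(pooled, nrow = nrow(counts),
                   dimnames = list(rownames(counts), names(idx)))
  parts <- do.call(rbind, strsplit(names(idx), "||", fixed = TRUE))
  coldata <- data.frame(sample = parts[, 1], group = parts[, 2],
                        n_cells = lengths(idx), stringsAsFactors = FALSE)
  for (dc in intersect(c("genotype", "sex", "stage"), names(metadata))) {
    coldata[[dc]] <- vapply(idx, function(i)
      as.character(metadata[[dc]][i[1]]), character(1))
  }
  structure(list(counts = pooled, coldata = coldata), class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat("Pseudobulk table:", nrow(x$counts), "genes x", ncol(x$counts),
      "(sample, group) columns\n")
  cat("  cells per column: median", stats::median(x$coldata$n_cells), "\n")
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' Per-column normalization factors: the median over all-nonzero genes of
#' the ratio of each count to the gene's geometric mean, rescaled to
#' geometric mean one. Falls back to total-count factors (with a message)
#' when no gene is nonzero in every column.
#'
#' @param pooled genes x columns count matrix.
#' @return numeric vector of positive size factors.
#' @export
size_factors <- function(pooled) {
  pooled <- as.matrix(pooled)
  allnz <- rowSums(pooled > 0) == ncol(pooled)
  if (!any(allnz)) {
    message("no gene is nonzero in every column; using total-count size factors")
    sf <- colSums(pooled)
  } else {
    lg <- log(pooled[allnz, , drop = FALSE])
    gm <- rowMeans(lg)
    sf <- apply(exp(lg - gm), 2, stats::median)
  }
  unname(sf / exp(mean(log(sf))))
}

#' Expression-fraction gene filter
#'
#' Keeps a gene iff it is detected (nonzero) in at least `min_frac` of the
#' cells in the given subset; the bound is inclusive.
#'
#' @param counts genes x cells count matrix.
#' @param cells index or logical vector selecting the cell subset.
#' @param min_frac minimum detection fraction in (0, 1] (default 0.05).
#' @return logical gene mask.
#' @export
expression_fraction_filter <- function(counts, cells, min_frac = 0.05) {
  stopifnot(min_frac > 0, min_frac <= 1)
  sub <- counts[, cells, drop = FALSE]
  if (ncol(sub) == 0L) stop("cell subset is empty")
  Matrix::rowSums(sub > 0) / ncol(sub) >= min_frac
}

## per-gene NB fit with ML dispersion and method-of-moments fallback.
## Returns list(coef, se, ok, theta, dev, df_resid) or NULL.
.fit_nb <- function(y, X, off) {
  df <- data.frame(y = y)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ X - 1 + offset(off), data = df,
                                  control = stats::glm.control(maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    ## method-of-moments dispersion, then fixed-theta GLM
    mu0 <- pmax(mean(y), 1e-8)
    v <- stats::var(y)
    theta <- if (v > mu0) mu0^2 / (v - mu0) else 1e6
    theta <- min(max(theta, 1e-3), 1e6)
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ X - 1 + offset(off), data = df,
                                  family = MASS::negative.binomial(theta))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(NULL)
    fit$theta <- theta
  }
  sm <- summary(fit)$coefficients
  list(coef = stats::coef(fit), se = sm[, 2], theta = fit$theta,
       deviance = fit$deviance, df_resid = fit$df.residual, fit = fit)
}

.de_result <- function(df, test) {
  tested <- !is.na(df$p)
  df$q <- NA_real_
  df$q[tested] <- stats::p.adjust(df$p[tested], method = "BH")
  attr(df, "test") <- test
  attr(df, "n_not_converged") <- sum(df$status == "not_converged")
  class(df) <- c("de_result", "data.frame")
  df
}

#' @export
print.de_result <- function(x, ...) {
  cat("Pseudobulk NB differential expression (", attr(x, "test"), ")\n", sep = "")
  cat("  genes tested:", sum(!is.na(x$p)),
      " q<0.1:", sum(x$q < 0.1, na.rm = TRUE),
      " not converged:", attr(x, "n_not_converged"), "\n")
  invisible(as.data.frame(x))
}

#' Pseudobulk NB Wald test with cell-count covariate
#'
#' Fits, per gene, a negative-binomial log-linear model of the pooled
#' counts on the two-level contrast plus centered log10 cell count (and any
#' further design covariates), with log size factors as offset. Dispersion
#' is estimated per gene by maximum likelihood with a method-of-moments
#' fallback, and the Wald statistic on the contrast coefficient is
#' quasi-likelihood corrected: its standard error is inflated by the
#' root Pearson overdispersion (floored at 1) and referred to a t
#' distribution on the residual degrees of freedom, which keeps the test
#' calibrated at replicate-level sample sizes. Reports log2 fold changes
#' with BH-adjusted q-values; non-convergent genes get p = NA and are
#' excluded from the BH denominator, and all-zero genes are excluded
#' before fitting.
#'
#' @param pseudobulk a [aggregate_pseudobulk()] result (or list with
#'   `counts`, `coldata`).
#' @param contrast_field two-level column of `coldata` to test.
#' @param covariates further `coldata` columns to adjust for;
#'   `"log_n_cells"` (default) is the centered log10 number of cells.
#' @param sf size factors; computed by [size_factors()] when missing.
#' @return data.frame of class `de_result`: gene, log2fc, se, stat, p, q,
#'   status.
#' @export
nb_wald_test <- function(pseudobulk, contrast_field,
                         covariates = "log_n_cells", sf = NULL) {
  cts <- as.matrix(pseudobulk$counts)
  cd <- pseudobulk$coldata
  f <- factor(cd[[contrast_field]])
  if (nlevels(f) != 2L) stop("contrast_field must have exactly two levels")
  if (min(table(f)) < 2L) stop("need at least 2 columns per contrast level")
  X <- stats::model.matrix(~f)
  colnames(X)[2] <- "contrast"
  for (cv in covariates) {
    v <- if (cv == "log_n_cells") scale(log10(cd$n_cells), scale = FALSE)[, 1]
         else cd[[cv]]
    if (is.character(v) || is.factor(v)) {
      mm <- stats::model.matrix(~factor(v))[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, seq_len(ncol(mm)))
      X <- cbind(X, mm)
    } else {
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- cv
    }
  }
  if (is.null(sf)) sf <- size_factors(cts)
  off <- log(sf)
  genes <- rownames(cts) %||% as.character(seq_len(nrow(cts)))
  res <- data.frame(gene = genes, log2fc = NA_real_, se = NA_real_,
                    stat = NA_real_, p = NA_real_,
                    status = "excluded", stringsAsFactors = FALSE)
  nonzero <- rowSums(cts) > 0
  df_resid <- ncol(cts) - ncol(X)
  for (g in which(nonzero)) {
    ft <- .fit_nb(cts[g, ], X, off)
    if (is.null(ft)) { res$status[g] <- "not_converged"; next }
    b <- ft$coef[["Xcontrast"]]; se <- ft$se[["Xcontrast"]]
    mu <- stats::fitted(ft$fit)
    phi <- sum((cts[g, ] - mu)^2 / (mu + mu^2 / ft$theta)) / df_resid
    se <- se * sqrt(max(phi, 1))
    tt <- b / se
    res$log2fc[g] <- b / log(2)
    res$se[g] <- se / log(2)
    res$stat[g] <- tt
    res$p[g] <- 2 * stats::pt(-abs(tt), df = df_resid)
    res$status[g] <- "ok"
  }
  .de_result(res, "Wald")
}

#' Pseudobulk NB likelihood-ratio test over multiple groups
#'
#' Tests, per gene, the group factor (e.g. the four trajectory
#' subpopulations) jointly: the full NB model with the group factor and
#' covariates is compared against the reduced model without it at the
#' gene's full-model dispersion. The deviance difference is
#' quasi-likelihood corrected (divided by the Pearson overdispersion,
#' floored at 1) and referred to an F distribution with (groups - 1) and
#' residual degrees of freedom, which keeps the null uniform at
#' replicate-level sample sizes. Supports ranking the top differential
#' genes between subpopulations.
#'
#' @inheritParams nb_wald_test
#' @param group_field multi-level column of `coldata` to test.
#' @return data.frame of class `de_result` with the LRT statistic in
#'   `stat`; `log2fc` holds the largest absolute pairwise group log2 fold
#'   change.
#' @export
nb_lrt_test <- function(pseudobulk, group_field,
                        covariates = "log_n_cells", sf = NULL) {
  cts <- as.matrix(pseudobulk$counts)
  cd <- pseudobulk$coldata
  f <- factor(cd[[group_field]])
  if (sum(table(f) >= 2L) < 2L) stop("need >= 2 columns in >= 2 groups")
  Xg <- stats::model.matrix(~f)
  X0 <- Xg[, 1, drop = FALSE]
  for (cv in covariates) {
    v <- if (cv == "log_n_cells") scale(log10(cd$n_cells), scale = FALSE)[, 1]
         else cd[[cv]]
    Xg <- cbind(Xg, v); X0 <- cbind(X0, v)
  }
  df_test <- nlevels(f) - 1L
  if (is.null(sf)) sf <- size_factors(cts)
  off <- log(sf)
  genes <- rownames(cts) %||% as.character(seq_len(nrow(cts)))
  res <- data.frame(gene = genes, log2fc = NA_real_, se = NA_real_,
                    stat = NA_real_, p = NA_real_,
                    status = "excluded", stringsAsFactors = FALSE)
  df_resid <- ncol(cts) - ncol(Xg)
  for (g in which(rowSums(cts) > 0)) {
    y <- cts[g, ]
    full <- .fit_nb(y, Xg, off)
    if (is.null(full)) { res$status[g] <- "not_converged"; next }
    red <- tryCatch(
      suppressWarnings(stats::glm(y ~ X0 - 1 + offset(off),
                                  family = MASS::negative.binomial(full$theta))),
      error = function(e) NULL)
    if (is.null(red)) { res$status[g] <- "not_converged"; next }
    mu <- stats::fitted(full$fit)
    phi <- sum((y - mu)^2 / (mu + mu^2 / full$theta)) / df_resid
    fstat <- max(0, red$deviance - full$deviance) / df_test / max(phi, 1)
    grp_coefs <- c(0, full$coef[2:nlevels(f)])
    res$log2fc[g] <- (max(grp_coefs) - min(grp_coefs)) / log(2)
    res$stat[g] <- fstat
    res$p[g] <- stats::pf(fstat, df_test, df_resid, lower.tail = FALSE)
    res$status[g] <- "ok"
  }
  .de_result(res, "LRT")
}

## beta-binomial log-likelihood reparameterized by mean p and dispersion rho
.betabinom_negll <- function(par, y, n, X) {
  nb <- ncol(X)
  eta <- X %*% par[seq_len(nb)]
  p <- 1 / (1 + exp(-eta))
  rho <- 1 / (1 + exp(-par[nb + 1]))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  -sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
}

#' Test cell-type composition with a binomial mixed model
#'
#' Models, per sample, the number of retained cells falling in the target
#' cluster as binomial with logit link, the supplied design variables as
#' fixed effects and the sample as the unit of extra-binomial variation.
#' The default backend integrates the per-sample random intercept out
#' marginally as a beta-binomial and maximizes that likelihood directly;
#' Wald statistics on the fixed effects are referred to a t distribution
#' on (samples - parameters) degrees of freedom, which stays calibrated
#' at cohort sizes of a few dozen samples. `backend = "glmer"` instead
#' fits the logit-normal random-intercept model by Laplace approximation
#' (lme4); its Wald z p-values are known to be anticonservative when the
#' between-sample variance is estimated from few samples. Quasi-complete
#' separation is flagged and the affected p set to NA.
#'
#' @param composition samples x clusters count matrix (row sums = retained
#'   cells per sample).
#' @param design per-sample data.frame aligned with rows.
#' @param cluster column (name or index) of `composition` to test.
#' @param fixed_effects design columns used as fixed effects.
#' @param backend `"betabinomial"` (default) or `"glmer"`.
#' @return data.frame: term, estimate (log-odds), se, z, p, separation,
#'   with attribute `backend`.
#' @export
composition_test <- function(composition, design, cluster,
                             fixed_effects = c("genotype", "sex", "stage"),
                             backend = c("betabinomial", "glmer")) {
  backend <- match.arg(backend)
  composition <- as.matrix(composition)
  y <- composition[, cluster]
  n <- rowSums(composition)
  fixed_effects <- intersect(fixed_effects, names(design))
  for (fe in fixed_effects) {
    lv <- table(design[[fe]])
    if (any(lv < 3L)) stop("fewer than 3 samples in a level of '", fe, "'")
  }
  dat <- design[, fixed_effects, drop = FALSE]
  dat$..y <- y; dat$..n <- n
  X <- stats::model.matrix(stats::as.formula(
    paste("~", paste(fixed_effects, collapse = " + "))), dat)
  df_resid <- length(y) - ncol(X)
  used <- backend
  if (backend == "glmer") {
    dat$..sample <- factor(seq_along(y))
    form <- stats::as.formula(paste(
      "cbind(..y, ..n - ..y) ~", paste(fixed_effects, collapse = " + "),
      "+ (1 | ..sample)"))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::glmer(form, data = dat, family = stats::binomial()))),
      error = function(e) NULL)
    if (is.null(fit)) { used <- "betabinomial" } else {
      sm <- summary(fit)$coefficients
      est <- sm[-1, 1]; se <- sm[-1, 2]
      z <- est / se
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  if (used == "betabinomial") {
    p0 <- min(max(sum(y) / sum(n), 1e-4), 1 - 1e-4)
    start <- c(log(p0 / (1 - p0)), rep(0, ncol(X) - 1), -3)
    op <- stats::optim(start, .betabinom_negll, y = y, n = n, X = X,
                       method = "BFGS", hessian = TRUE)
    co <- op$par[seq_len(ncol(X))]
    vc <- tryCatch(solve(op$hessian)[seq_len(ncol(X)), seq_len(ncol(X)),
                                     drop = FALSE],
                   error = function(e) matrix(NA, ncol(X), ncol(X)))
    dg <- diag(vc)
    dg[!is.finite(dg) | dg <= 0] <- NA_real_
    est <- co[-1]; se <- sqrt(dg)[-1]
    names(est) <- colnames(X)[-1]
    z <- est / se
    p <- 2 * stats::pt(-abs(z), df = df_resid)
  }
  sep <- !is.finite(se) | abs(est) > 10 | se > 10
  p[sep] <- NA_real_
  out <- data.frame(term = names(est), estimate = est, se = se, z = z, p = p,
                    separation = sep, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "backend") <- used
  out
}

#' Correlate pooled single-cell profiles with bulk RNA-seq
#'
#' Converts pooled single-cell counts to a per-million (TPM-like) scale,
#' keeps genes whose abundance exceeds 1e-4 (strictly) in every compared
#' column, and reports the Pearson correlation of log10 values for every
#' pooled-column/bulk-column pair.
#'
#' @param pooled genes x groups pooled single-cell counts.
#' @param bulk_tpm genes x samples bulk abundance table (same gene order or
#'   shared rownames).
#' @param min_abund abundance floor (strict; default 1e-4).
#' @return matrix of Pearson R (pooled columns x bulk columns), with the
#'   number of genes used as attribute `n_genes`.
#' @export
pooled_vs_bulk_correlation <- function(pooled, bulk_tpm, min_abund = 1e-4) {
  pooled <- as.matrix(pooled); bulk_tpm <- as.matrix(bulk_tpm)
  if (!is.null(rownames(pooled)) && !is.null(rownames(bulk_tpm))) {
    shared <- intersect(rownames(pooled), rownames(bulk_tpm))
    pooled <- pooled[shared, , drop = FALSE]
    bulk_tpm <- bulk_tpm[shared, , drop = FALSE]
  } else stopifnot(nrow(pooled) == nrow(bulk_tpm))
  ptpm <- sweep(pooled, 2, colSums(pooled), "/") * 1e6
  keep <- rowSums(cbind(ptpm, bulk_tpm) > min_abund) == ncol(ptpm) + ncol(bulk_tpm)
  if (sum(keep) < 50L)
    warning("fewer than 50 shared genes pass the abundance filter (",
            sum(keep), ")")
  R <- stats::cor(log10(ptpm[keep, , drop = FALSE]),
                  log10(bulk_tpm[keep, , drop = FALSE]))
  attr(R, "n_genes") <- sum(keep)
  R
}
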