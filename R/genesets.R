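#' Curated stemness gene set
#'
#' The 14 literature-curated mouse stemness markers used for trajectory
#' module scoring. `"Aldh1a"` is stored verbatim although it is not a
#' unique mouse symbol (Aldh1a1/2/3); matching against expression data is
#' prefix-based (see [match_gene_set()]).
#'
#' @format character vector of 14 gene symbols.
#' @export
stemness_genes <- c("Pou5f1", "Nanog", "Sox2", "Prom1", "Bmi1", "Lgr5",
                    "Msi1", "Tdgf1", "Bmp4", "Cspg4", "Cxcr4", "Alcam",
                    "Slc2a13", "Aldh1a")

#' Match gene-set symbols against a gene universe
#'
#' Exact matches first; symbols with no exact match are matched as prefixes
#' (covering ambiguous family symbols such as `Aldh1a`), with a message
#' listing prefix-matched symbols.
#'
#' @param set character vector of symbols.
#' @param universe character vector of gene names.
#' @return integer indices into `universe`.
#' @export
match_gene_set <- function(set, universe) {
  hit <- match(set, universe)
  out <- hit[!is.na(hit)]
  miss <- set[is.na(hit)]
  if (length(miss)) {
    pref <- unlist(lapply(miss, function(s) grep(paste0("^", s), universe)))
    if (length(pref))
      message("prefix-matched symbols: ",
              paste(unique(miss), collapse = ", "))
    out <- c(out, pref)
  }
  sort(unique(out))
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1))
}

#' Gene-set enrichment on log2 fold changes
#'
#' For each set, an unequal-variance two-sample t-test of the member
#' genes' log2 fold changes against all non-member tested genes
#' (two-sided; direction read from the sign of the member mean). Only
#' genes present in `lfc` (i.e. passing the upstream expression filter)
#' contribute. Sets with fewer than 3 expressed members are skipped.
#' BH adjustment is applied across tested sets.
#'
#' @param lfc named numeric vector of per-gene log2 fold changes
#'   (background = all tested genes).
#' @param gene_sets named list of character vectors.
#' @param ribosomal optional character vector (or logical mask over
#'   `names(lfc)`) marking ribosomal genes, used to report each set's
#'   ribosomal fraction.
#' @return data.frame of class `geneset_result`: set, n_members,
#'   mean_lfc, t, p, q, frac_ribosomal.
#' @export
set_enrichment_test <- function(lfc, gene_sets, ribosomal = NULL) {
  genes <- names(lfc)
  if (is.null(genes)) stop("lfc must be named by gene")
  ribo <- if (is.null(ribosomal)) rep(FALSE, length(genes))
          else if (is.logical(ribosomal)) ribosomal
          else genes %in% ribosomal
  rows <- lapply(names(gene_sets), function(nm) {
    idx <- match_gene_set(gene_sets[[nm]], genes)
    n_m <- length(idx)
    if (n_m < 3L) {
      message("set '", nm, "' has fewer than 3 expressed members; skipped")
      return(NULL)
    }
    member <- lfc[idx]
    rest <- lfc[-idx]
    tt <- stats::t.test(member, rest, var.equal = FALSE)
    data.frame(set = nm, n_members = n_m,
               mean_lfc = mean(member),
               t = unname(tt$statistic), p = tt$p.value,
               frac_ribosomal = mean(ribo[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(), n_members = integer(),
                      mean_lfc = numeric(), t = numeric(), p = numeric(),
                      frac_ribosomal = numeric())
  out$q <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("geneset_result", "data.frame")
  out
}

#' Reporting filter for enriched gene sets
#'
#' Retains a set iff its q-value is below `q_max`, the absolute mean log2
#' fold change strictly exceeds `min_abs_mean_lfc`, and at most
#' `ribo_frac_max` of its members are ribosomal (sets with strictly more
#' are ignored).
#'
#' @param results a [set_enrichment_test()] data.frame.
#' @param q_max FDR bound (default 0.1).
#' @param min_abs_mean_lfc strict lower bound on |mean log2 FC| (default 0.5).
#' @param ribo_frac_max maximum ribosomal member fraction (default 0.1).
#' @return the retained rows.
#' @export
filter_enrichment <- function(results, q_max = 0.1, min_abs_mean_lfc = 0.5,
                              ribo_frac_max = 0.1) {
  keep <- results$q < q_max &
    abs(results$mean_lfc) > min_abs_mean_lfc &
    results$frac_ribosomal <= ribo_frac_max
  results[keep, , drop = FALSE]
}

#' Per-cell gene-set module score with binned controls
#'
#' Scores each cell as the mean expression of the set genes minus the mean
#' of control genes drawn from the same data-set-average expression bins:
#' genes are ranked by average expression into `n_bins` bins and `n_ctrl`
#' controls per set gene are sampled from its bin (with replacement when
#' the bin is small). Centering against expression-matched controls removes
#' the depth and mean-expression component, so a random set scores ~0.
#'
#' @param expr genes x cells expression matrix (optionally
#'   neighbor-smoothed beforehand).
#' @param gene_set character vector of symbols (matched via
#'   [match_gene_set()]) or integer gene indices.
#' @param n_bins number of average-expression bins (default 25).
#' @param n_ctrl control genes per set gene (default 100).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return numeric per-cell score.
#' @export
module_score <- function(expr, gene_set, n_bins = 25L, n_ctrl = 100L,
                         seed = 1L) {
  genes <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  idx <- if (is.numeric(gene_set)) as.integer(gene_set)
         else match_gene_set(gene_set, genes)
  idx <- idx[idx >= 1 & idx <= nrow(expr)]
  if (!length(idx)) stop("gene set entirely absent from the expression matrix")
  avg <- Matrix::rowMeans(expr)
  ## genes with identically zero expression are excluded from binning and
  ## from the control pool, so adding such genes cannot change the score
  expressed <- which(avg > 0)
  idx <- idx[idx %in% expressed]
  if (!length(idx)) stop("no expressed gene-set member in the expression matrix")
  bin_of <- rep(NA_integer_, nrow(expr))
  bin_of[expressed] <- cut(rank(avg[expressed], ties.method = "first"),
                           breaks = n_bins, labels = FALSE)
  set.seed(as.integer(seed))
  ctrl <- unlist(lapply(idx, function(g) {
    pool <- expressed[bin_of[expressed] == bin_of[g]]
    pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
  }))
  set_mean <- Matrix::colMeans(expr[idx, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(expr[ctrl, , drop = FALSE])
  as.numeric(set_mean - ctrl_mean)
}
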