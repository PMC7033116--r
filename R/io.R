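#' Flag mitochondrial and ribosomal genes by symbol prefix
#'
#' @param gene character vector of gene symbols.
#' @param mito_prefix regular expression for mitochondrial genes
#'   (default `"^mt-"`, case-insensitive).
#' @param ribo_prefix regular expression for ribosomal genes
#'   (default `"^Rp[sl]"`).
#' @return data.frame: gene, mito, ribo.
#' @export
flag_genes <- function(gene, mito_prefix = "^mt-", ribo_prefix = "^Rp[sl]") {
  data.frame(gene = gene,
             mito = grepl(mito_prefix, gene, ignore.case = TRUE),
             ribo = grepl(ribo_prefix, gene),
             stringsAsFactors = FALSE)
}

#' Read a UMI count matrix bundle
#'
#' Accepts a directory holding a Matrix Market triplet
#' (`matrix.mtx`, `genes.tsv`, `barcodes.tsv`, optional `metadata.tsv`
#' and `ground_truth.tsv`), or a dense TSV file (genes in rows, first
#' column gene names, remaining columns cells). Orientation is normalized
#' to genes x cells using the gene/barcode table lengths (a transposed
#' matrix is auto-oriented with a message); entries must be non-negative
#' integers. Gene mito/ribo flags are attached from symbol prefixes.
#'
#' @param path directory or TSV file.
#' @param mito_prefix,ribo_prefix symbol rules passed to [flag_genes()].
#' @return list: `counts` (genes x cells dgCMatrix), `genes`, `metadata`
#'   (NULL when absent), `truth` (NULL when absent).
#' @export
read_counts <- function(path, mito_prefix = "^mt-", ribo_prefix = "^Rp[sl]") {
  metadata <- NULL; truth <- NULL
  if (dir.exists(path)) {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    genes <- utils::read.delim(file.path(path, "genes.tsv"),
                               header = FALSE, stringsAsFactors = FALSE)[, 1]
    barcodes <- utils::read.delim(file.path(path, "barcodes.tsv"),
                                  header = FALSE, stringsAsFactors = FALSE)[, 1]
    if (nrow(m) == length(barcodes) && ncol(m) == length(genes) &&
        length(genes) != length(barcodes)) {
      message("matrix stored cells x genes; transposing to genes x cells")
      m <- Matrix::t(m)
    }
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
      stop("matrix dimensions (", nrow(m), " x ", ncol(m),
           ") do not match genes.tsv/barcodes.tsv lengths")
    mf <- file.path(path, "metadata.tsv")
    if (file.exists(mf)) metadata <- utils::read.delim(mf, stringsAsFactors = FALSE)
    tf <- file.path(path, "ground_truth.tsv")
    if (file.exists(tf)) truth <- utils::read.delim(tf, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- tab[[1]]
    m <- as.matrix(tab[, -1, drop = FALSE])
    barcodes <- colnames(m)
  }
  v <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (any(v < 0) || any(v != floor(v)))
    stop("count matrix contains negative or non-integer entries")
  counts <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  dimnames(counts) <- list(genes, barcodes)
  list(counts = counts,
       genes = flag_genes(genes, mito_prefix, ribo_prefix),
       metadata = metadata, truth = truth)
}

#' Write a count matrix bundle
#'
#' Writes `matrix.mtx` (coordinate format, 1-based indices), `genes.tsv`,
#' `barcodes.tsv`, and when supplied `metadata.tsv` and
#' `ground_truth.tsv`, into `dir`.
#'
#' @param counts genes x cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @param metadata,truth optional per-cell tables.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(counts, dir, metadata = NULL, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  wr <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata)) wr(metadata, "metadata.tsv")
  if (!is.null(truth)) wr(truth, "ground_truth.tsv")
  invisible(dir)
}

#' Pipeline configuration
#'
#' Assembles and validates the full pipeline configuration. All thresholds
#' default to the study's stated values (100-gene floor, 15% mitochondrial
#' bound, 30-NN mixing neighborhoods, 3-SD and 10-NN refinement, 5%
#' expression filter). Unknown keys are rejected.
#'
#' @param seed master seed; every stochastic stage derives its own
#'   substream from it.
#' @param out_dir output directory.
#' @param sim a [sim_config()] for synthetic input, or NULL with `input`.
#' @param input path readable by [read_counts()] (used when `sim` is NULL).
#' @param ... overrides of the default stage parameters (see Details).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("scmixtraj_run_"),
                            sim = NULL, input = NULL, ...) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir, sim = sim, input = input,
    min_genes = 100L, max_genes = NULL, max_mito_frac = 0.15,
    scale_factor = 1e4, n_hvg = 500L, n_pcs = 10L,
    cluster_k = 20L, cluster_resolution = 1.0,
    mix_k = 30L, density_field = "genotype",
    refine_sd = 3, refine_k = 10L,
    de_min_frac = 0.05, traj_populations = c("basal_tumor", "CSC1", "CSC2",
                                             "luminal_Clu"),
    traj_root = "basal_tumor", traj_k_kernel = 15L, traj_n_comps = 10L,
    stage_min_cells = 5L, repro_min_cells = 10L,
    run_trajectory = TRUE, run_de = TRUE, run_composition = TRUE,
    run_density = TRUE, run_mixqc = TRUE, run_reproducibility = FALSE)
  extra <- list(...)
  unknown <- setdiff(names(extra), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(extra)] <- extra
  class(cfg) <- "pipeline_config"
  cfg
}

.log_stage <- function(log_path, stage, params, n_in, n_out) {
  line <- paste(stage, params, n_in, n_out, sep = "\t")
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate/ingest, knee demonstration, QC,
#' normalization, HVG selection, PCA, clustering, 2D embedding, mixing QC,
#' density contrast, refinement filters, composition tests, pseudobulk DE,
#' program scores, trajectory — writing one TSV per stage plus a structured
#' log and the fully resolved configuration into `config$out_dir`. Every
#' stochastic stage derives its seed from the master seed and the stage
#' name, so a rerun of the same configuration reproduces every output
#' byte-identically. A failing stage aborts with its name; earlier outputs
#' remain on disk.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline_log.tsv")
  cat("stage\tparams\tn_in\tn_out\n", file = log_path)
  dput(unclass(cfg), file = file.path(cfg$out_dir, "config_resolved.txt"),
       control = c("keepNA", "keepInteger", "showAttributes"))
  wr <- function(x, f) utils::write.table(
    x, file.path(cfg$out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list()

  ## --- input -------------------------------------------------------------
  res$data <- stage("input", function() {
    if (!is.null(cfg$sim)) {
      sc <- cfg$sim
      sc$seed <- .stage_seed(cfg$seed, "simulate")
      simulate_dataset(sc)
    } else if (!is.null(cfg$input)) read_counts(cfg$input)
    else stop("provide either sim or input")
  })
  d <- res$data
  .log_stage(log_path, "input", "", NA, ncol(d$counts))

  ## --- knee demonstration on a matched barcode mixture -------------------
  res$knee <- stage("knee", function() {
    mix <- simulate_barcode_mixture(
      n_real = 500L, n_ambient = 50000L,
      seed = .stage_seed(cfg$seed, "knee"))
    k <- knee_select(mix$totals)
    data.frame(selected = k, n_real = sum(mix$is_real),
               recovered_real = sum(mix$is_real[seq_len(k)]))
  })
  wr(res$knee, "knee.tsv")
  .log_stage(log_path, "knee", "", 50500L, res$knee$selected)

  ## --- QC ----------------------------------------------------------------
  res$qc <- stage("qc", function()
    qc_filter(d$counts, d$genes$mito, min_genes = cfg$min_genes,
              max_genes = cfg$max_genes, max_mito_frac = cfg$max_mito_frac))
  keep <- res$qc$keep
  wr(cbind(res$qc$qc, kept = keep), "qc.tsv")
  .log_stage(log_path, "qc", paste0("min_genes=", cfg$min_genes),
             ncol(d$counts), sum(keep))
  counts <- d$counts[, keep, drop = FALSE]
  meta <- d$metadata[keep, , drop = FALSE]
  truth <- if (!is.null(d$truth)) d$truth[keep, , drop = FALSE]

  ## --- normalize / HVG / PCA / cluster / embed ---------------------------
  expr <- stage("normalize", function()
    normalize_log(counts, scale_factor = cfg$scale_factor))
  hvg <- stage("hvg", function() select_hvg(expr, cfg$n_hvg))
  pca <- stage("pca", function()
    pca_embed(expr[hvg, , drop = FALSE], n_pcs = cfg$n_pcs))
  clusters <- stage("cluster", function()
    cluster_graph(pca$scores, k_neighbors = cfg$cluster_k,
                  resolution = cfg$cluster_resolution,
                  seed = .stage_seed(cfg$seed, "cluster")))
  emb <- stage("embed", function()
    embed_2d(pca$scores, seed = .stage_seed(cfg$seed, "embed")))
  res$cells <- data.frame(cell = meta$cell, meta[-1], cluster = clusters,
                          dim1 = emb[, 1], dim2 = emb[, 2])
  .log_stage(log_path, "cluster",
             paste0("resolution=", cfg$cluster_resolution),
             ncol(counts), length(unique(clusters)))

  ## --- mixing QC ----------------------------------------------------------
  if (cfg$run_mixqc) {
    res$mixing <- stage("mixqc", function() {
      nn <- knn_graph(pca$scores, k = cfg$mix_k)
      fm <- stats::setNames(
        paste(d$samples$genotype, d$samples$sex, d$samples$stage, sep = "_"),
        d$samples$sample)
      dec <- decompose_mixing(nn, meta$sample, fm)
      list(decomposition = dec,
           divergence = mixing_divergence(nn, meta$sample))
    })
    wr(cbind(cell = meta$cell, res$mixing$decomposition$per_cell),
       "mixing.tsv")
    .log_stage(log_path, "mixqc", paste0("k=", cfg$mix_k), ncol(counts),
               round(res$mixing$decomposition$fraction_between, 4))
  }

  ## --- density contrast ---------------------------------------------------
  if (cfg$run_density && length(unique(meta[[cfg$density_field]])) == 2L) {
    res$density <- stage("density", function()
      relative_log_density(emb, meta[[cfg$density_field]]))
    wr(data.frame(cell = meta$cell, log2_ratio = res$density$log2_ratio),
       "density.tsv")
    .log_stage(log_path, "density", cfg$density_field, ncol(counts), NA)
  }

  ## --- refinement ---------------------------------------------------------
  res$refined <- stage("refine", function() {
    k1 <- centroid_outlier_filter(emb, clusters, n_sd = cfg$refine_sd)
    k2 <- knn_majority_filter(emb, clusters, k = cfg$refine_k)
    k1 & k2
  })
  wr(data.frame(cell = meta$cell, kept = res$refined), "refined.tsv")
  .log_stage(log_path, "refine", "", ncol(counts), sum(res$refined))

  ## --- composition --------------------------------------------------------
  if (cfg$run_composition) {
    res$composition <- stage("composition", function() {
      ct <- table(meta$sample[res$refined], meta$celltype[res$refined])
      des <- d$samples[match(rownames(ct), d$samples$sample), ]
      fe <- intersect(c("genotype", "sex", "stage"), names(des))
      fe <- fe[vapply(fe, function(f) length(unique(des[[f]])) > 1L, logical(1))]
      tests <- lapply(colnames(ct), function(cl) {
        out <- tryCatch(composition_test(unclass(ct), des, cl,
                                         fixed_effects = fe),
                        error = function(e) NULL)
        if (!is.null(out)) cbind(cluster = cl, out)
      })
      do.call(rbind, tests)
    })
    if (!is.null(res$composition)) wr(res$composition, "composition.tsv")
    .log_stage(log_path, "composition", "", length(unique(meta$celltype)), NA)
  }

  ## --- pseudobulk DE -------------------------------------------------------
  if (cfg$run_de) {
    res$de <- stage("de", function() {
      md <- meta; md$all <- "all"
      pb <- aggregate_pseudobulk(counts, md, "all")
      gm <- expression_fraction_filter(counts, seq_len(ncol(counts)),
                                       cfg$de_min_frac)
      pb$counts <- pb$counts[gm, , drop = FALSE]
      nb_wald_test(pb, "genotype")
    })
    wr(as.data.frame(res$de), "de_genotype.tsv")
    .log_stage(log_path, "de", "wald_genotype", nrow(res$de),
               sum(res$de$q < 0.1, na.rm = TRUE))
  }

  ## --- trajectory ----------------------------------------------------------
  if (cfg$run_trajectory) {
    res$trajectory <- stage("trajectory", function() {
      tumor <- which(meta$celltype %in% cfg$traj_populations)
      if (length(tumor) < cfg$traj_n_comps + 2L)
        stop("too few trajectory-population cells (", length(tumor), ")")
      sub <- expr[hvg, tumor, drop = FALSE]
      dm <- diffusion_map(sub, n_comps = min(cfg$traj_n_comps,
                                             length(tumor) - 2L),
                          k_kernel = min(cfg$traj_k_kernel,
                                         length(tumor) - 2L))
      dpt <- diffusion_pseudotime(dm, root_cluster = cfg$traj_root,
                                  labels = meta$celltype[tumor])
      curve <- fit_trajectory_curve(dm$coords[, 1:2, drop = FALSE],
                                    dpt$pseudotime)
      shift <- tryCatch(
        stage_shift_test(dpt$pseudotime, meta[tumor, , drop = FALSE],
                         min_cells = cfg$stage_min_cells),
        error = function(e) NULL)
      repro <- if (cfg$run_reproducibility)
        per_sample_reproducibility(sub, meta$sample[tumor], dpt$pseudotime,
                                   min_cells = cfg$repro_min_cells)
      list(cells = tumor, dmap = dm, dpt = dpt, curve = curve,
           shift = shift, reproducibility = repro)
    })
    tr <- res$trajectory
    wr(data.frame(cell = meta$cell[tr$cells],
                  population = meta$celltype[tr$cells],
                  tr$dmap$coords[, 1:2, drop = FALSE],
                  pseudotime = tr$dpt$pseudotime), "trajectory.tsv")
    wr(tr$curve, "trajectory_curve.tsv")
    if (!is.null(tr$repro)) wr(tr$repro, "trajectory_reproducibility.tsv")
    .log_stage(log_path, "trajectory", "", length(tr$cells),
               if (!is.null(tr$shift)) round(tr$shift$p, 6) else NA)
  }
  invisible(res)
}
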