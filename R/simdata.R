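#' Configuration for the synthetic tumor single-cell dataset
#'
#' Builds the parameter list consumed by [simulate_dataset()]. The defaults
#' emulate a two-genotype mouse salivary-gland tumor study: 12 control and 14
#' double-mutant samples of either sex at an early (P40) and a late (P90)
#' stage, sequenced to a median depth of roughly 1000 UMIs and 500 detected
#' genes per cell. Double-mutant samples carry four tumor-specific
#' populations laid out along a latent pseudotime axis t in [0,1]:
#' basal tumor cells, two rare cancer-stem-cell-like populations (CSC1,
#' CSC2) and luminal Clu+ cells, with an EMT program that decays early, a
#' Wnt program peaking mid-trajectory and a luminal program rising late.
#'
#' @param n_genes number of genes.
#' @param n_samples_control,n_samples_mutant numbers of biological samples
#'   per genotype.
#' @param cells_per_sample cells per sample; a single count or a length-2
#'   range sampled uniformly.
#' @param celltype_table data.frame with columns `name`, `base_proportion`,
#'   `n_markers` describing the non-tumor cell types. Proportions are
#'   renormalized over non-tumor cells.
#' @param tumor_populations data.frame with columns `name`, `t_min`, `t_max`
#'   giving the ordered pseudotime windows of the four tumor populations.
#'   Windows must tile [0,1] in order.
#' @param base_tumor_prop probability that a control cell belongs to the
#'   tumor lineage (log-odds baseline).
#' @param genotype_effect log-odds shift of tumor-lineage membership in
#'   double-mutant samples; 0 gives a null dataset with exchangeable
#'   genotypes.
#' @param sex_effect log-odds shift of the duct population in male samples
#'   (sexual dimorphism of the gland); 0 disables it.
#' @param stage_effect list with Beta parameters `p40 = c(a, b)` and
#'   `p90 = c(a, b)` for the pseudotime distribution at each stage. Equal
#'   parameters make stages exchangeable.
#' @param program_params list of `(center, width, amplitude)` for the
#'   `emt` (decreasing sigmoid), `wnt` (Gaussian bump) and `luminal`
#'   (increasing sigmoid) programs.
#' @param n_program_genes genes per expression program block.
#' @param library_size list with `median` and `sdlog` of the log-normal
#'   per-cell library size.
#' @param baseline_sdlog sd (log scale) of baseline gene expression
#'   weights; 1.4 reproduces the ~500-gene / ~1000-UMI depth target.
#' @param nb_dispersion per-gene negative-binomial dispersion (1/size).
#' @param mito_fraction_mean expected fraction of reads from mitochondrial
#'   genes.
#' @param n_mito_genes,n_ribo_genes numbers of genes flagged with `mt-` and
#'   `Rps`/`Rpl` prefixes.
#' @param batch_effect_sd sd of the per-sample log-scale batch effect.
#' @param marker_lfc natural-log offset of cell-type marker genes in their
#'   cell type.
#' @param tumor_marker_lfc natural-log offset of the tumor subpopulations'
#'   state-specific genes; weaker than `marker_lfc` because the tumor
#'   compartment is a continuum of program states with continuous
#'   transitions, not a set of discrete cell types.
#' @param seed integer master seed.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_samples_control = 12L,
                       n_samples_mutant = 14L,
                       cells_per_sample = 100L,
                       celltype_table = NULL,
                       tumor_populations = NULL,
                       base_tumor_prop = 0.05,
                       genotype_effect = 2.0,
                       sex_effect = 0,
                       stage_effect = list(p40 = c(2, 4), p90 = c(4, 2)),
                       program_params = list(
                         emt     = c(center = 0.35, width = 0.08, amplitude = 2.5),
                         wnt     = c(center = 0.45, width = 0.07, amplitude = 1.2),
                         luminal = c(center = 0.75, width = 0.08, amplitude = 2.5)),
                       n_program_genes = 40L,
                       library_size = list(median = 1000, sdlog = 0.35),
                       baseline_sdlog = 1.4,
                       nb_dispersion = 0.3,
                       mito_fraction_mean = 0.05,
                       n_mito_genes = 10L,
                       n_ribo_genes = 40L,
                       batch_effect_sd = 0.1,
                       marker_lfc = 2.0,
                       tumor_marker_lfc = 1.0,
                       seed = 1L) {
  if (is.null(celltype_table)) {
    celltype_table <- data.frame(
      name = c("acinar", "duct", "immune", "basal_normal"),
      base_proportion = c(0.45, 0.25, 0.15, 0.15),
      n_markers = c(30L, 30L, 30L, 30L))
  }
  if (is.null(tumor_populations)) {
    tumor_populations <- data.frame(
      name = c("basal_tumor", "CSC1", "CSC2", "luminal_Clu"),
      t_min = c(0, 0.35, 0.5, 0.7),
      t_max = c(0.35, 0.5, 0.7, 1))
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_samples_control = as.integer(n_samples_control),
    n_samples_mutant = as.integer(n_samples_mutant),
    cells_per_sample = cells_per_sample,
    celltype_table = celltype_table,
    tumor_populations = tumor_populations,
    base_tumor_prop = base_tumor_prop,
    genotype_effect = genotype_effect,
    sex_effect = sex_effect,
    stage_effect = stage_effect,
    program_params = program_params,
    n_program_genes = as.integer(n_program_genes),
    library_size = library_size,
    baseline_sdlog = baseline_sdlog,
    nb_dispersion = nb_dispersion,
    mito_fraction_mean = mito_fraction_mean,
    n_mito_genes = as.integer(n_mito_genes),
    n_ribo_genes = as.integer(n_ribo_genes),
    batch_effect_sd = batch_effect_sd,
    marker_lfc = marker_lfc,
    tumor_marker_lfc = tumor_marker_lfc,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  tp <- cfg$tumor_populations
  if (nrow(tp) < 1L) stop("tumor_populations must have at least one row")
  if (abs(tp$t_min[1]) > 1e-12 || abs(tp$t_max[nrow(tp)] - 1) > 1e-12)
    stop("pseudotime windows must start at 0 and end at 1")
  for (i in seq_len(nrow(tp))) {
    if (tp$t_max[i] <= tp$t_min[i])
      stop("empty pseudotime window for population '", tp$name[i], "'")
    if (i > 1L && abs(tp$t_min[i] - tp$t_max[i - 1L]) > 1e-12)
      stop("pseudotime windows must tile [0,1]: gap or overlap at population '",
           tp$name[i], "'")
  }
  if (cfg$base_tumor_prop <= 0 || cfg$base_tumor_prop >= 1)
    stop("base_tumor_prop must be in (0,1)")
  ct <- cfg$celltype_table
  if (any(ct$base_proportion <= 0)) stop("celltype base proportions must be positive")
  invisible(cfg)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Latent expression-program activities along tumor pseudotime
#'
#' EMT is a decreasing sigmoid, Wnt a Gaussian bump and the luminal program
#' an increasing sigmoid of pseudotime t in [0,1].
#'
#' @param t pseudotime vector.
#' @param params program parameter list as in [sim_config()].
#' @return matrix with columns `emt`, `wnt`, `luminal`, values in [0,1].
#' @export
program_activity <- function(t, params = sim_config()$program_params) {
  e <- params$emt; w <- params$wnt; l <- params$luminal
  cbind(
    emt = 1 - sigmoid((t - e[["center"]]) / e[["width"]]),
    wnt = exp(-(t - w[["center"]])^2 / (2 * w[["width"]]^2)),
    luminal = sigmoid((t - l[["center"]]) / l[["width"]]))
}

#' Simulate a multi-sample tumor single-cell dataset with ground truth
#'
#' Draws per-cell UMI counts gene-wise from a negative binomial whose mean is
#' `library_size x expression profile`, where the log expression profile is
#' baseline + cell-type marker offsets + program loadings x program(t) +
#' a per-sample batch effect. Mitochondrial genes receive a fixed expected
#' share of reads. The same seed gives bit-identical output.
#'
#' @param config a [sim_config()] object.
#' @return list with `counts` (genes x cells dgCMatrix, dimnames set),
#'   `genes` (data.frame: gene, mito, ribo, program/marker annotation),
#'   `metadata` (per cell: cell, sample, genotype, sex, stage, celltype),
#'   `truth` (per cell: true population label, true pseudotime t — NA for
#'   non-tumor cells), and `samples` (per-sample design table).
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)

  ## sample design: genotype x sex x stage, balanced as far as counts allow
  n_s <- cfg$n_samples_control + cfg$n_samples_mutant
  genotype <- rep(c("control", "double_mutant"),
                  c(cfg$n_samples_control, cfg$n_samples_mutant))
  mk_balanced <- function(n, lev) lev[(seq_len(n) - 1L) %% length(lev) + 1L]
  sex <- c(mk_balanced(cfg$n_samples_control, c("F", "M")),
           mk_balanced(cfg$n_samples_mutant, c("F", "M")))
  stage <- c(mk_balanced(cfg$n_samples_control, c("P40", "P90")),
             mk_balanced(cfg$n_samples_mutant, c("P90", "P40")))
  samples <- data.frame(
    sample = sprintf("S%02d_%s", seq_len(n_s), ifelse(genotype == "control", "ctl", "mut")),
    genotype = genotype, sex = sex, stage = stage,
    stringsAsFactors = FALSE)

  ## gene universe and annotation
  ng <- cfg$n_genes
  gene <- sprintf("Gene%04d", seq_len(ng))
  idx <- 1L
  take <- function(n) { out <- idx:(idx + n - 1L); idx <<- idx + n; out }
  if (idx + cfg$n_mito_genes + cfg$n_ribo_genes > ng)
    stop("n_genes too small for requested mito/ribo blocks")
  mito_idx <- take(cfg$n_mito_genes)
  ribo_idx <- take(cfg$n_ribo_genes)
  gene[mito_idx] <- sprintf("mt-Sim%02d", seq_along(mito_idx))
  gene[ribo_idx] <- sprintf("%s%02d", rep(c("Rps", "Rpl"), length.out = length(ribo_idx)),
                            seq_along(ribo_idx))
  ct <- cfg$celltype_table
  marker_idx <- lapply(seq_len(nrow(ct)), function(i) take(ct$n_markers[i]))
  names(marker_idx) <- ct$name
  tp <- cfg$tumor_populations
  pop_marker_idx <- lapply(seq_len(nrow(tp)), function(i) take(15L))
  names(pop_marker_idx) <- tp$name
  prog_idx <- list(emt = take(cfg$n_program_genes),
                   wnt = take(cfg$n_program_genes),
                   luminal = take(cfg$n_program_genes))
  if (idx > ng) stop("n_genes too small for marker/program blocks")

  baseline <- stats::rnorm(ng, 0, cfg$baseline_sdlog)
  batch <- stats::rnorm(n_s, 0, cfg$batch_effect_sd)

  ## per-cell assignment
  ncells <- if (length(cfg$cells_per_sample) == 2L)
    sample(cfg$cells_per_sample[1]:cfg$cells_per_sample[2], n_s, replace = TRUE)
  else rep(as.integer(cfg$cells_per_sample), n_s)
  total <- sum(ncells)
  cell_sample <- rep(seq_len(n_s), ncells)

  logit <- function(p) log(p / (1 - p))
  p_tumor <- sigmoid(logit(cfg$base_tumor_prop) +
                       cfg$genotype_effect * (genotype == "double_mutant"))
  is_tumor <- stats::rbinom(total, 1L, p_tumor[cell_sample]) == 1L

  ## non-tumor cell types; sex effect shifts the duct proportion
  base_prop <- ct$base_proportion / sum(ct$base_proportion)
  celltype <- character(total)
  true_t <- rep(NA_real_, total)
  pop <- character(total)
  for (s in seq_len(n_s)) {
    in_s <- which(cell_sample == s)
    tum <- in_s[is_tumor[in_s]]
    non <- in_s[!is_tumor[in_s]]
    pr <- base_prop
    if (cfg$sex_effect != 0 && samples$sex[s] == "M" && "duct" %in% ct$name) {
      lo <- log(pr) # multiplicative shift on duct, renormalize
      lo[ct$name == "duct"] <- lo[ct$name == "duct"] + cfg$sex_effect
      pr <- exp(lo) / sum(exp(lo))
    }
    celltype[non] <- sample(ct$name, length(non), replace = TRUE, prob = pr)
    if (length(tum)) {
      ab <- if (samples$stage[s] == "P40") cfg$stage_effect$p40 else cfg$stage_effect$p90
      tt <- stats::rbeta(length(tum), ab[1], ab[2])
      true_t[tum] <- tt
      win <- findInterval(tt, c(tp$t_min, 1), rightmost.closed = TRUE)
      win[win > nrow(tp)] <- nrow(tp)
      pop[tum] <- tp$name[win]
      celltype[tum] <- pop[tum]
    }
  }
  pop[!is_tumor] <- NA_character_

  ## expression means per cell: exp(baseline + offsets), mito share fixed
  amp <- vapply(cfg$program_params, function(p) p[["amplitude"]], numeric(1))
  act <- matrix(0, total, 3, dimnames = list(NULL, c("emt", "wnt", "luminal")))
  act[is_tumor, ] <- program_activity(true_t[is_tumor], cfg$program_params)

  lib <- stats::rlnorm(total, log(cfg$library_size$median), cfg$library_size$sdlog)

  ## build counts sample-block-wise to bound memory
  counts_blocks <- vector("list", n_s)
  size <- 1 / cfg$nb_dispersion
  for (s in seq_len(n_s)) {
    in_s <- which(cell_sample == s)
    loff <- matrix(baseline + batch[s], ng, length(in_s))
    for (i in seq_len(nrow(ct))) {
      hit <- celltype[in_s] == ct$name[i]
      if (any(hit)) loff[marker_idx[[i]], hit] <- loff[marker_idx[[i]], hit] + cfg$marker_lfc
    }
    for (i in seq_len(nrow(tp))) {
      hit <- !is.na(pop[in_s]) & pop[in_s] == tp$name[i]
      if (any(hit)) loff[pop_marker_idx[[i]], hit] <-
          loff[pop_marker_idx[[i]], hit] + cfg$tumor_marker_lfc
    }
    for (pg in names(prog_idx)) {
      a <- act[in_s, pg]
      if (any(a > 0)) loff[prog_idx[[pg]], ] <-
          loff[prog_idx[[pg]], ] + amp[[pg]] * rep(a, each = cfg$n_program_genes)
    }
    w <- exp(loff)
    ## mitochondrial genes take a fixed expected share of each cell's reads
    w[mito_idx, ] <- 0
    w <- sweep(w, 2, colSums(w), "/") * (1 - cfg$mito_fraction_mean)
    w[mito_idx, ] <- cfg$mito_fraction_mean / length(mito_idx)
    mu <- sweep(w, 2, lib[in_s], "*")
    cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = size),
                  ng, length(in_s))
    counts_blocks[[s]] <- methods::as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix")
  }
  counts <- do.call(cbind, counts_blocks)
  barcodes <- sprintf("cell%05d", seq_len(total))
  dimnames(counts) <- list(gene, barcodes)

  genes <- data.frame(
    gene = gene,
    mito = seq_len(ng) %in% mito_idx,
    ribo = seq_len(ng) %in% ribo_idx,
    stringsAsFactors = FALSE)
  genes$block <- "baseline"
  for (nm in names(marker_idx)) genes$block[marker_idx[[nm]]] <- paste0("marker_", nm)
  for (nm in names(pop_marker_idx)) genes$block[pop_marker_idx[[nm]]] <- paste0("marker_", nm)
  for (nm in names(prog_idx)) genes$block[prog_idx[[nm]]] <- paste0("program_", nm)
  genes$block[mito_idx] <- "mito"
  genes$block[ribo_idx] <- "ribo"

  metadata <- data.frame(
    cell = barcodes,
    sample = samples$sample[cell_sample],
    genotype = samples$genotype[cell_sample],
    sex = samples$sex[cell_sample],
    stage = samples$stage[cell_sample],
    celltype = celltype,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    cell = barcodes,
    population = pop,
    t = true_t,
    stringsAsFactors = FALSE)

  list(counts = counts, genes = genes, metadata = metadata,
       truth = truth, samples = samples, config = cfg)
}

#' Simulate droplet barcode totals: real cells over an ambient tail
#'
#' Produces the total-UMI-per-barcode vector a droplet run yields before cell
#' calling: `n_real` log-normal real-cell barcodes over `n_ambient`
#' exponential-tail ambient barcodes. `real_depth` should be well above
#' `ambient_depth` (>= 10x recommended) for a visible knee.
#'
#' @param n_real,n_ambient barcode counts; `n_real` must be positive.
#' @param real_depth,ambient_depth mean total UMIs for real and ambient
#'   barcodes.
#' @param sdlog_real sd (log) of real-cell totals.
#' @param seed integer seed.
#' @return list with `totals` (sorted descending) and `is_real` (logical,
#'   aligned with `totals`) for oracle use.
#' @export
simulate_barcode_mixture <- function(n_real, n_ambient,
                                     real_depth = 1000, ambient_depth = 20,
                                     sdlog_real = 0.3, seed = 1L) {
  if (n_real < 1L) stop("n_real must be positive: no knee exists without real cells")
  set.seed(as.integer(seed))
  real <- stats::rlnorm(n_real, log(real_depth), sdlog_real)
  amb <- if (n_ambient > 0L) stats::rexp(n_ambient, 1 / ambient_depth) else numeric(0)
  totals <- round(c(real, amb)) + 1
  is_real <- rep(c(TRUE, FALSE), c(n_real, n_ambient))
  o <- order(totals, decreasing = TRUE)
  list(totals = totals[o], is_real = is_real[o])
}
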