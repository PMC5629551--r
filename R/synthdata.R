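# Synthetic cohort generator: planted process -> pathway -> TF -> gene
# hierarchy, Gaussian tissue controls, CNV expression shifts, subtype-
# enriched mutations, and subtype-dependent exponential survival.

#' Construct a planted latent regulatory hierarchy
#'
#' Builds the three-level latent structure (biological processes at the top,
#' signaling pathways in the middle, transcription factors at the bottom)
#' that drives synthetic tumor expression. Genes are partitioned among TFs,
#' TFs among pathways, and pathways among processes, so every gene is
#' targeted by exactly one TF and every latent unit has at least one child.
#' Each TF is assigned a fixed direction of effect (up or down,
#' Bernoulli(0.5)) and shifts its target genes by \code{effect_size} control
#' standard deviations when active.
#'
#' @param n_genes Number of genes in the cohort.
#' @param n_processes,n_pathways,n_tfs Sizes of the three latent levels;
#'   must satisfy \code{n_processes <= n_pathways <= n_tfs <= n_genes}.
#' @param effect_size Nonnegative standardized expression shift (in control
#'   SD units) applied to a TF's target genes when the TF is active.
#' @param seed Integer seed; the hierarchy is a pure function of its
#'   arguments and this seed.
#' @return An object of class \code{latent_hierarchy} with the membership
#'   maps \code{tf_to_genes}, \code{pathway_to_tfs},
#'   \code{process_to_pathways} and per-TF signs \code{tf_direction}.
#' @export
latent_hierarchy <- function(n_genes, n_processes = 3L, n_pathways = 6L,
                             n_tfs = 12L, effect_size = 3, seed = 1L) {
  stopifnot(n_processes >= 1L, n_pathways >= n_processes, n_tfs >= n_pathways,
            n_genes >= n_tfs)
  if (effect_size < 0) stop("effect_size must be >= 0")
  set.seed(seed)
  # random partition with guaranteed coverage: shuffle then deal round-robin
  tf_of_gene <- sample(rep_len(seq_len(n_tfs), n_genes))
  pathway_of_tf <- sample(rep_len(seq_len(n_pathways), n_tfs))
  process_of_pathway <- sample(rep_len(seq_len(n_processes), n_pathways))
  h <- list(
    n_processes = as.integer(n_processes),
    n_pathways = as.integer(n_pathways),
    n_tfs = as.integer(n_tfs),
    n_genes = as.integer(n_genes),
    tf_to_genes = split(seq_len(n_genes), factor(tf_of_gene, seq_len(n_tfs))),
    pathway_to_tfs = split(seq_len(n_tfs),
                           factor(pathway_of_tf, seq_len(n_pathways))),
    process_to_pathways = split(seq_len(n_pathways),
                                factor(process_of_pathway,
                                       seq_len(n_processes))),
    tf_direction = sample(c(-1, 1), n_tfs, replace = TRUE),
    effect_size = effect_size
  )
  class(h) <- "latent_hierarchy"
  h
}

#' @export
print.latent_hierarchy <- function(x, ...) {
  cat(sprintf(
    "latent_hierarchy: %d processes -> %d pathways -> %d TFs -> %d genes, effect size %.2f SD\n",
    x$n_processes, x$n_pathways, x$n_tfs, x$n_genes, x$effect_size))
  invisible(x)
}

#' Configuration for a synthetic cohort
#'
#' Collects the generative parameters for [generate_cohort()]. Defaults give
#' a small multi-tissue cohort with three planted tumor subtypes, clearly
#' separated expression programs, sparse copy-number events that shift
#' expression, subtype-enriched driver mutations, and exponential survival
#' with subtype-specific hazard ratios plus independent exponential
#' censoring (rate chosen for roughly 30% censoring).
#'
#' @param n_tissues Number of tissue types.
#' @param tumors_per_tissue,controls_per_tissue Samples per tissue.
#' @param n_genes Genes in the cohort.
#' @param n_subtypes Planted tumor subtypes; must not exceed the number of
#'   distinct non-empty process-activation patterns
#'   (\code{2^n_processes - 1}).
#' @param hierarchy A [latent_hierarchy()]; built from the other arguments
#'   when \code{NULL}.
#' @param control_mean_range,control_sd_range Uniform sampling intervals for
#'   per-(gene, tissue) control Gaussian parameters. The lower mean bound
#'   must be at least 5 upper-bound SDs above zero so the expression scale
#'   is strictly positive and fold changes are well defined.
#' @param cnv_rate Per-(tumor, gene) probability of a copy-number event
#'   (amplification or deletion, equally likely).
#' @param cnv_expression_shift Expression shift (control SD units) added
#'   with the sign of the copy-number event.
#' @param mutations_per_subtype Number of driver genes planted per subtype.
#' @param mutation_enrichment Probability a tumor carries a driver mutation
#'   of its own subtype.
#' @param mutation_background Background mutation probability for all other
#'   (tumor, gene) pairs.
#' @param baseline_hazard Event hazard (events per time unit) for subtype 1.
#' @param subtype_hazard_ratios Positive hazard ratios, one per subtype
#'   (relative to baseline). Default spaces subtypes geometrically by 2x.
#' @param censoring_hazard Rate of the independent exponential censoring
#'   time; default \code{3/7} of the mean subtype hazard, giving ~30%
#'   censoring.
#' @param seed Integer seed; generation is byte-reproducible given the
#'   config.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_tissues = 2L, tumors_per_tissue = 100L,
                          controls_per_tissue = 30L, n_genes = 200L,
                          n_subtypes = 3L, hierarchy = NULL,
                          control_mean_range = c(8, 12),
                          control_sd_range = c(0.4, 1.2),
                          cnv_rate = 0.02, cnv_expression_shift = 4,
                          mutations_per_subtype = 3L,
                          mutation_enrichment = 0.6,
                          mutation_background = 0.05,
                          baseline_hazard = 0.1,
                          subtype_hazard_ratios = 2^(seq_len(n_subtypes) - 1),
                          censoring_hazard = NULL,
                          effect_size = 3, seed = 1L) {
  counts <- c(n_tissues, tumors_per_tissue, controls_per_tissue, n_genes,
              n_subtypes)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (mutations_per_subtype < 0) stop("mutations_per_subtype must be >= 0")
  probs <- c(cnv_rate, mutation_enrichment, mutation_background)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(subtype_hazard_ratios <= 0)) stop("hazard ratios must be > 0")
  if (length(subtype_hazard_ratios) != n_subtypes)
    stop("subtype_hazard_ratios must have length n_subtypes")
  if (any(control_sd_range <= 0) || diff(control_sd_range) < 0 ||
      diff(control_mean_range) < 0)
    stop("control parameter ranges must be positive, nondecreasing intervals")
  if (control_mean_range[1] < 5 * control_sd_range[2])
    stop("control means must be bounded away from 0 by >= 5 SD ",
         "(raise control_mean_range or lower control_sd_range)")
  if (is.null(hierarchy))   # scale latent-level sizes down for tiny cohorts
    hierarchy <- latent_hierarchy(n_genes,
                                  n_processes = min(3L, n_genes),
                                  n_pathways = min(6L, n_genes),
                                  n_tfs = min(12L, n_genes),
                                  effect_size = effect_size, seed = seed)
  if (hierarchy$n_genes != n_genes)
    stop("hierarchy was built for a different number of genes")
  if (n_subtypes > 2^hierarchy$n_processes - 1)
    stop("n_subtypes exceeds the number of distinct activatable ",
         "process combinations (2^n_processes - 1)")
  if (is.null(censoring_hazard))
    censoring_hazard <- (3 / 7) * baseline_hazard * mean(subtype_hazard_ratios)
  cfg <- list(
    n_tissues = as.integer(n_tissues),
    tumors_per_tissue = as.integer(tumors_per_tissue),
    controls_per_tissue = as.integer(controls_per_tissue),
    n_genes = as.integer(n_genes),
    n_subtypes = as.integer(n_subtypes),
    hierarchy = hierarchy,
    control_mean_range = control_mean_range,
    control_sd_range = control_sd_range,
    cnv_rate = cnv_rate,
    cnv_expression_shift = cnv_expression_shift,
    mutations_per_subtype = as.integer(mutations_per_subtype),
    mutation_enrichment = mutation_enrichment,
    mutation_background = mutation_background,
    baseline_hazard = baseline_hazard,
    subtype_hazard_ratios = subtype_hazard_ratios,
    censoring_hazard = censoring_hazard,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

# Deterministic subtype -> process activation code: distinct non-empty
# process subsets ordered by size then lexicographically, so subtype 1..p
# activate single processes, then pairs, etc. Identifiable by construction.
subtype_process_code <- function(n_subtypes, n_processes) {
  combos <- expand.grid(rep(list(c(0L, 1L)), n_processes))
  combos <- as.matrix(combos[rowSums(combos) > 0L, , drop = FALSE])
  ord <- order(rowSums(combos), apply(combos, 1L, function(r)
    -sum(r * 2^(seq_along(r) - 1))))
  code <- combos[ord[seq_len(n_subtypes)], , drop = FALSE]
  dimnames(code) <- list(paste0("subtype", seq_len(n_subtypes)),
                         paste0("process", seq_len(n_processes)))
  code
}

# Per-gene standardized shift (in control-SD units) for one subtype:
# active processes cascade deterministically to pathways, TFs, genes.
subtype_gene_shift <- function(h, active_processes) {
  shift <- numeric(h$n_genes)
  pathways <- unique(unlist(h$process_to_pathways[active_processes]))
  tfs <- unique(unlist(h$pathway_to_tfs[pathways]))
  for (tf in tfs)
    shift[h$tf_to_genes[[tf]]] <- shift[h$tf_to_genes[[tf]]] +
      h$tf_direction[tf] * h$effect_size
  shift
}

#' Generate a synthetic expression cohort
#'
#' Draws controls per gene and tissue from Gaussians with parameters sampled
#' from the config ranges, assigns each tumor a subtype whose active
#' processes cascade down the latent hierarchy to shift TF target genes,
#' overlays copy-number events that move expression in the matching
#' direction, plants subtype-enriched driver mutations, and draws survival
#' from an exponential model with subtype-specific hazard ratios and
#' independent exponential censoring. A fixed seed gives byte-identical
#' output.
#'
#' @param config A [cohort_config()].
#' @return An object of class \code{expression_cohort}: a list with the
#'   samples-by-genes \code{expression} matrix, \code{sample_ids},
#'   \code{gene_ids}, \code{tissue}, \code{is_tumor}, discrete
#'   \code{cnv} scores in \{-1, 0, +1\}, binary \code{mutations},
#'   per-tumor \code{survival_time}/\code{survival_event}, the planted
#'   \code{true_subtype} (NA for controls) and the generating config.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  h <- cfg$hierarchy
  set.seed(cfg$seed)

  n_per_tissue <- cfg$tumors_per_tissue + cfg$controls_per_tissue
  n <- cfg$n_tissues * n_per_tissue
  G <- cfg$n_genes
  gene_ids <- sprintf("G%04d", seq_len(G))
  sample_ids <- sprintf("S%04d", seq_len(n))
  tissue <- rep(paste0("tissue", seq_len(cfg$n_tissues)), each = n_per_tissue)
  is_tumor <- rep(rep(c(1L, 0L), c(cfg$tumors_per_tissue,
                                   cfg$controls_per_tissue)), cfg$n_tissues)

  # per-(gene, tissue) control Gaussian parameters
  mu <- matrix(runif(G * cfg$n_tissues, cfg$control_mean_range[1],
                     cfg$control_mean_range[2]), G, cfg$n_tissues)
  sg <- matrix(runif(G * cfg$n_tissues, cfg$control_sd_range[1],
                     cfg$control_sd_range[2]), G, cfg$n_tissues)

  # subtype labels: round-robin within tissue, then shuffled, so all
  # subtypes are represented whenever tumors_per_tissue >= n_subtypes
  true_subtype <- rep(NA_integer_, n)
  for (t in seq_len(cfg$n_tissues)) {
    idx <- which(tissue == paste0("tissue", t) & is_tumor == 1L)
    true_subtype[idx] <- sample(rep_len(seq_len(cfg$n_subtypes), length(idx)))
  }

  code <- subtype_process_code(cfg$n_subtypes, h$n_processes)
  shifts <- t(vapply(seq_len(cfg$n_subtypes), function(s)
    subtype_gene_shift(h, which(code[s, ] == 1L)), numeric(G)))

  expr <- matrix(NA_real_, n, G, dimnames = list(sample_ids, gene_ids))
  cnv <- matrix(0L, n, G, dimnames = list(sample_ids, gene_ids))
  for (t in seq_len(cfg$n_tissues)) {
    idx <- which(tissue == paste0("tissue", t))
    base <- matrix(rnorm(length(idx) * G, mean = rep(mu[, t], each = length(idx)),
                         sd = rep(sg[, t], each = length(idx))),
                   length(idx), G)
    sub <- true_subtype[idx]
    tum <- which(!is.na(sub))
    base[tum, ] <- base[tum, ] +
      shifts[sub[tum], , drop = FALSE] * rep(sg[, t], each = length(tum))
    # copy-number events (tumors only) shift expression with matching sign
    if (cfg$cnv_rate > 0 && length(tum)) {
      ev <- matrix(runif(length(tum) * G) < cfg$cnv_rate, length(tum), G)
      sign_ev <- matrix(sample(c(-1L, 1L), length(tum) * G, replace = TRUE),
                        length(tum), G) * ev
      cnv[idx[tum], ] <- sign_ev
      base[tum, ] <- base[tum, ] +
        sign_ev * cfg$cnv_expression_shift * rep(sg[, t], each = length(tum))
    }
    expr[idx, ] <- base
  }

  # subtype-enriched driver mutations on disjoint seeded gene sets
  # (mutations_per_subtype = 0 disables driver planting)
  n_drivers <- cfg$mutations_per_subtype * cfg$n_subtypes
  if (n_drivers > G)
    stop("more planted driver genes than genes; lower mutations_per_subtype")
  mut <- matrix(0L, n, G, dimnames = list(sample_ids, gene_ids))
  tum_all <- which(is_tumor == 1L)
  mut[tum_all, ] <- matrix(
    as.integer(runif(length(tum_all) * G) < cfg$mutation_background),
    length(tum_all), G)
  driver_genes <- NULL
  if (n_drivers > 0L) {
    driver_pool <- sample(G, n_drivers)
    driver_genes <- split(driver_pool,
                          rep(seq_len(cfg$n_subtypes),
                              each = cfg$mutations_per_subtype))
    names(driver_genes) <- paste0("subtype", seq_len(cfg$n_subtypes))
    for (s in seq_len(cfg$n_subtypes)) {
      idx <- which(!is.na(true_subtype) & true_subtype == s)
      for (g in driver_genes[[s]])
        mut[idx, g] <- as.integer(runif(length(idx)) < cfg$mutation_enrichment)
    }
  }

  # exponential survival with subtype hazard ratios; independent censoring
  survival_time <- rep(NA_real_, n)
  survival_event <- rep(NA_integer_, n)
  for (s in seq_len(cfg$n_subtypes)) {
    idx <- which(!is.na(true_subtype) & true_subtype == s)
    ev_t <- rexp(length(idx), cfg$baseline_hazard * cfg$subtype_hazard_ratios[s])
    cn_t <- rexp(length(idx), cfg$censoring_hazard)
    survival_time[idx] <- pmin(ev_t, cn_t)
    survival_event[idx] <- as.integer(ev_t <= cn_t)
  }

  cohort <- list(
    expression = expr, sample_ids = sample_ids, gene_ids = gene_ids,
    tissue = tissue, is_tumor = is_tumor, cnv = cnv, mutations = mut,
    survival_time = survival_time, survival_event = survival_event,
    true_subtype = true_subtype, config = cfg,
    control_params = list(mean = mu, sd = sg),
    driver_genes = driver_genes,
    subtype_code = code
  )
  class(cohort) <- "expression_cohort"
  cohort
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf(
    "expression_cohort: %d samples (%d tumors, %d controls) x %d genes, %d tissues\n",
    length(x$sample_ids), sum(x$is_tumor), sum(1L - x$is_tumor),
    length(x$gene_ids), length(unique(x$tissue))))
  if (!all(is.na(x$true_subtype)))
    cat("planted subtypes:",
        paste(names(table(x$true_subtype)), table(x$true_subtype),
              sep = ":", collapse = " "), "\n")
  invisible(x)
}

# gene-per-row TSV: first column gene id, remaining columns samples
write_gene_matrix <- function(m, path) {
  dt <- data.table::data.table(gene_id = colnames(m), t(m))
  data.table::setnames(dt, c("gene_id", rownames(m)))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
}

read_gene_matrix <- function(path, integer = FALSE) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  genes <- dt[[1L]]
  m <- t(as.matrix(dt[, -1L]))
  colnames(m) <- genes
  if (integer) storage.mode(m) <- "integer"
  m
}

#' Write a cohort to a directory of TSV files
#'
#' Emits \code{expression.tsv} (genes in rows, samples in columns),
#' \code{cnv.tsv} and \code{mutations.tsv} in the same layout (omitted when
#' the cohort lacks them), \code{metadata.tsv} (sample, tissue, tumor flag),
#' \code{clinical.tsv} (survival and planted subtype for tumors), and a
#' \code{cohort_config.json} sidecar recording the generating configuration
#' and seed. Round-trips losslessly through [read_cohort()].
#'
#' @param cohort An \code{expression_cohort}.
#' @param dir Output directory (created if needed).
#' @param overwrite Refuse to overwrite an existing \code{expression.tsv}
#'   unless TRUE.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.exists(file.path(dir, "expression.tsv")) && !overwrite)
    stop("refusing to overwrite existing cohort in ", dir,
         " (use overwrite = TRUE)")
  write_gene_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  if (!is.null(cohort$cnv))
    write_gene_matrix(cohort$cnv, file.path(dir, "cnv.tsv"))
  if (!is.null(cohort$mutations))
    write_gene_matrix(cohort$mutations, file.path(dir, "mutations.tsv"))
  meta <- data.table::data.table(sample_id = cohort$sample_ids,
                                 tissue = cohort$tissue,
                                 is_tumor = cohort$is_tumor)
  data.table::fwrite(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE)
  clin <- data.table::data.table(
    sample_id = cohort$sample_ids, tissue = cohort$tissue,
    is_tumor = cohort$is_tumor, time = cohort$survival_time,
    event = cohort$survival_event, true_subtype = cohort$true_subtype)
  data.table::fwrite(clin, file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE)
  if (!is.null(cohort$config)) {
    cfg <- cohort$config
    cfg$hierarchy <- unclass(cfg$hierarchy)
    jsonlite::write_json(unclass(cfg), file.path(dir, "cohort_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Optional tables (\code{cnv.tsv}, \code{mutations.tsv}) may be absent.
#'
#' @param dir Directory containing the cohort TSVs.
#' @return An \code{expression_cohort}.
#' @export
read_cohort <- function(dir) {
  expr <- read_gene_matrix(file.path(dir, "expression.tsv"))
  clin <- data.table::fread(file.path(dir, "clinical.tsv"), sep = "\t")
  clin <- clin[match(rownames(expr), clin$sample_id), ]
  cnv <- mut <- NULL
  if (file.exists(file.path(dir, "cnv.tsv")))
    cnv <- read_gene_matrix(file.path(dir, "cnv.tsv"), integer = TRUE)
  if (file.exists(file.path(dir, "mutations.tsv")))
    mut <- read_gene_matrix(file.path(dir, "mutations.tsv"), integer = TRUE)
  cohort <- list(
    expression = expr, sample_ids = rownames(expr), gene_ids = colnames(expr),
    tissue = clin$tissue, is_tumor = as.integer(clin$is_tumor),
    cnv = cnv, mutations = mut,
    survival_time = as.numeric(clin$time),
    survival_event = as.integer(clin$event),
    true_subtype = as.integer(clin$true_subtype),
    config = NULL)
  class(cohort) <- "expression_cohort"
  cohort
}
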