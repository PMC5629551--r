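# End-to-end orchestration: cohort -> aberrations -> filters -> DBN
# ensemble -> consensus of consensus -> survival + correlates, with a
# checksum manifest and checkpoint-based resume.

#' Default scaled-down DBN ensemble
#'
#' Six seeded training configurations whose shapes mirror the
#' strictly-decreasing three-layer architectures used for ensemble
#' subtyping, scaled to desk size.
#'
#' @param layer_sets List of layer-size vectors (recycled to
#'   \code{n_models}).
#' @param n_models Ensemble size.
#' @param seed Base seed; model i uses \code{seed + 17 * i}.
#' @param ... Passed to [train_config()].
#' @return List of \code{train_config}s.
#' @export
default_ensemble <- function(layer_sets = list(c(60, 25, 10), c(70, 30, 10),
                                               c(60, 30, 12), c(50, 25, 10),
                                               c(70, 35, 14), c(60, 25, 12)),
                             n_models = 6L, seed = 1L, ...) {
  lapply(seq_len(n_models), function(i)
    train_config(layer_sets[[(i - 1L) %% length(layer_sets) + 1L]],
                 seed = (seed + 17L * i) %% .Machine$integer.max, ...))
}

#' Pipeline configuration
#'
#' @param cohort_dir Directory of cohort TSVs, or NULL to simulate.
#' @param synth_config A [cohort_config()] used when \code{cohort_dir} is
#'   NULL.
#' @param tail,low_sd,fold Aberration-calling parameters.
#' @param p,r_max Feature-filter parameters.
#' @param ensemble List of [train_config()]s (defaults to six seeded
#'   scaled-down models).
#' @param k_list Candidate cluster counts for PAC-based selection.
#' @param trials,fraction Consensus-clustering parameters.
#' @param top_k Top correlates per cluster.
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, cohort_dir = NULL, synth_config = NULL,
                            tail = 0.001, low_sd = 0.2, fold = 3,
                            p = 0.90, r_max = 0.85,
                            ensemble = NULL,
                            k_list = 2:5, trials = 50L, fraction = 0.8,
                            top_k = 10L, seed = 1L) {
  if (is.null(ensemble)) ensemble <- default_ensemble(seed = seed)
  stopifnot(length(ensemble) >= 1L, length(k_list) >= 1L)
  if (is.null(cohort_dir) && is.null(synth_config))
    synth_config <- cohort_config(seed = seed)
  structure(list(out_dir = out_dir, cohort_dir = cohort_dir,
                 synth_config = synth_config, tail = tail, low_sd = low_sd,
                 fold = fold, p = p, r_max = r_max, ensemble = ensemble,
                 k_list = as.integer(k_list), trials = as.integer(trials),
                 fraction = fraction, top_k = as.integer(top_k),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_done <- function(dir, stage) file.exists(file.path(dir, stage, ".done"))

mark_done <- function(dir, stage)
  writeLines(format(Sys.time()), file.path(dir, stage, ".done"))

#' Run the full subtyping pipeline
#'
#' Executes, in order: cohort loading or simulation, aberration calling
#' with copy-number masking, feature filtering, training of each ensemble
#' model and encoding of tumors, per-model consensus clustering,
#' PAC-based choice of k on the pooled matrix, consensus-of-consensus
#' assignment, Kaplan-Meier / log-rank survival readout, and per-cluster
#' correlate tables. Every artifact is written under \code{cfg$out_dir}
#' with a manifest of MD5 checksums; runs are reproducible from (inputs,
#' config, seed). With \code{resume = TRUE}, completed stages (marked by
#' checkpoint files) are skipped and their artifacts reused.
#'
#' @param cfg A [pipeline_config()].
#' @param resume Reuse completed stages from a previous interrupted run.
#' @return Invisibly, a list with the final assignment, selected k, PAC,
#'   log-rank result, correlate tables and the manifest path.
#' @export
run_pipeline <- function(cfg, resume = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_file <- file.path(out, "run.log")
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", sep = "", file = log_file, append = TRUE)
    message(msg)
  }
  run_stage <- function(stage, fn) {
    sdir <- file.path(out, stage)
    if (resume && stage_done(out, stage)) {
      say("stage ", stage, ": reusing checkpoint")
      return(invisible(NULL))
    }
    if (!dir.exists(sdir)) dir.create(sdir, recursive = TRUE)
    ok <- tryCatch({ fn(sdir); TRUE },
                   error = function(e) {
                     say("stage ", stage, " FAILED: ", conditionMessage(e))
                     stop("pipeline halted at stage '", stage, "': ",
                          conditionMessage(e), call. = FALSE)
                   })
    mark_done(out, stage)
    say("stage ", stage, ": done")
    invisible(NULL)
  }

  # --- cohort ---------------------------------------------------------
  run_stage("cohort", function(sdir) {
    if (is.null(cfg$cohort_dir)) {
      cohort <- generate_cohort(cfg$synth_config)
      write_cohort(cohort, sdir, overwrite = TRUE)
    } else {
      for (f in list.files(cfg$cohort_dir, full.names = TRUE))
        file.copy(f, sdir, overwrite = TRUE)
    }
  })
  cohort <- read_cohort(file.path(out, "cohort"))
  tumors <- which(cohort$is_tumor == 1L)

  # --- aberration calling + masking -----------------------------------
  run_stage("aberration", function(sdir) {
    ab <- cohort_aberrations(cohort, tail = cfg$tail, low_sd = cfg$low_sd,
                             fold = cfg$fold)
    write_aberrations(ab, sdir)
  })
  ab <- read_gene_matrix(file.path(out, "aberration", "aberrations.tsv"),
                         integer = TRUE)

  # --- feature filtering ----------------------------------------------
  run_stage("filter", function(sdir) {
    report <- filter_features(ab, tissue = cohort$tissue[tumors],
                              p = cfg$p, r_max = cfg$r_max)
    write_filter_report(report, sdir)
  })
  filtered <- read_gene_matrix(file.path(out, "filter", "filtered.tsv"),
                               integer = TRUE)

  # --- DBN ensemble: train + encode -----------------------------------
  for (i in seq_along(cfg$ensemble)) {
    local({
      ii <- i
      run_stage(sprintf("model%02d", ii), function(sdir) {
        model <- train_dbn(filtered, cfg$ensemble[[ii]])
        write_dbn(model, file.path(sdir, "model.json"))
        enc <- dbn_encode(model, filtered)
        colnames(enc) <- paste0("h", seq_len(ncol(enc)))
        data.table::fwrite(
          data.table::data.table(sample_id = rownames(enc), enc),
          file.path(sdir, "encodings.tsv"), sep = "\t", quote = FALSE)
      })
    })
  }
  encodings <- lapply(seq_along(cfg$ensemble), function(i) {
    dt <- data.table::fread(file.path(out, sprintf("model%02d", i),
                                      "encodings.tsv"))
    m <- as.matrix(dt[, -1L])
    rownames(m) <- dt[[1L]]
    m
  })

  # --- consensus clustering per model, pooled, k by PAC ----------------
  run_stage("cluster", function(sdir) {
    pac_tab <- NULL
    by_k <- list()
    for (k in cfg$k_list) {
      mats <- lapply(seq_along(encodings), function(i)
        consensus_cluster(encodings[[i]], k, trials = cfg$trials,
                          fraction = cfg$fraction,
                          seed = (cfg$seed + 101L * i + k) %%
                            .Machine$integer.max)$consensus)
      coc <- consensus_of_consensus(mats, k)
      by_k[[as.character(k)]] <- coc
    }
    sel <- select_k(lapply(by_k, `[[`, "consensus"))
    data.table::fwrite(sel$table, file.path(sdir, "pac_by_k.tsv"),
                       sep = "\t", quote = FALSE)
    final <- by_k[[as.character(sel$k)]]
    write_consensus(final, sdir)
    jsonlite::write_json(list(k = sel$k, pac = final$pac),
                         file.path(sdir, "selected_k.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  assign_dt <- data.table::fread(file.path(out, "cluster",
                                           "assignments.tsv"))
  labels <- assign_dt$cluster
  names(labels) <- assign_dt$sample_id
  sel <- jsonlite::read_json(file.path(out, "cluster", "selected_k.json"),
                             simplifyVector = TRUE)

  # --- survival + correlates ------------------------------------------
  run_stage("downstream", function(sdir) {
    idx <- match(names(labels), cohort$sample_ids)
    muts <- if (!is.null(cohort$mutations))
      cohort$mutations[idx, , drop = FALSE] else NULL
    write_downstream(cohort$survival_time[idx], cohort$survival_event[idx],
                     labels, sdir,
                     deg_features = ab[names(labels), , drop = FALSE],
                     mutation_features = muts, top_k = cfg$top_k)
  })

  # --- manifest --------------------------------------------------------
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$|run\\.log$|\\.done$", files)]
  manifest <- list(
    seed = cfg$seed,
    r_version = as.character(getRversion()),
    stages = split(
      data.frame(file = sub(paste0("^", out, "/?"), "", files),
                 md5 = unname(tools::md5sum(files))),
      dirname(sub(paste0("^", out, "/?"), "", files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  idx <- match(names(labels), cohort$sample_ids)
  lr <- logrank_test(cohort$survival_time[idx], cohort$survival_event[idx],
                     labels)
  result <- list(assignment = labels, k = sel$k, pac = sel$pac,
                 logrank = lr,
                 true_subtype = cohort$true_subtype[idx],
                 manifest = file.path(out, "manifest.json"))
  invisible(result)
}
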