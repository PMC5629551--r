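# Cross-validated reconstruction-error model selection: seeded folds
# (evaluate a subset of an 8-fold split), random + grid hyperparameter
# search, overfitting detection, and elbow location on error curves.

#' Seeded k-fold split with a subset of evaluated folds
#'
#' Splits samples into \code{k} disjoint near-equal folds and marks the
#' first \code{n_eval} (in seeded order) for evaluation, so a sweep can
#' evaluate e.g. four folds of an 8-fold split.
#'
#' @param n_samples Number of samples.
#' @param k Number of folds.
#' @param n_eval Number of folds actually evaluated.
#' @param seed Integer seed.
#' @return List with \code{folds} (list of index vectors) and \code{eval}
#'   (indices of the evaluated folds).
#' @export
make_folds <- function(n_samples, k = 8L, n_eval = 4L, seed = 1L) {
  if (k > n_samples) stop("k exceeds the number of samples")
  stopifnot(n_eval >= 1L, n_eval <= k)
  set.seed(seed)
  ord <- sample(n_samples)
  folds <- split(ord, rep_len(seq_len(k), n_samples))
  names(folds) <- NULL
  list(folds = folds, eval = seq_len(n_eval))
}

#' Evaluate one training configuration by cross-validated reconstruction error
#'
#' For each evaluated fold, trains a DBN on the complement and records the
#' held-out mean squared reconstruction error after every fine-tuning
#' epoch. The configuration's score is the mean final held-out error across
#' folds. A configuration is flagged as overfitting when, averaged over the
#' evaluated folds, the final held-out error exceeds the fold curve's own
#' minimum by more than \code{overfit_margin} (relative): the model kept
#' improving on the training data while held-out error rose again.
#'
#' @param cfg A [train_config()].
#' @param data Binary samples x genes matrix.
#' @param folds From [make_folds()].
#' @param overfit_margin Relative final-vs-minimum margin (default 5%).
#' @return Object of class \code{evaluation_record}: the config, per-fold
#'   held-out curves, the mean curve, mean train/test error and
#'   \code{overfit}.
#' @export
evaluate_config <- function(cfg, data, folds, overfit_margin = 0.05) {
  stopifnot(inherits(cfg, "train_config"))
  data <- as.matrix(data)
  curves <- list(); train_err <- test_err <- numeric(0)
  for (f in folds$eval) {
    test_idx <- folds$folds[[f]]
    train <- data[-test_idx, , drop = FALSE]
    test <- data[test_idx, , drop = FALSE]
    fit <- try(train_dbn(train, cfg, eval_data = test), silent = TRUE)
    if (inherits(fit, "try-error")) {
      curves[[length(curves) + 1L]] <- rep(NA_real_, cfg$epochs_finetune)
      train_err <- c(train_err, NA_real_)
      test_err <- c(test_err, NA_real_)
      next
    }
    curves[[length(curves) + 1L]] <- fit$training_log$eval_mse
    train_err <- c(train_err, fit$training_log$mse[cfg$epochs_finetune])
    test_err <- c(test_err, fit$training_log$eval_mse[cfg$epochs_finetune])
  }
  mean_curve <- colMeans(do.call(rbind, curves), na.rm = TRUE)
  rebound <- vapply(curves, function(cv) {
    if (anyNA(cv)) return(NA_real_)
    cv[length(cv)] / min(cv)
  }, numeric(1))
  overfit <- is.finite(mean(rebound, na.rm = TRUE)) &&
    mean(rebound, na.rm = TRUE) > 1 + overfit_margin
  rec <- list(config = cfg, fold_curves = curves, mean_curve = mean_curve,
              fold_rebound = rebound,
              mean_train_error = mean(train_err, na.rm = TRUE),
              mean_test_error = mean(test_err, na.rm = TRUE),
              overfit = overfit)
  class(rec) <- "evaluation_record"
  rec
}

#' Hyperparameter search space
#'
#' Ranges for a seeded random search: log-uniform learning rates, integer
#' layer sizes per depth with a strictly decreasing constraint, and integer
#' epoch/batch ranges.
#'
#' @param layer_ranges List of \code{c(min, max)} integer ranges, one per
#'   hidden layer (length = depth).
#' @param lr_pretrain_range,lr_finetune_range Positive ranges sampled
#'   log-uniformly.
#' @param epochs_pretrain_range,epochs_finetune_range,batch_range Integer
#'   ranges sampled uniformly.
#' @param cd_steps CD steps (fixed).
#' @return Object of class \code{search_space}.
#' @export
search_space <- function(layer_ranges,
                         lr_pretrain_range = c(1e-4, 1e-1),
                         lr_finetune_range = c(1e-3, 3e-1),
                         epochs_pretrain_range = c(5L, 15L),
                         epochs_finetune_range = c(10L, 50L),
                         batch_range = c(20L, 100L),
                         cd_steps = 1L) {
  stopifnot(length(layer_ranges) >= 1L,
            all(vapply(layer_ranges, length, 1L) == 2L),
            all(unlist(layer_ranges) >= 1L),
            all(c(lr_pretrain_range, lr_finetune_range) > 0))
  structure(list(layer_ranges = layer_ranges,
                 lr_pretrain_range = lr_pretrain_range,
                 lr_finetune_range = lr_finetune_range,
                 epochs_pretrain_range = as.integer(epochs_pretrain_range),
                 epochs_finetune_range = as.integer(epochs_finetune_range),
                 batch_range = as.integer(batch_range),
                 cd_steps = as.integer(cd_steps)),
            class = "search_space")
}

draw_config <- function(space, seed, max_tries = 1000L) {
  runif_log <- function(r) exp(stats::runif(1L, log(r[1L]), log(r[2L])))
  runif_int <- function(r) r[1L] + sample.int(r[2L] - r[1L] + 1L, 1L) - 1L
  for (i in seq_len(max_tries)) {
    sizes <- vapply(space$layer_ranges, runif_int, 1L)
    if (length(sizes) == 1L || all(diff(sizes) < 0)) {
      return(train_config(
        layer_sizes = sizes,
        lr_pretrain = runif_log(space$lr_pretrain_range),
        lr_finetune = runif_log(space$lr_finetune_range),
        epochs_pretrain = runif_int(space$epochs_pretrain_range),
        epochs_finetune = runif_int(space$epochs_finetune_range),
        batch_size = runif_int(space$batch_range),
        cd_steps = space$cd_steps, seed = seed))
    }
  }
  stop("could not draw a strictly decreasing architecture from the ",
       "layer ranges (infeasible constraints?)")
}

#' Seeded random search over hyperparameters
#'
#' Draws \code{n_draws} configurations from the space (rejection sampling
#' enforces strictly decreasing layer sizes), evaluates each by
#' cross-validated reconstruction error and returns records ranked by mean
#' held-out error. A pure function of (data, space, seed).
#'
#' @param space A [search_space()].
#' @param n_draws Number of configurations.
#' @param data Binary samples x genes matrix.
#' @param folds From [make_folds()].
#' @param seed Integer seed.
#' @return List of \code{evaluation_record}s, best first, with a
#'   \code{summary} data.frame attribute.
#' @export
random_search <- function(space, n_draws, data, folds, seed = 1L) {
  stopifnot(n_draws >= 1L)
  configs <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    set.seed(seed + i)
    configs[[i]] <- draw_config(space, seed = seed + i)
  }
  records <- lapply(configs, evaluate_config, data = data, folds = folds)
  ord <- order(vapply(records, `[[`, numeric(1), "mean_test_error"))
  records <- records[ord]
  attr(records, "summary") <- search_table(records)
  records
}

search_table <- function(records) {
  do.call(rbind, lapply(records, function(r) data.frame(
    architecture = paste(r$config$layer_sizes, collapse = "-"),
    lr_pretrain = r$config$lr_pretrain,
    lr_finetune = r$config$lr_finetune,
    epochs_pretrain = r$config$epochs_pretrain,
    epochs_finetune = r$config$epochs_finetune,
    batch_size = r$config$batch_size,
    mean_train_error = r$mean_train_error,
    mean_test_error = r$mean_test_error,
    overfit = r$overfit)))
}

#' Grid search over hidden-layer architectures
#'
#' Evaluates each architecture with the remaining hyperparameters fixed and
#' returns a table suitable for elbow inspection of reconstruction error
#' versus layer size.
#'
#' @param architectures List of integer layer-size vectors.
#' @param fixed A [train_config()] supplying every non-architecture
#'   hyperparameter.
#' @param data Binary samples x genes matrix.
#' @param folds From [make_folds()].
#' @return List with \code{records} and a \code{table} data.frame (one row
#'   per architecture: sizes, per-fold and mean test errors, overfit flag).
#' @export
grid_search <- function(architectures, fixed, data, folds) {
  stopifnot(length(architectures) >= 1L, inherits(fixed, "train_config"))
  records <- lapply(architectures, function(sizes) {
    cfg <- fixed
    cfg$layer_sizes <- as.integer(sizes)
    evaluate_config(cfg, data, folds)
  })
  list(records = records, table = search_table(records))
}

#' Locate the elbow of an error-versus-size curve
#'
#' Returns the size at the maximum discrete second difference (curvature)
#' of the error curve: the point where reconstruction error stops dropping
#' rapidly. Reported for inspection, not applied automatically.
#'
#' @param sizes Increasing layer sizes.
#' @param errors Reconstruction errors at those sizes.
#' @return The elbow size (with the curvature table as attribute
#'   \code{diagnostics}).
#' @export
find_elbow <- function(sizes, errors) {
  stopifnot(length(sizes) == length(errors), length(sizes) >= 3L,
            !is.unsorted(sizes))
  i <- 2:(length(sizes) - 1L)
  curvature <- errors[i - 1L] - 2 * errors[i] + errors[i + 1L]
  elbow <- sizes[i][which.max(curvature)]
  attr(elbow, "diagnostics") <- data.frame(size = sizes[i],
                                           curvature = curvature)
  elbow
}
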