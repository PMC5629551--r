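# Subsampled consensus clustering, PAC scoring, and the
# consensus-of-consensus ensemble across independently trained models.

#' Agglomerative hierarchical clustering (Euclidean, average linkage)
#'
#' @param X Samples x features matrix, or a distance-like symmetric matrix
#'   / \code{dist} when \code{is_distance = TRUE}.
#' @param k Number of clusters to cut the tree into.
#' @param is_distance Treat \code{X} as precomputed dissimilarities.
#' @return Object of class \code{cluster_assignment}: integer
#'   \code{labels} in 1..k (named by sample), \code{k} and the
#'   \code{hclust} tree.
#' @export
hierarchical_cluster <- function(X, k, is_distance = FALSE) {
  d <- if (is_distance) stats::as.dist(X) else stats::dist(X)
  n <- attr(d, "Size")
  if (k > n) stop("k exceeds the number of samples")
  tree <- stats::hclust(d, method = "average")
  labels <- stats::cutree(tree, k = k)
  structure(list(labels = labels, k = as.integer(k), tree = tree),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d samples in %d clusters (%s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

new_consensus_matrix <- function(values, trials, fraction,
                                 n_never_cosampled = 0L) {
  stopifnot(isSymmetric(unname(values)), all(values >= 0 & values <= 1))
  structure(list(values = values, sample_ids = rownames(values),
                 trials = as.integer(trials), subsample_fraction = fraction,
                 n_never_cosampled = as.integer(n_never_cosampled)),
            class = "consensus_matrix")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat(sprintf(
    "consensus_matrix: %d x %d, %d trials at %.0f%% subsampling, PAC %.3f\n",
    nrow(x$values), ncol(x$values), x$trials, 100 * x$subsample_fraction,
    pac(x)))
  invisible(x)
}

#' Consensus clustering by repeated subsampled clustering
#'
#' Runs \code{trials} rounds in which \code{floor(fraction * n)} samples
#' are drawn without replacement and clustered hierarchically (Euclidean
#' distance, average linkage) into \code{k} groups. The consensus value for
#' a pair of samples is the number of trials in which they were clustered
#' together divided by the number of trials in which both were drawn.
#' Pairs never drawn together get consensus 0 (counted and reported). The
#' final assignment clusters \code{1 - consensus} as a dissimilarity with
#' the same linkage.
#'
#' @param X Samples x features representation matrix.
#' @param k Number of clusters.
#' @param trials Number of subsampling rounds.
#' @param fraction Subsample fraction in (0, 1].
#' @param seed Integer seed.
#' @return List with \code{consensus} (a \code{consensus_matrix}) and
#'   \code{assignment} (a \code{cluster_assignment}).
#' @export
consensus_cluster <- function(X, k, trials = 100L, fraction = 0.8,
                              seed = 1L) {
  stopifnot(trials >= 1L, fraction > 0, fraction <= 1)
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(n))
  m <- max(2L, floor(fraction * n))
  set.seed(seed)
  together <- cosampled <- matrix(0, n, n)
  for (trial in seq_len(trials)) {
    idx <- if (m >= n) seq_len(n) else sort(sample(n, m))
    labels <- stats::cutree(
      stats::hclust(stats::dist(X[idx, , drop = FALSE]), "average"), k = k)
    co <- outer(labels, labels, `==`) * 1
    cosampled[idx, idx] <- cosampled[idx, idx] + 1
    together[idx, idx] <- together[idx, idx] + co
  }
  never <- cosampled == 0
  cm <- ifelse(never, 0, together / pmax(cosampled, 1))
  diag(cm) <- 1
  dimnames(cm) <- list(rownames(X), rownames(X))
  consensus <- new_consensus_matrix(cm, trials, fraction,
                                    sum(never[upper.tri(never)]))
  assignment <- hierarchical_cluster(1 - cm, k, is_distance = TRUE)
  list(consensus = consensus, assignment = assignment)
}

#' Proportion of ambiguous clustering (PAC)
#'
#' The fraction of off-diagonal sample pairs whose consensus value lies
#' strictly between \code{lower} and \code{upper}: pairs that clustered
#' together in some trials but not others. Low PAC indicates a stable
#' clustering. Boundary values count as unambiguous.
#'
#' @param cm A \code{consensus_matrix} or plain symmetric matrix.
#' @param lower,upper Ambiguity band (defaults 0.2 and 0.8).
#' @return Proportion in [0, 1].
#' @export
pac <- function(cm, lower = 0.2, upper = 0.8) {
  stopifnot(lower < upper)
  v <- if (inherits(cm, "consensus_matrix")) cm$values else cm
  x <- v[upper.tri(v)]
  mean(x > lower & x < upper)
}

#' Pool consensus matrices from multiple models (consensus of consensus)
#'
#' Equal-vote ensemble across independently trained models: the pooled
#' matrix is the elementwise mean of the per-model consensus matrices
#' (\code{pool = "mean"}), or of the co-assignment indicator matrices of
#' each model's final labels (\code{pool = "assignment"}). The pooled
#' matrix is then clustered like a single consensus matrix.
#'
#' @param matrices List (length >= 2) of \code{consensus_matrix} objects
#'   over identical sample sets.
#' @param k Number of clusters for the final cut.
#' @param pool Pooling rule.
#' @return List with the pooled \code{consensus_matrix}, the final
#'   \code{assignment} and its \code{pac}.
#' @export
consensus_of_consensus <- function(matrices, k, pool = c("mean",
                                                         "assignment")) {
  pool <- match.arg(pool)
  stopifnot(length(matrices) >= 2L)
  ids <- matrices[[1L]]$sample_ids
  for (m in matrices)
    if (!identical(m$sample_ids, ids))
      stop("consensus matrices cover different sample sets")
  stack <- lapply(matrices, function(m) {
    if (pool == "mean") m$values
    else {
      labels <- hierarchical_cluster(1 - m$values, k,
                                     is_distance = TRUE)$labels
      outer(labels, labels, `==`) * 1
    }
  })
  pooled <- Reduce(`+`, stack) / length(stack)
  diag(pooled) <- 1
  dimnames(pooled) <- list(ids, ids)
  cm <- new_consensus_matrix(pooled,
                             sum(vapply(matrices, `[[`, 1L, "trials")),
                             matrices[[1L]]$subsample_fraction)
  assignment <- hierarchical_cluster(1 - pooled, k, is_distance = TRUE)
  list(consensus = cm, assignment = assignment, pac = pac(cm))
}

#' Choose the number of clusters by minimum PAC
#'
#' @param cm_by_k Named list mapping k to a \code{consensus_matrix} (names
#'   are the k values).
#' @param lower,upper PAC ambiguity band.
#' @return List with the selected \code{k} (argmin PAC, ties toward
#'   smaller k) and the PAC-vs-k \code{table}.
#' @export
select_k <- function(cm_by_k, lower = 0.2, upper = 0.8) {
  ks <- as.integer(names(cm_by_k))
  stopifnot(length(ks) >= 1L, !anyNA(ks))
  pacs <- vapply(cm_by_k, pac, numeric(1), lower = lower, upper = upper)
  tab <- data.frame(k = ks, pac = unname(pacs))
  tab <- tab[order(tab$k), ]
  best <- tab$k[which.min(tab$pac)] # which.min takes the first = smallest k
  list(k = best, table = tab)
}

#' Write consensus-clustering artifacts
#'
#' @param result Output of [consensus_cluster()] or
#'   [consensus_of_consensus()].
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_consensus <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cm <- result$consensus$values
  dt <- data.table::data.table(sample_id = rownames(cm), cm)
  data.table::fwrite(dt, file.path(dir, "consensus_matrix.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(
    data.table::data.table(sample_id = names(result$assignment$labels),
                           cluster = result$assignment$labels),
    file.path(dir, "assignments.tsv"), sep = "\t", quote = FALSE)
  invisible(dir)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two clusterings; 1 for identical
#' partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
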