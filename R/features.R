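# Feature selection on the binary aberration matrix: drop low-information
# (near-constant) genes and genes confounded with tissue of origin.

new_filter_report <- function(kept, removed, input_genes) {
  stopifnot(!anyDuplicated(c(colnames(kept), removed$gene)),
            setequal(c(colnames(kept), removed$gene), input_genes))
  out <- list(kept = kept, kept_genes = colnames(kept), removed = removed)
  class(out) <- "feature_filter_report"
  out
}

#' @export
print.feature_filter_report <- function(x, ...) {
  cat(sprintf("feature_filter_report: %d genes kept, %d removed\n",
              length(x$kept_genes), nrow(x$removed)))
  if (nrow(x$removed))
    print(table(x$removed$reason))
  invisible(x)
}

#' Remove genes with low Bernoulli variance
#'
#' A binarized gene carries little information when it is aberrant (or
#' non-aberrant) in almost every tumor. A gene is removed when its fraction
#' of 1s is at least \code{p} or its fraction of 0s is at least \code{p}
#' (ties at exactly \code{p} are removed). The paper-style thresholds 0.90
#' and 0.95 are typical; 0.70 gives the high-variance subset.
#'
#' @param m Binary samples x genes matrix.
#' @param p Bernoulli success-probability threshold, in (0, 1).
#' @return A \code{feature_filter_report} with the filtered matrix
#'   (\code{$kept}, input column order preserved), kept gene ids, and a
#'   removal table with each removed gene's Bernoulli rate.
#' @export
bernoulli_variance_filter <- function(m, p = 0.90) {
  if (length(m) == 0L || nrow(m) == 0L || ncol(m) == 0L)
    stop("empty matrix")
  if (p <= 0 || p >= 1) stop("p must lie strictly in (0, 1)")
  if (!all(m %in% c(0L, 1L))) stop("matrix must be binary")
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(ncol(m)))
  rate <- colMeans(m)
  drop <- rate >= p | (1 - rate) >= p
  removed <- data.frame(gene = colnames(m)[drop],
                        reason = rep("low_bernoulli_variance", sum(drop)),
                        statistic = unname(rate[drop]), row.names = NULL)
  new_filter_report(unclass_matrix(m)[, !drop, drop = FALSE], removed,
                    colnames(m))
}

#' Remove genes confounded with tissue of origin
#'
#' Computes, for each gene, the Pearson correlation with each tissue's
#' one-hot indicator and removes the gene when the maximum absolute
#' correlation exceeds \code{r_max} (strictly). Absolute correlation is
#' used: a gene perfectly anti-correlated with a tissue is just as
#' tissue-identifying as a perfectly correlated one. Constant genes have no
#' defined correlation and are removed with reason \code{"constant"}. With a
#' single tissue the filter warns and keeps everything.
#'
#' @param m Binary samples x genes matrix.
#' @param tissue Tissue label per sample.
#' @param r_max Correlation threshold.
#' @return A \code{feature_filter_report}; removal table records the
#'   offending tissue and the maximal |r|.
#' @export
tissue_correlation_filter <- function(m, tissue, r_max = 0.85) {
  if (length(m) == 0L || nrow(m) == 0L || ncol(m) == 0L)
    stop("empty matrix")
  if (length(tissue) != nrow(m))
    stop("tissue labels must cover all samples")
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(ncol(m)))
  tissues <- unique(tissue)
  if (length(tissues) < 2L) {
    warning("single tissue: tissue-correlation filter is a no-op")
    return(new_filter_report(unclass_matrix(m),
                             data.frame(gene = character(),
                                        reason = character(),
                                        statistic = numeric(),
                                        tissue = character()),
                             colnames(m)))
  }
  constant <- apply(m, 2L, function(x) stats::var(x) == 0)
  onehot <- sapply(tissues, function(t) as.numeric(tissue == t))
  r <- matrix(0, ncol(m), length(tissues),
              dimnames = list(colnames(m), tissues))
  ok <- which(!constant)
  if (length(ok))
    r[ok, ] <- abs(stats::cor(m[, ok, drop = FALSE], onehot))
  max_r <- apply(r, 1L, max)
  worst <- tissues[apply(r, 1L, which.max)]
  drop <- constant | max_r > r_max
  removed <- data.frame(
    gene = colnames(m)[drop],
    reason = ifelse(constant[drop], "constant", "tissue_correlated"),
    statistic = ifelse(constant[drop], NA_real_, max_r[drop]),
    tissue = ifelse(constant[drop], NA_character_, worst[drop]),
    row.names = NULL)
  new_filter_report(unclass_matrix(m)[, !drop, drop = FALSE], removed,
                    colnames(m))
}

#' Apply both feature filters in sequence
#'
#' Bernoulli-variance filter first, then the tissue-correlation filter on
#' the surviving genes, mirroring the preprocessing order of the analysis.
#'
#' @inheritParams bernoulli_variance_filter
#' @inheritParams tissue_correlation_filter
#' @return A \code{feature_filter_report} whose removal table concatenates
#'   both stages.
#' @export
filter_features <- function(m, tissue = NULL, p = 0.90, r_max = 0.85) {
  rep1 <- bernoulli_variance_filter(m, p = p)
  if (is.null(tissue) || length(unique(tissue)) < 2L)
    return(rep1)
  rep2 <- tissue_correlation_filter(rep1$kept, tissue, r_max = r_max)
  rep1$removed$tissue <- rep(NA_character_, nrow(rep1$removed))
  removed <- rbind(rep1$removed, rep2$removed)
  new_filter_report(rep2$kept, removed, colnames(m))
}

#' Write a filter report and the filtered matrix
#'
#' @param report A \code{feature_filter_report}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_filter_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gene_matrix(report$kept, file.path(dir, "filtered.tsv"))
  decisions <- rbind(
    data.frame(gene = report$kept_genes, decision = "kept",
               reason = NA_character_, statistic = NA_real_),
    data.frame(gene = report$removed$gene, decision = "removed",
               reason = report$removed$reason,
               statistic = report$removed$statistic))
  data.table::fwrite(decisions, file.path(dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(dir)
}
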