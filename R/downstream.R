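# Clinical and mechanistic readout of clusters: product-limit survival
# curves, the g-sample log-rank test, and per-cluster ranked correlates.

#' Kaplan-Meier product-limit estimate
#'
#' Right-continuous nonincreasing step function starting at 1, with the
#' risk set, events and censorings at every observed event time.
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicator (1 = death observed, 0 = censored).
#' @return Data frame of class \code{km_curve}: \code{time},
#'   \code{n_risk}, \code{n_event}, \code{n_censor}, \code{survival}
#'   (one row per distinct observed time, censoring-only times included so
#'   tick marks can be drawn).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(time < 0)) stop("negative survival times")
  event <- as.integer(event)
  times <- sort(unique(time))
  n_risk <- vapply(times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(times, function(t) sum(time == t & event == 1L),
                    numeric(1))
  n_censor <- vapply(times, function(t) sum(time == t & event == 0L),
                     numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = times, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, survival = surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' Kaplan-Meier curves per group
#'
#' @param time,event As in [km_estimate()].
#' @param group Group (cluster) label per record.
#' @return Data frame with a \code{group} column stacking the per-group
#'   curves.
#' @export
km_by_group <- function(time, event, group) {
  stopifnot(length(group) == length(time))
  do.call(rbind, lapply(split(seq_along(time), group), function(idx) {
    km <- km_estimate(time[idx], event[idx])
    cbind(group = rep(unname(group[idx[1L]]), nrow(km)), km)
  }))
}

#' g-sample log-rank test
#'
#' Standard log-rank comparison of survival across g >= 2 groups: at every
#' pooled event time the observed events per group are compared with their
#' hypergeometric expectation given the risk sets, with the usual
#' aggregated handling of tied event times. The statistic is
#' (O - E)' V^{-1} (O - E) over the first g - 1 groups, chi-square with
#' g - 1 degrees of freedom under the null.
#'
#' @param time,event As in [km_estimate()].
#' @param group Group label per record; all groups must be nonempty.
#' @return List with \code{statistic}, \code{df}, \code{p_value}, and the
#'   per-group observed/expected table.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time < 0)) stop("negative survival times")
  event <- as.integer(event)
  group <- as.factor(group)
  g <- nlevels(group)
  if (g < 2L) stop("need at least 2 groups")
  if (sum(event) == 0L) stop("no events observed; log-rank undefined")
  ev_times <- sort(unique(time[event == 1L]))
  O <- E <- numeric(g)
  V <- matrix(0, g, g)
  for (t in ev_times) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    d_j <- sum(time == t & event == 1L)
    n_ij <- vapply(levels(group), function(lv) sum(at_risk & group == lv),
                   numeric(1))
    d_ij <- vapply(levels(group),
                   function(lv) sum(time == t & event == 1L & group == lv),
                   numeric(1))
    O <- O + d_ij
    E <- E + d_j * n_ij / n_j
    if (n_j > 1) {
      scale <- d_j * (n_j - d_j) / (n_j - 1)
      V <- V + scale * (diag(n_ij / n_j, g) -
                          tcrossprod(n_ij / n_j))
    }
  }
  i <- seq_len(g - 1L)
  d <- (O - E)[i]
  Vi <- V[i, i, drop = FALSE]
  stat <- tryCatch(as.numeric(t(d) %*% solve(Vi, d)),
                   error = function(e) {
                     s <- svd(Vi)
                     pos <- s$d > max(s$d) * 1e-12
                     as.numeric(t(d) %*% s$v[, pos, drop = FALSE] %*%
                                  ((t(s$u[, pos, drop = FALSE]) %*% d) /
                                     s$d[pos]))
                   })
  list(statistic = stat, df = g - 1L,
       p_value = stats::pchisq(stat, g - 1L, lower.tail = FALSE),
       table = data.frame(group = levels(group), observed = O, expected = E))
}

#' Rank binary features by correlation with each cluster
#'
#' For each cluster, computes the Pearson correlation between every binary
#' feature (aberrant gene or mutation) and the cluster's one-vs-rest
#' indicator, and reports the \code{top_k} features with the largest
#' positive correlations. Zero-variance features are excluded (logged in
#' \code{excluded}); the full signed table is also returned so users can
#' apply their own cutoffs or corrections (n is included for that purpose).
#'
#' @param features Binary samples x features matrix.
#' @param labels Cluster label per sample (aligned with rows).
#' @param top_k Number of top positively correlated features per cluster.
#' @return Object of class \code{correlate_table}: \code{top} (cluster,
#'   rank, feature, r), \code{full}, \code{excluded}, \code{n}.
#' @export
cluster_correlates <- function(features, labels, top_k = 10L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  if (!all(features %in% c(0, 1))) stop("features must be binary")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  keep <- apply(features, 2L, function(x) stats::var(x) > 0)
  excluded <- data.frame(feature = colnames(features)[!keep],
                         reason = rep("zero_variance", sum(!keep)))
  f <- features[, keep, drop = FALSE]
  clusters <- sort(unique(labels))
  full <- do.call(rbind, lapply(clusters, function(cl) {
    ind <- as.numeric(labels == cl)
    r <- as.numeric(stats::cor(f, ind))
    data.frame(cluster = cl, feature = colnames(f), r = r)
  }))
  top <- do.call(rbind, lapply(clusters, function(cl) {
    sub <- full[full$cluster == cl & full$r > 0, ]
    sub <- sub[order(-sub$r), , drop = FALSE]
    sub <- utils::head(sub, top_k)
    if (nrow(sub)) sub$rank <- seq_len(nrow(sub))
    sub
  }))
  structure(list(top = top[, c("cluster", "rank", "feature", "r")],
                 full = full, excluded = excluded, n = nrow(features)),
            class = "correlate_table")
}

#' Word-cloud-ready weights for a correlate table
#'
#' Scales correlations to relative weights within each cluster only (the
#' cluster's strongest feature gets weight 1), so weights are comparable
#' within a cluster but deliberately not across clusters.
#'
#' @param tab A \code{correlate_table}.
#' @return Data frame (cluster, rank, feature, r, weight).
#' @export
export_wordcloud_table <- function(tab) {
  stopifnot(inherits(tab, "correlate_table"), nrow(tab$top) > 0L)
  out <- tab$top
  out$weight <- NA_real_
  for (cl in unique(out$cluster)) {
    i <- out$cluster == cl
    out$weight[i] <- out$r[i] / max(out$r[i])
  }
  out
}

#' Write survival and correlate artifacts
#'
#' Emits \code{km_curves.tsv}, \code{logrank.txt} and per-family correlate
#' TSVs with word-cloud weights.
#'
#' @param time,event,labels Survival data and cluster labels.
#' @param dir Output directory.
#' @param deg_features,mutation_features Optional binary matrices for
#'   correlate ranking.
#' @param top_k Top correlates per cluster.
#' @return \code{dir}, invisibly.
#' @export
write_downstream <- function(time, event, labels, dir,
                             deg_features = NULL, mutation_features = NULL,
                             top_k = 10L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(km_by_group(time, event, labels),
                     file.path(dir, "km_curves.tsv"), sep = "\t",
                     quote = FALSE)
  lr <- logrank_test(time, event, labels)
  writeLines(c(sprintf("chi_square\t%.10g", lr$statistic),
               sprintf("df\t%d", lr$df),
               sprintf("p_value\t%.10g", lr$p_value)),
             file.path(dir, "logrank.txt"))
  for (fam in c("degs", "mutations")) {
    feats <- if (fam == "degs") deg_features else mutation_features
    if (is.null(feats)) next
    tab <- cluster_correlates(feats, labels, top_k = top_k)
    data.table::fwrite(export_wordcloud_table(tab),
                       file.path(dir, paste0("correlates_", fam, ".tsv")),
                       sep = "\t", quote = FALSE)
  }
  invisible(dir)
}
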