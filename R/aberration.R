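# Tumor-vs-normal expression discretization with copy-number masking.

#' Fit per-gene, per-tissue control Gaussians
#'
#' Fits a Gaussian to each gene's expression within each tissue using the
#' non-cancer control samples of that tissue only; tumors are ignored. The
#' SD divisor is n-1 (unbiased) by default.
#'
#' @param cohort An \code{expression_cohort}.
#' @param sd_divisor \code{"n-1"} (default) or \code{"n"} (maximum
#'   likelihood).
#' @return Object of class \code{control_gaussians}: genes-by-tissues
#'   \code{mean} and \code{sd} matrices, per-tissue control counts, and the
#'   ids of zero-variance (flagged low-variance) (gene, tissue) pairs.
#' @export
fit_control_gaussians <- function(cohort, sd_divisor = c("n-1", "n")) {
  stopifnot(inherits(cohort, "expression_cohort"))
  sd_divisor <- match.arg(sd_divisor)
  if (anyNA(cohort$expression)) stop("expression contains missing values")
  tissues <- unique(cohort$tissue)
  G <- length(cohort$gene_ids)
  mu <- sg <- matrix(NA_real_, G, length(tissues),
                     dimnames = list(cohort$gene_ids, tissues))
  n_controls <- integer(length(tissues))
  names(n_controls) <- tissues
  for (t in tissues) {
    idx <- which(cohort$tissue == t & cohort$is_tumor == 0L)
    if (length(idx) < 2L)
      stop("tissue '", t, "' has fewer than 2 control samples")
    x <- cohort$expression[idx, , drop = FALSE]
    mu[, t] <- colMeans(x)
    ss <- colSums(sweep(x, 2L, mu[, t])^2)
    div <- if (sd_divisor == "n-1") length(idx) - 1L else length(idx)
    sg[, t] <- sqrt(ss / div)
    n_controls[t] <- length(idx)
  }
  zero_var <- which(sg == 0, arr.ind = TRUE)
  out <- list(mean = mu, sd = sg, n_controls = n_controls,
              sd_divisor = sd_divisor,
              zero_variance = if (nrow(zero_var))
                data.frame(gene = rownames(mu)[zero_var[, 1L]],
                           tissue = tissues[zero_var[, 2L]])
              else data.frame(gene = character(), tissue = character()))
  class(out) <- "control_gaussians"
  out
}

#' Call signed expression aberrations in tumors
#'
#' A tumor's expression of a gene is called aberrant when it falls outside
#' the two-sided tails of the control Gaussian for that gene and tissue:
#' +1 if above \code{mean + z * sd}, -1 if below \code{mean - z * sd}, where
#' \code{z = qnorm(1 - tail)} (each one-sided tail holds mass \code{tail};
#' 0.001 per side by default, z ~ 3.09). For genes whose control SD is below
#' \code{low_sd} the Gaussian tail is unreliable and a fold-change rule is
#' used instead: +1 when the value is at least \code{fold} times the control
#' mean, -1 when at most \code{mean / fold} (expression assumed on a
#' strictly positive scale). Controls are never scored.
#'
#' @param tumors Tumor expression matrix, samples x genes.
#' @param tissue Tissue label per tumor row.
#' @param params A \code{control_gaussians} fit covering all tissues/genes.
#' @param tail One-sided tail mass for the Gaussian rule.
#' @param low_sd Control-SD threshold below which the fold rule applies
#'   (strictly smaller; SD equal to \code{low_sd} uses the Gaussian rule).
#' @param fold Fold-change threshold for low-variance genes.
#' @return Samples x genes matrix of signed calls in \{-1, 0, +1\}, class
#'   \code{signed_call_matrix}.
#' @export
call_aberrations <- function(tumors, tissue, params, tail = 0.001,
                             low_sd = 0.2, fold = 3) {
  stopifnot(inherits(params, "control_gaussians"),
            nrow(tumors) == length(tissue))
  if (!all(tissue %in% colnames(params$mean)))
    stop("params missing tissues: ",
         paste(setdiff(tissue, colnames(params$mean)), collapse = ", "))
  if (!is.null(colnames(tumors)) &&
      !identical(colnames(tumors), rownames(params$mean)))
    stop("gene ids of tumors and params disagree")
  z <- stats::qnorm(1 - tail)
  calls <- matrix(0L, nrow(tumors), ncol(tumors), dimnames = dimnames(tumors))
  for (t in unique(tissue)) {
    idx <- which(tissue == t)
    mu <- params$mean[, t]
    sg <- params$sd[, t]
    x <- tumors[idx, , drop = FALSE]
    gaussian <- sg >= low_sd
    if (any(!gaussian) && any(mu[!gaussian] <= 0))
      stop("nonpositive control mean under the fold rule for tissue '", t,
           "'; fold change undefined")
    up <- sweep(x, 2L, ifelse(gaussian, mu + z * sg, fold * mu),
                `>=`) # boundary: fold rule uses >=; Gaussian strict below
    up[, gaussian] <- sweep(x[, gaussian, drop = FALSE], 2L,
                            (mu + z * sg)[gaussian], `>`)
    dn <- sweep(x, 2L, ifelse(gaussian, mu - z * sg, mu / fold), `<=`)
    dn[, gaussian] <- sweep(x[, gaussian, drop = FALSE], 2L,
                            (mu - z * sg)[gaussian], `<`)
    calls[idx, ] <- ifelse(up, 1L, ifelse(dn, -1L, 0L))
  }
  class(calls) <- c("signed_call_matrix", class(calls))
  calls
}

#' Mask aberration calls explained by copy-number alteration
#'
#' An up-regulation call co-occurring with an amplification (score >= +1),
#' or a down-regulation call with a deletion (score <= -1), is attributed to
#' the copy-number event rather than signaling and set to 0; all other calls
#' keep their magnitude. GISTIC scores of +/-2, if present, are treated as
#' +/-1. Masking never creates a call.
#'
#' @param calls Signed call matrix from [call_aberrations()].
#' @param cnv Discrete copy-number matrix aligned with \code{calls} (same
#'   samples and genes).
#' @return Binary samples x genes \code{aberration_matrix}; attribute
#'   \code{audit} is a data.frame (sample, gene, call, cnv, masked) covering
#'   every nonzero signed call.
#' @export
mask_cnv <- function(calls, cnv) {
  if (!identical(dim(calls), dim(cnv)))
    stop("calls and cnv have different dimensions")
  if (!is.null(dimnames(calls)) && !is.null(dimnames(cnv))) {
    if (!identical(rownames(calls), rownames(cnv))) {
      bad <- which(rownames(calls) != rownames(cnv))[1L]
      stop("sample ids misaligned, first mismatch at row ", bad, ": '",
           rownames(calls)[bad], "' vs '", rownames(cnv)[bad], "'")
    }
    if (!identical(colnames(calls), colnames(cnv))) {
      bad <- which(colnames(calls) != colnames(cnv))[1L]
      stop("gene ids misaligned, first mismatch at column ", bad, ": '",
           colnames(calls)[bad], "' vs '", colnames(cnv)[bad], "'")
    }
  }
  calls <- unclass(calls)
  masked <- (calls == 1L & cnv >= 1L) | (calls == -1L & cnv <= -1L)
  out <- abs(calls)
  out[masked] <- 0L
  storage.mode(out) <- "integer"
  nz <- which(calls != 0L, arr.ind = TRUE)
  audit <- data.frame(
    sample = rownames(calls)[nz[, 1L]],
    gene = colnames(calls)[nz[, 2L]],
    call = calls[nz], cnv = cnv[nz], masked = masked[nz])
  attr(out, "audit") <- audit
  class(out) <- c("aberration_matrix", class(out))
  out
}

#' Discretize a cohort end to end
#'
#' Convenience wrapper: fit control Gaussians, call aberrations on the
#' tumors, and mask copy-number-explained calls (when the cohort carries CNV
#' scores).
#'
#' @inheritParams call_aberrations
#' @param cohort An \code{expression_cohort}.
#' @param sd_divisor Passed to [fit_control_gaussians()].
#' @return Binary tumors x genes \code{aberration_matrix}.
#' @export
cohort_aberrations <- function(cohort, tail = 0.001, low_sd = 0.2, fold = 3,
                               sd_divisor = c("n-1", "n")) {
  params <- fit_control_gaussians(cohort, sd_divisor = match.arg(sd_divisor))
  tum <- which(cohort$is_tumor == 1L)
  calls <- call_aberrations(cohort$expression[tum, , drop = FALSE],
                            cohort$tissue[tum], params,
                            tail = tail, low_sd = low_sd, fold = fold)
  cnv <- if (!is.null(cohort$cnv)) cohort$cnv[tum, , drop = FALSE]
         else matrix(0L, length(tum), length(cohort$gene_ids),
                     dimnames = dimnames(calls))
  mask_cnv(calls, cnv)
}

#' Write an aberration matrix and its masking audit
#'
#' @param m An \code{aberration_matrix}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_aberrations <- function(m, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gene_matrix(unclass_matrix(m), file.path(dir, "aberrations.tsv"))
  audit <- attr(m, "audit")
  if (!is.null(audit))
    data.table::fwrite(audit, file.path(dir, "masking_audit.tsv"),
                       sep = "\t", quote = FALSE)
  invisible(dir)
}

unclass_matrix <- function(m) {
  attr(m, "audit") <- NULL
  class(m) <- NULL
  m
}
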