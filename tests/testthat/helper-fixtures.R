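# Shared fixture builders and independent oracles.

# small two-tissue cohort with three planted subtypes
make_test_cohort <- function(seed = 1, ...) {
  defaults <- list(n_tissues = 2L, tumors_per_tissue = 30L,
                   controls_per_tissue = 10L, n_genes = 60L,
                   n_subtypes = 3L, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  generate_cohort(do.call(cohort_config, args))
}

# aberration matrix from a cohort whose variation is driven by n_tfs
# independently activatable TFs (many subtypes = many activation combos)
make_tf_factor_data <- function(seed, n_genes = 64L, tumors = 160L,
                                n_tfs = 8L, effect_size = 6,
                                controls = 30L) {
  h <- latent_hierarchy(n_genes, n_processes = n_tfs, n_pathways = n_tfs,
                        n_tfs = n_tfs, effect_size = effect_size,
                        seed = seed)
  cfg <- cohort_config(n_tissues = 1L, tumors_per_tissue = tumors,
                       controls_per_tissue = controls, n_genes = n_genes,
                       n_subtypes = min(100L, 2L^n_tfs - 1L), hierarchy = h,
                       cnv_rate = 0, mutations_per_subtype = 0,
                       seed = seed)
  ab <- cohort_aberrations(generate_cohort(cfg))
  attr(ab, "audit") <- NULL
  class(ab) <- NULL
  ab
}

# strip class/attributes from an aberration matrix
plain_matrix <- function(m) {
  attr(m, "audit") <- NULL
  class(m) <- NULL
  m
}

# brute-force Pearson correlation (explicit sums, no stats::cor)
pearson_brute <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# independent enumeration of an RBM's Boltzmann distribution via explicit
# per-state loops and the energy formula written out by hand
enumerate_rbm_brute <- function(W, b, c) {
  nv <- ncol(W); nh <- nrow(W)
  vs <- as.matrix(expand.grid(rep(list(0:1), nv)))
  hs <- as.matrix(expand.grid(rep(list(0:1), nh)))
  p <- matrix(0, nrow(vs), nrow(hs))
  for (a in seq_len(nrow(vs))) for (bb in seq_len(nrow(hs))) {
    v <- vs[a, ]; h <- hs[bb, ]
    e <- 0
    for (j in seq_len(nh)) for (i in seq_len(nv))
      e <- e - h[j] * W[j, i] * v[i]
    e <- e - sum(c * v) - sum(b * h)
    p[a, bb] <- exp(-e)
  }
  p / sum(p)
}

# exact gradient of log P(v) wrt W for one visible vector, by enumeration
exact_rbm_gradient <- function(W, b, c, v) {
  nh <- nrow(W)
  ph <- 1 / (1 + exp(-(W %*% v + b)))          # p(h_j = 1 | v)
  positive <- ph %*% t(v)
  br <- enumerate_rbm_brute(W, b, c)
  vs <- as.matrix(expand.grid(rep(list(0:1), ncol(W))))
  hs <- as.matrix(expand.grid(rep(list(0:1), nh)))
  negative <- matrix(0, nrow(W), ncol(W))
  for (a in seq_len(nrow(vs))) for (bb in seq_len(nrow(hs)))
    negative <- negative + br[a, bb] * (hs[bb, ] %*% t(vs[a, ]))
  positive - negative
}

# brute-force average-linkage agglomeration recording merge order
average_linkage_brute <- function(X) {
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(n))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d) { best_d <- dij; best <- c(i, j) }
    }
    merges[[length(merges) + 1L]] <-
      list(members = sort(c(clusters[[best[1L]]], clusters[[best[2L]]])),
           height = best_d)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  merges
}

# Kaplan-Meier product-limit by direct sequential arithmetic
km_brute <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ts, survival = out)
}
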