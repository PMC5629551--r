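test_that("the product-limit estimator matches hand arithmetic", {
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km$survival, c(0.5, 0))
  expect_equal(km$n_risk, c(2, 1))

  # all censored: survival stays at 1
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$survival == 1))
  expect_true(all(km2$n_censor == 1))

  # order invariance
  t <- c(5, 1, 3, 2, 4); e <- c(1, 0, 1, 1, 0)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(km_estimate(t, e), km_estimate(t[perm], e[perm]))

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("with no censoring the KM curve equals one minus the empirical CDF", {
  set.seed(3)
  t <- rexp(50)
  km <- km_estimate(t, rep(1, 50))
  ecdf_vals <- 1 - ecdf(t)(km$time)
  expect_equal(km$survival, ecdf_vals, tolerance = 1e-12)
})

test_that("KM and log-rank agree with the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(9)
  t <- round(rexp(60, 0.2), 2)
  e <- rbinom(60, 1, 0.7)
  g <- sample(c("a", "b", "c"), 60, replace = TRUE)
  fit <- survival::survfit(survival::Surv(t, e) ~ 1)
  km <- km_estimate(t, e)
  ours <- km$survival[km$n_event > 0]
  expect_equal(ours, fit$surv[fit$n.event > 0], tolerance = 1e-10)
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-8)
  expect_equal(lr$p_value, stats::pchisq(sd$chisq, 2, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("log-rank on a toy fixture matches the hand observed/expected table", {
  # group A: events at 1, 3; censored at 4. group B: events at 2, 4, 5.
  t <- c(1, 3, 4, 2, 4, 5)
  e <- c(1, 1, 0, 1, 1, 1)
  g <- c("A", "A", "A", "B", "B", "B")
  # hand table over event times 1,2,3,4,5:
  # t=1: risk 6 (3A,3B), 1 event in A. E_A += 1*3/6 = 0.5, V += 1*5/5*(3/6)(3/6)=0.25
  # t=2: risk 5 (2A,3B), 1 event in B. E_A += 2/5 = 0.4,  V += (2/5)(3/5)=0.24
  # t=3: risk 4 (2A,2B), 1 event in A. E_A += 0.5,        V += 0.25
  # t=4: risk 3 (1A,2B), 1 event in B (A censored at 4 still at risk at t=4).
  #      E_A += 1/3, V += (1/3)(2/3) = 2/9
  # t=5: risk 1 (0A,1B), 1 event in B. E_A += 0, V += 0
  O_A <- 2; E_A <- 0.5 + 0.4 + 0.5 + 1 / 3
  V_A <- 0.25 + 0.24 + 0.25 + 2 / 9
  stat_hand <- (O_A - E_A)^2 / V_A
  lr <- logrank_test(t, e, g)
  expect_equal(lr$statistic, stat_hand, tolerance = 1e-10)
  expect_identical(lr$df, 1L)
  expect_equal(lr$table$observed, c(2, 3))
  expect_equal(lr$table$expected[1], E_A, tolerance = 1e-10)
})

test_that("identical groups give statistic 0 and p = 1", {
  t <- c(1, 2, 3, 1, 2, 3)
  e <- c(1, 1, 0, 1, 1, 0)
  g <- rep(c("x", "y"), each = 3)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(t, rep(0, 6), g), "no events")
})

test_that("log-rank is invariant to time rescaling and group relabeling", {
  set.seed(4)
  t <- rexp(40); e <- rbinom(40, 1, 0.8); g <- rep(1:2, 20)
  a <- logrank_test(t, e, g)
  b <- logrank_test(t * 365, e, g)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  c_ <- logrank_test(t, e, c("B", "A")[g])
  expect_equal(a$statistic, c_$statistic, tolerance = 1e-12)
})

test_that("planted hazard differences are detected", {
  co <- make_test_cohort(seed = 31, n_tissues = 1L,
                         tumors_per_tissue = 200L, n_subtypes = 2L,
                         subtype_hazard_ratios = c(1, 3))
  tum <- co$is_tumor == 1L
  lr <- logrank_test(co$survival_time[tum], co$survival_event[tum],
                     co$true_subtype[tum])
  expect_lt(lr$p_value, 0.01)
})

test_that("cluster correlates rank features by one-vs-rest Pearson r", {
  labels <- rep(1:2, each = 5)
  ind <- as.numeric(labels == 1)
  f <- cbind(exact = ind,                    # r = 1 with cluster 1
             anti = 1 - ind,                 # r = -1 with cluster 1
             flat = rep(1, 10),              # zero variance -> excluded
             noisy = c(1, 1, 1, 0, 1, 0, 0, 1, 0, 0))
  tab <- cluster_correlates(f, labels, top_k = 3)
  top1 <- tab$top[tab$top$cluster == 1, ]
  expect_identical(top1$feature[1], "exact")
  expect_equal(top1$r[1], 1)
  expect_false("anti" %in% top1$feature)     # negative r never ranked
  expect_identical(tab$excluded$feature, "flat")
  expect_identical(tab$n, 10L)
  # r values match the brute-force Pearson oracle
  for (i in seq_len(nrow(tab$full))) {
    row <- tab$full[i, ]
    expect_equal(row$r,
                 pearson_brute(f[, row$feature],
                               as.numeric(labels == row$cluster)),
                 tolerance = 1e-12)
  }
})

test_that("word-cloud weights are scaled within, not across, clusters", {
  labels <- rep(1:2, each = 6)
  set.seed(8)
  f <- cbind(a = as.numeric(labels == 1),
             b = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 1, 0),
             c = as.numeric(labels == 2),
             d = c(0, 1, 0, 0, 0, 0, 1, 1, 0, 1, 1, 1))
  tab <- cluster_correlates(f, labels, top_k = 2)
  wc <- export_wordcloud_table(tab)
  for (cl in unique(wc$cluster)) {
    w <- wc$weight[wc$cluster == cl]
    r <- wc$r[wc$cluster == cl]
    expect_equal(max(w), 1)                     # each cluster has weight 1
    expect_identical(order(w), order(r))        # weights ordered as r
  }
})

test_that("planted driver mutations surface in their cluster's top list", {
  co <- make_test_cohort(seed = 17, n_tissues = 1L,
                         tumors_per_tissue = 90L,
                         mutations_per_subtype = 2L,
                         mutation_enrichment = 0.6,
                         mutation_background = 0.05)
  tum <- co$is_tumor == 1L
  tab <- cluster_correlates(co$mutations[tum, ], co$true_subtype[tum],
                            top_k = 10)
  hits <- 0L; total <- 0L
  for (s in 1:3) {
    planted <- co$gene_ids[co$driver_genes[[paste0("subtype", s)]]]
    top <- tab$top$feature[tab$top$cluster == s]
    hits <- hits + sum(planted %in% top)
    total <- total + length(planted)
  }
  expect_gte(hits / total, 0.8)
})

test_that("downstream artifacts are written completely", {
  co <- make_test_cohort(seed = 19, n_tissues = 1L, tumors_per_tissue = 40L)
  tum <- which(co$is_tumor == 1L)
  labels <- co$true_subtype[tum]
  names(labels) <- co$sample_ids[tum]
  dir <- withr::local_tempdir()
  write_downstream(co$survival_time[tum], co$survival_event[tum], labels,
                   dir, deg_features = plain_matrix(cohort_aberrations(co)),
                   mutation_features = co$mutations[tum, ])
  expect_true(all(file.exists(file.path(dir,
    c("km_curves.tsv", "logrank.txt", "correlates_degs.tsv",
      "correlates_mutations.tsv")))))
  lr_lines <- readLines(file.path(dir, "logrank.txt"))
  expect_match(lr_lines[1], "chi_square")
})
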