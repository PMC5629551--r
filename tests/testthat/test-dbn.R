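worked_rbm <- function() {
  # 2 visible, 1 hidden worked example
  structure(list(W = matrix(c(0.5, -0.2), 1, 2), b = 0.1, c = c(0.3, 0)),
            class = "rbm_params")
}

test_that("the energy function matches hand arithmetic and is linear", {
  p <- worked_rbm()
  expect_identical(rbm_energy(c(0, 0), 0, p), 0)
  # E = -(h'Wv + c'v + b'h) = -(0.5 + 0.3 + 0.1) = -0.9
  expect_equal(rbm_energy(c(1, 0), 1, p), -0.9)
  p2 <- p; p2$W <- 2 * p$W; p2$b <- 2 * p$b; p2$c <- 2 * p$c
  expect_equal(rbm_energy(c(1, 0), 1, p2), -1.8)
  expect_error(rbm_energy(c(1, 0, 0), 1, p), "dimension")
})

test_that("exact distribution normalizes, is uniform at zero energy, and matches enumeration", {
  p0 <- structure(list(W = matrix(0, 2, 3), b = c(0, 0), c = c(0, 0, 0)),
                  class = "rbm_params")
  d0 <- rbm_exact_distribution(p0)
  expect_equal(sum(d0$prob), 1, tolerance = 1e-12)
  expect_true(all(abs(d0$prob - 1 / 32) < 1e-12))

  d <- rbm_exact_distribution(worked_rbm())
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  brute <- enumerate_rbm_brute(worked_rbm()$W, 0.1, c(0.3, 0))
  expect_equal(unname(d$prob), unname(brute), tolerance = 1e-12)

  set.seed(99)
  for (i in 1:5) {
    W <- matrix(rnorm(6), 2, 3)
    p <- structure(list(W = W, b = rnorm(2), c = rnorm(3)),
                   class = "rbm_params")
    expect_equal(unname(rbm_exact_distribution(p)$prob),
                 unname(enumerate_rbm_brute(p$W, p$b, p$c)),
                 tolerance = 1e-10)
  }
  big <- structure(list(W = matrix(0, 11, 10), b = numeric(11),
                        c = numeric(10)), class = "rbm_params")
  expect_error(rbm_exact_distribution(big), "too large")
})

test_that("exact log-likelihood agrees with the enumerated marginal", {
  p <- worked_rbm()
  d <- rbm_exact_distribution(p)
  data <- rbind(c(1, 0), c(0, 1))
  idx <- apply(data, 1, function(v)
    which(apply(d$v_states, 1, function(s) all(s == v))))
  expect_equal(rbm_exact_loglik(p, data), mean(log(d$prob_v[idx])),
               tolerance = 1e-10)
})

test_that("CD-1 training raises exact training-set log-likelihood on tiny RBMs", {
  set.seed(5)
  data <- matrix(rbinom(8 * 3, 1, c(0.9, 0.1, 0.8)[rep(1:3, each = 8)]),
                 8, 3)
  improved <- 0L
  for (seed in 1:20) {
    cfg <- train_config(2, lr_pretrain = 0.2, epochs_pretrain = 30,
                        batch_size = 4, seed = seed)
    init <- structure(list(W = {set.seed(seed); matrix(rnorm(6, sd = 0.01), 2, 3)},
                           b = c(0, 0), c = c(0, 0, 0)),
                      class = "rbm_params")
    fit <- rbm_train_cd(data, 2, cfg)
    if (rbm_exact_loglik(fit, data) > rbm_exact_loglik(init, data))
      improved <- improved + 1L
  }
  expect_gte(improved, 19L)
})

test_that("the CD update points in the direction of the exact gradient on average", {
  v <- c(1, 0, 1)
  cos_sims <- numeric(100)
  for (seed in 1:100) {
    cfg <- train_config(2, lr_pretrain = 1, epochs_pretrain = 1,
                        batch_size = 1, cd_steps = 1, seed = seed)
    set.seed(seed)
    W0 <- matrix(rnorm(6, sd = 0.01), 2, 3)
    fit <- rbm_train_cd(matrix(v, 1, 3), 2, cfg)
    delta <- fit$W - W0                     # single update, lr = 1
    g <- exact_rbm_gradient(W0, c(0, 0), c(0, 0, 0), v)
    cos_sims[seed] <- sum(delta * g) / sqrt(sum(delta^2) * sum(g^2))
  }
  expect_gt(mean(cos_sims), 0)
})

test_that("zero learning rate leaves parameters at their initialization", {
  data <- matrix(rbinom(12, 1, 0.5), 4, 3)
  cfg <- train_config(2, lr_pretrain = 0, epochs_pretrain = 5,
                      batch_size = 2, seed = 3)
  fit <- rbm_train_cd(data, 2, cfg)
  set.seed(3)
  W0 <- matrix(rnorm(6, sd = 0.01), 2, 3)
  expect_equal(fit$W, W0)
  expect_equal(fit$b, c(0, 0))
})

test_that("stacked pre-training produces the contracted shapes, reproducibly", {
  set.seed(2)
  data <- matrix(rbinom(30 * 40, 1, 0.3), 30, 40)
  cfg <- train_config(c(12, 6, 3), epochs_pretrain = 2, batch_size = 10,
                      seed = 11)
  rbms <- stack_pretrain(data, cfg)
  expect_length(rbms, 3L)
  expect_identical(dim(rbms[[1]]$W), c(12L, 40L))
  expect_identical(dim(rbms[[2]]$W), c(6L, 12L))
  expect_identical(dim(rbms[[3]]$W), c(3L, 6L))
  rbms2 <- stack_pretrain(data, cfg)
  expect_identical(rbms[[3]]$W, rbms2[[3]]$W)

  # one layer equals a single RBM trained with the same seed
  cfg1 <- train_config(5, epochs_pretrain = 2, batch_size = 10, seed = 11)
  one <- stack_pretrain(data, cfg1)
  direct <- rbm_train_cd(data, 5, cfg1)
  expect_equal(one[[1]]$W, direct$W)
})

test_that("unfolding unties encoder and decoder weights", {
  set.seed(1)
  data <- matrix(rbinom(20 * 10, 1, 0.4), 20, 10)
  cfg <- train_config(c(6, 3), epochs_pretrain = 2, batch_size = 5, seed = 1)
  model <- unfold(stack_pretrain(data, cfg))
  expect_length(model$encoder, 2L)
  expect_length(model$decoder, 2L)
  expect_equal(model$encoder[[1]]$W, model$decoder[[1]]$W) # tied at start
  model$decoder[[1]]$W[1, 1] <- 99
  expect_false(model$encoder[[1]]$W[1, 1] == 99)

  # reconstruction is the deterministic up-then-down pass
  acts <- deepsubtype:::dbn_forward(model, data)
  top <- acts[[length(acts)]]
  manual <- deepsubtype:::dbn_decode(model, top)[[1]]
  expect_equal(dbn_reconstruct(model, data), manual)
})

test_that("reconstruction metrics match closed forms and hand arithmetic", {
  # fixture model: 2 visible, 1 hidden with fixed weights
  rbm <- structure(list(W = matrix(c(1, -1), 1, 2), b = 0.5, c = c(0, 0.2)),
                   class = "rbm_params")
  model <- unfold(list(rbm))
  x <- rbind(c(1, 0), c(0, 1))
  # hand forward pass
  h <- 1 / (1 + exp(-(x %*% t(rbm$W) + 0.5)))
  y <- 1 / (1 + exp(-(cbind(h) %*% rbm$W + rep(c(0, 0.2), each = 2))))
  expect_equal(reconstruction_error(model, x), mean((x - y)^2),
               tolerance = 1e-12)
  expect_equal(cross_entropy(model, x),
               -mean(x * log(y) + (1 - x) * log(1 - y)), tolerance = 1e-12)

  # all-0.5 reconstructions give cross-entropy ln 2 per unit
  flat <- structure(list(W = matrix(0, 1, 2), b = 0, c = c(0, 0)),
                    class = "rbm_params")
  mflat <- unfold(list(flat))
  expect_equal(cross_entropy(mflat, x), log(2), tolerance = 1e-12)
  expect_equal(reconstruction_error(mflat, x), 0.25, tolerance = 1e-12)
})

test_that("fine-tuning reduces cross-entropy and can overtrain a tiny sample", {
  set.seed(8)
  data <- matrix(rbinom(5 * 12, 1, 0.5), 5, 12)
  cfg <- train_config(c(10, 4), lr_pretrain = 0.5, lr_finetune = 1,
                      epochs_pretrain = 200, epochs_finetune = 500,
                      batch_size = 5, seed = 8)
  model <- train_dbn(data, cfg)
  log <- model$training_log
  expect_lt(log$cross_entropy[nrow(log)], 0.05)
  # non-increasing in >= 90% of steps
  steps <- diff(log$cross_entropy)
  expect_gte(mean(steps <= 0), 0.9)
  # reconstructions are strict probabilities
  y <- dbn_reconstruct(model, data)
  expect_true(all(y > 0 & y < 1))
  # shapes unchanged by fine-tuning
  expect_identical(dim(model$encoder[[1]]$W), c(10L, 12L))
  expect_identical(dim(model$decoder[[1]]$W), c(10L, 12L))
})

test_that("encodings have the top-layer shape and are deterministic", {
  set.seed(4)
  data <- matrix(rbinom(30 * 50, 1, 0.3), 30, 50)
  cfg <- train_config(c(20, 10, 5), epochs_pretrain = 3,
                      epochs_finetune = 5, batch_size = 10, seed = 4)
  model <- train_dbn(data, cfg)
  enc <- dbn_encode(model, data)
  expect_identical(dim(enc), c(30L, 5L))
  expect_identical(enc, dbn_encode(model, data))
  # duplicated samples encode identically
  enc2 <- dbn_encode(model, data[c(1, 1, 7, 7), ])
  expect_identical(enc2[1, ], enc2[2, ])
  expect_identical(enc2[3, ], enc2[4, ])
  expect_error(dbn_encode(model, data[, 1:10]), "genes")
})

test_that("subtype structure separates in the encoding space", {
  co <- make_test_cohort(seed = 21, n_tissues = 1L, tumors_per_tissue = 60L,
                         n_genes = 80L, n_subtypes = 2L, effect_size = 4)
  ab <- plain_matrix(cohort_aberrations(co))
  cfg <- train_config(c(20, 8, 4), epochs_pretrain = 8,
                      epochs_finetune = 20, batch_size = 20, seed = 21)
  model <- train_dbn(ab, cfg)
  enc <- dbn_encode(model, ab)
  sub <- co$true_subtype[co$is_tumor == 1L]
  centroids <- rbind(colMeans(enc[sub == 1, ]), colMeans(enc[sub == 2, ]))
  between <- sqrt(sum((centroids[1, ] - centroids[2, ])^2))
  within <- mean(sapply(1:2, function(s) {
    e <- enc[sub == s, ]
    mean(sqrt(rowSums(sweep(e, 2, colMeans(e))^2)))
  }))
  expect_gt(between, within)
})

test_that("models serialize and restore bit-exactly", {
  set.seed(10)
  data <- matrix(rbinom(20 * 15, 1, 0.4), 20, 15,
                 dimnames = list(NULL, paste0("G", 1:15)))
  cfg <- train_config(c(8, 3), epochs_pretrain = 2, epochs_finetune = 3,
                      batch_size = 5, seed = 10)
  model <- train_dbn(data, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_dbn(model, path)
  back <- read_dbn(path)
  expect_identical(back$layer_sizes, model$layer_sizes)
  expect_identical(back$gene_ids, model$gene_ids)
  for (l in 1:2) {
    expect_identical(back$encoder[[l]]$W, model$encoder[[l]]$W)
    expect_identical(back$decoder[[l]]$W, model$decoder[[l]]$W)
    expect_identical(back$encoder[[l]]$b, model$encoder[[l]]$b)
  }
  expect_identical(dbn_encode(back, data), dbn_encode(model, data))
})

test_that("divergent fine-tuning aborts with a diagnostic", {
  set.seed(2)
  data <- matrix(rbinom(10 * 8, 1, 0.5), 10, 8)
  cfg <- train_config(c(6), lr_pretrain = 0.05, lr_finetune = 500,
                      epochs_pretrain = 2, epochs_finetune = 50,
                      batch_size = 5, seed = 2)
  rbms <- stack_pretrain(data, cfg)
  expect_error(finetune(unfold(rbms), data, cfg), "diverged|lower")
})
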