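# Bernoulli RBM stack: contrastive-divergence pre-training, unfolding into
# a deep autoencoder, cross-entropy fine-tuning, and encoding.
#
# Conventions: data matrices are samples x visible; an RBM's weight matrix W
# is hidden x visible with hidden offsets b and visible offsets c, so the
# energy of a configuration is E(v, h) = -(h' W v + c' v + b' h).

sigmoid <- function(x) 1 / (1 + exp(-x))

clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Training configuration for RBM pre-training and autoencoder fine-tuning
#'
#' @param layer_sizes Integer vector of hidden layer sizes, bottom-up.
#' @param lr_pretrain,lr_finetune Positive learning rates for CD
#'   pre-training and SGD fine-tuning.
#' @param epochs_pretrain,epochs_finetune Training durations in epochs.
#' @param batch_size Minibatch size; batches are reshuffled every epoch.
#' @param cd_steps Gibbs steps per contrastive-divergence update (k in
#'   CD-k).
#' @param momentum,weight_decay Optional classical momentum and L2 penalty;
#'   both 0 by default.
#' @param seed Integer seed controlling weight initialization and batch
#'   order.
#' @return Object of class \code{train_config}.
#' @export
train_config <- function(layer_sizes, lr_pretrain = 0.5, lr_finetune = 0.5,
                         epochs_pretrain = 50L, epochs_finetune = 100L,
                         batch_size = 50L, cd_steps = 1L,
                         momentum = 0, weight_decay = 0, seed = 1L) {
  stopifnot(length(layer_sizes) >= 1L, all(layer_sizes >= 1L),
            lr_pretrain > 0 || lr_pretrain == 0,
            lr_finetune > 0 || lr_finetune == 0,
            epochs_pretrain >= 0L, epochs_finetune >= 0L,
            batch_size >= 1L, cd_steps >= 1L)
  structure(list(layer_sizes = as.integer(layer_sizes),
                 lr_pretrain = lr_pretrain, lr_finetune = lr_finetune,
                 epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_finetune = as.integer(epochs_finetune),
                 batch_size = as.integer(batch_size),
                 cd_steps = as.integer(cd_steps),
                 momentum = momentum, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

new_rbm <- function(W, b, c) {
  stopifnot(is.matrix(W), length(b) == nrow(W), length(c) == ncol(W),
            all(is.finite(W)), all(is.finite(b)), all(is.finite(c)))
  dimnames(W) <- NULL
  structure(list(W = W, b = unname(as.numeric(b)),
                 c = unname(as.numeric(c))),
            class = "rbm_params")
}

#' RBM energy of a joint configuration
#'
#' \code{E(v, h) = -(h' W v + c' v + b' h)} for binary visible vector
#' \code{v} and hidden vector \code{h}.
#'
#' @param v,h Binary state vectors (visible, hidden).
#' @param p An \code{rbm_params} object with fields \code{W} (hidden x
#'   visible), \code{b} (hidden offsets), \code{c} (visible offsets).
#' @return Scalar energy.
#' @export
rbm_energy <- function(v, h, p) {
  if (length(v) != ncol(p$W) || length(h) != nrow(p$W))
    stop("dimension mismatch between states and parameters")
  -(as.numeric(h %*% p$W %*% v) + sum(p$c * v) + sum(p$b * h))
}

all_binary_states <- function(n) {
  if (n == 0L) return(matrix(0, 1L, 0L))
  g <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dimnames(g) <- NULL
  g
}

#' Exact Boltzmann distribution of a small RBM by enumeration
#'
#' Enumerates all joint states (v, h), computes Boltzmann weights
#' \code{exp(-E)} and normalizes by the partition function Z. Only feasible
#' for tiny models (at most 20 total units); intended as an oracle for
#' testing the learning code.
#'
#' @param p An \code{rbm_params}.
#' @return List with the visible and hidden state matrices, the joint
#'   probability matrix \code{prob} (visible states in rows), the marginal
#'   \code{prob_v}, and \code{log_z}.
#' @export
rbm_exact_distribution <- function(p) {
  nv <- ncol(p$W); nh <- nrow(p$W)
  if (nv + nh > 20L) stop("state space too large for enumeration (> 20 units)")
  V <- all_binary_states(nv)
  H <- all_binary_states(nh)
  # energy matrix over (v, h) pairs, vectorized: E[a, b] = E(V[a,], H[b,])
  E <- -(V %*% t(p$W) %*% t(H)) - as.numeric(V %*% p$c) -
    rep(as.numeric(H %*% p$b), each = nrow(V))
  m <- max(-E)
  w <- exp(-E - m)
  z <- sum(w)
  list(v_states = V, h_states = H, prob = w / z, prob_v = rowSums(w / z),
       log_z = log(z) + m)
}

#' Exact log-likelihood of binary data under a small RBM
#'
#' Uses the free-energy form \code{log P(v) = -F(v) - log Z} with
#' \code{F(v) = -c'v - sum_j log(1 + exp(W v + b)_j)}; the partition
#' function is obtained by enumerating visible states (at most 20 visible
#' units).
#'
#' @param p An \code{rbm_params}.
#' @param data Binary samples x visible matrix.
#' @return Mean log-likelihood per sample.
#' @export
rbm_exact_loglik <- function(p, data) {
  nv <- ncol(p$W)
  if (nv > 20L) stop("too many visible units for enumeration")
  free_energy <- function(V)
    -as.numeric(V %*% p$c) -
      rowSums(log1p(exp(sweep(V %*% t(p$W), 2L, p$b, `+`))))
  V <- all_binary_states(nv)
  fv <- -free_energy(V)
  m <- max(fv)
  log_z <- log(sum(exp(fv - m))) + m
  mean(-free_energy(data) - log_z)
}

rbm_hidden_prob <- function(p, v) # samples x hidden
  sigmoid(sweep(v %*% t(p$W), 2L, p$b, `+`))

rbm_visible_prob <- function(p, h) # samples x visible
  sigmoid(sweep(h %*% p$W, 2L, p$c, `+`))

#' Train a Bernoulli RBM by contrastive divergence
#'
#' Minibatch CD-k: the positive phase uses mean-field hidden probabilities
#' for the gradient statistics but samples binary hidden states to start the
#' Gibbs chain; reconstructions use visible probabilities (not samples), and
#' the negative statistics use the chain's final mean-field hidden
#' probabilities. Weights start at N(0, 0.01^2), offsets at zero.
#'
#' @param data Binary samples x visible matrix.
#' @param n_hidden Number of hidden units.
#' @param cfg A [train_config()]; uses \code{lr_pretrain},
#'   \code{epochs_pretrain}, \code{batch_size}, \code{cd_steps},
#'   \code{momentum}, \code{weight_decay} and \code{seed}.
#' @return An \code{rbm_params} with a per-epoch \code{training_log}
#'   (mean squared reconstruction error) attribute.
#' @export
rbm_train_cd <- function(data, n_hidden, cfg) {
  stopifnot(inherits(cfg, "train_config"), n_hidden >= 1L)
  data <- as.matrix(data)
  n <- nrow(data); nv <- ncol(data)
  set.seed(cfg$seed)
  W <- matrix(stats::rnorm(n_hidden * nv, sd = 0.01), n_hidden, nv)
  b <- numeric(n_hidden); c <- numeric(nv)
  vW <- W * 0; vb <- b; vc <- c
  recon_err <- numeric(cfg$epochs_pretrain)
  lr <- cfg$lr_pretrain
  for (epoch in seq_len(cfg$epochs_pretrain)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    err <- 0
    for (batch in batches) {
      v0 <- data[batch, , drop = FALSE]
      m <- nrow(v0)
      ph0 <- sigmoid(sweep(v0 %*% t(W), 2L, b, `+`))
      h <- matrix(as.numeric(stats::runif(length(ph0)) < ph0), m, n_hidden)
      for (step in seq_len(cfg$cd_steps)) {
        vk <- sigmoid(sweep(h %*% W, 2L, c, `+`))
        phk <- sigmoid(sweep(vk %*% t(W), 2L, b, `+`))
        if (step < cfg$cd_steps)
          h <- matrix(as.numeric(stats::runif(length(phk)) < phk), m, n_hidden)
      }
      dW <- (t(ph0) %*% v0 - t(phk) %*% vk) / m - cfg$weight_decay * W
      db <- colMeans(ph0) - colMeans(phk)
      dc <- colMeans(v0) - colMeans(vk)
      vW <- cfg$momentum * vW + lr * dW
      vb <- cfg$momentum * vb + lr * db
      vc <- cfg$momentum * vc + lr * dc
      W <- W + vW; b <- b + vb; c <- c + vc
      if (anyNA(W) || any(!is.finite(W)))
        stop("RBM training diverged (NaN in parameters); ",
             "lower the learning rate")
      err <- err + sum((v0 - vk)^2)
    }
    recon_err[epoch] <- err / (n * nv)
  }
  out <- new_rbm(W, b, c)
  attr(out, "training_log") <- data.frame(epoch = seq_len(cfg$epochs_pretrain),
                                          mse = recon_err)
  out
}

#' Layer-wise pre-training of a stack of RBMs
#'
#' Trains the first RBM on the data, then each subsequent RBM on the hidden
#' activation probabilities (mean-field, not samples) of the layer below.
#' Layer seeds are derived deterministically from \code{cfg$seed}.
#'
#' @param data Binary samples x genes matrix.
#' @param cfg A [train_config()] whose \code{layer_sizes} give the stack.
#' @return List of \code{rbm_params}, bottom-up.
#' @export
stack_pretrain <- function(data, cfg) {
  stopifnot(inherits(cfg, "train_config"), length(cfg$layer_sizes) >= 1L)
  x <- as.matrix(data)
  rbms <- vector("list", length(cfg$layer_sizes))
  for (l in seq_along(cfg$layer_sizes)) {
    layer_cfg <- cfg
    layer_cfg$seed <- (cfg$seed + 1000L * (l - 1L)) %% .Machine$integer.max
    rbms[[l]] <- rbm_train_cd(x, cfg$layer_sizes[l], layer_cfg)
    x <- rbm_hidden_prob(rbms[[l]], x)
  }
  rbms
}

#' Unfold a pre-trained RBM stack into a deep autoencoder
#'
#' The encoder takes the bottom-up weights; the decoder takes independent
#' (untied) copies applied top-down with the visible offsets. From this
#' point encoder and decoder weights evolve separately under fine-tuning.
#'
#' @param rbms List of \code{rbm_params}, bottom-up (from
#'   [stack_pretrain()]).
#' @param gene_ids Optional visible-feature ids recorded for encode-time
#'   checks.
#' @return Object of class \code{dbn_model} with \code{encoder} and
#'   \code{decoder} weight lists, \code{layer_sizes}, and an empty
#'   \code{training_log}.
#' @export
unfold <- function(rbms, gene_ids = NULL) {
  stopifnot(length(rbms) >= 1L)
  encoder <- lapply(rbms, function(r) list(W = r$W, b = r$b))
  decoder <- lapply(rbms, function(r) list(W = r$W, b = r$c))
  model <- list(encoder = encoder, decoder = decoder,
                layer_sizes = vapply(rbms, function(r) nrow(r$W), integer(1)),
                n_visible = ncol(rbms[[1L]]$W),
                gene_ids = gene_ids,
                training_log = data.frame(epoch = integer(),
                                          cross_entropy = numeric(),
                                          mse = numeric()))
  class(model) <- "dbn_model"
  model
}

#' @export
print.dbn_model <- function(x, ...) {
  cat(sprintf("dbn_model: %d visible -> [%s]%s\n", x$n_visible,
              paste(x$layer_sizes, collapse = "-"),
              if (nrow(x$training_log)) sprintf(
                ", fine-tuned %d epochs (final CE %.4f/unit)",
                max(x$training_log$epoch),
                x$training_log$cross_entropy[nrow(x$training_log)]) else
                  " (pre-trained only)"))
  invisible(x)
}

dbn_forward <- function(model, data) {
  acts <- vector("list", length(model$encoder) + 1L)
  acts[[1L]] <- as.matrix(data)
  for (l in seq_along(model$encoder))
    acts[[l + 1L]] <- sigmoid(sweep(acts[[l]] %*% t(model$encoder[[l]]$W),
                                    2L, model$encoder[[l]]$b, `+`))
  acts
}

dbn_decode <- function(model, top) {
  L <- length(model$decoder)
  zs <- vector("list", L + 1L)
  zs[[L + 1L]] <- top
  for (l in rev(seq_len(L)))
    zs[[l]] <- sigmoid(sweep(zs[[l + 1L]] %*% model$decoder[[l]]$W,
                             2L, model$decoder[[l]]$b, `+`))
  zs
}

#' Reconstruct input through the autoencoder
#'
#' One deterministic up-then-down pass: encoder to the top layer, decoder
#' back to visible probabilities.
#'
#' @param model A \code{dbn_model}.
#' @param data Binary samples x genes matrix.
#' @return Samples x genes matrix of reconstruction probabilities in (0, 1).
#' @export
dbn_reconstruct <- function(model, data) {
  acts <- dbn_forward(model, data)
  dbn_decode(model, acts[[length(acts)]])[[1L]]
}

#' Mean squared reconstruction error
#' @param model A \code{dbn_model}.
#' @param data Binary samples x genes matrix.
#' @return Mean over samples and units of squared reconstruction error.
#' @export
reconstruction_error <- function(model, data)
  mean((as.matrix(data) - dbn_reconstruct(model, data))^2)

#' Mean binary cross-entropy between data and reconstructions
#' @param model A \code{dbn_model}.
#' @param data Binary samples x genes matrix.
#' @return Mean cross-entropy per sample per unit (nats).
#' @export
cross_entropy <- function(model, data) {
  x <- as.matrix(data)
  y <- clip_prob(dbn_reconstruct(model, data))
  -mean(x * log(y) + (1 - x) * log(1 - y))
}

#' Fine-tune an unfolded autoencoder by backpropagation
#'
#' Plain minibatch stochastic gradient descent on the mean binary
#' cross-entropy between input and reconstruction, with logistic units and
#' deterministic probabilities throughout. The training log records
#' per-epoch cross-entropy and mean squared reconstruction error (and
#' held-out MSE when \code{eval_data} is given). Aborts when cross-entropy
#' exceeds 10x its initial value (divergence).
#'
#' @param model A \code{dbn_model} from [unfold()].
#' @param data Binary samples x genes matrix.
#' @param cfg A [train_config()]; uses \code{lr_finetune},
#'   \code{epochs_finetune}, \code{batch_size}, \code{seed}.
#' @param eval_data Optional held-out matrix; its per-epoch MSE is logged as
#'   \code{eval_mse}.
#' @return The fine-tuned \code{dbn_model} with a populated
#'   \code{training_log}.
#' @export
finetune <- function(model, data, cfg, eval_data = NULL) {
  stopifnot(inherits(model, "dbn_model"), inherits(cfg, "train_config"))
  x_all <- as.matrix(data)
  dimnames(x_all) <- NULL
  n <- nrow(x_all)
  L <- length(model$encoder)
  set.seed(cfg$seed + 500000L)
  init_ce <- cross_entropy(model, x_all)
  log_rows <- vector("list", cfg$epochs_finetune)
  lr <- cfg$lr_finetune
  for (epoch in seq_len(cfg$epochs_finetune)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (batch in batches) {
      x <- x_all[batch, , drop = FALSE]
      m <- nrow(x)
      acts <- dbn_forward(model, x)
      zs <- dbn_decode(model, acts[[L + 1L]])
      # output delta: sigmoid + cross-entropy cancels to (y - x)
      delta <- (zs[[1L]] - x) / m
      # decoder layers, bottom (visible) to top
      dec_grad <- vector("list", L)
      for (l in seq_len(L)) {
        dec_grad[[l]] <- list(W = t(zs[[l + 1L]]) %*% delta,
                              b = colSums(delta))
        delta <- (delta %*% t(model$decoder[[l]]$W))
        if (l < L) {
          a <- zs[[l + 1L]]
          delta <- delta * a * (1 - a)
        }
      }
      # delta now sits at the code layer output; continue down the encoder
      enc_grad <- vector("list", L)
      for (l in rev(seq_len(L))) {
        a <- acts[[l + 1L]]
        delta <- delta * a * (1 - a)
        enc_grad[[l]] <- list(W = t(delta) %*% acts[[l]],
                              b = colSums(delta))
        if (l > 1L) delta <- delta %*% model$encoder[[l]]$W
      }
      for (l in seq_len(L)) {
        model$encoder[[l]]$W <- model$encoder[[l]]$W - lr * enc_grad[[l]]$W
        model$encoder[[l]]$b <- model$encoder[[l]]$b - lr * enc_grad[[l]]$b
        model$decoder[[l]]$W <- model$decoder[[l]]$W - lr * dec_grad[[l]]$W
        model$decoder[[l]]$b <- model$decoder[[l]]$b - lr * dec_grad[[l]]$b
      }
    }
    ce <- cross_entropy(model, x_all)
    if (!is.finite(ce) || ce > 10 * max(init_ce, 1e-8))
      stop("fine-tuning diverged (cross-entropy ", signif(ce, 4),
           " vs initial ", signif(init_ce, 4), "); lower the learning rate")
    row <- data.frame(epoch = epoch, cross_entropy = ce,
                      mse = reconstruction_error(model, x_all))
    if (!is.null(eval_data))
      row$eval_mse <- reconstruction_error(model, eval_data)
    log_rows[[epoch]] <- row
  }
  model$training_log <- do.call(rbind, log_rows)
  model
}

#' Top-layer encoding of samples
#'
#' Deterministic forward pass through the encoder; returns the most
#' abstract (top hidden layer) representation of each sample, the features
#' used for consensus clustering.
#'
#' @param model A \code{dbn_model}.
#' @param data Binary samples x genes matrix with the same genes (and
#'   order) the model was trained on.
#' @return Samples x top-layer-size matrix.
#' @export
dbn_encode <- function(model, data) {
  data <- as.matrix(data)
  if (ncol(data) != model$n_visible)
    stop("input has ", ncol(data), " genes but model expects ",
         model$n_visible)
  if (!is.null(model$gene_ids) && !is.null(colnames(data)) &&
      !identical(colnames(data), model$gene_ids))
    stop("gene ids of input do not match the model's training genes")
  acts <- dbn_forward(model, data)
  out <- acts[[length(acts)]]
  rownames(out) <- rownames(data)
  out
}

#' Train a DBN end to end (pre-train, unfold, fine-tune)
#'
#' @param data Binary samples x genes matrix.
#' @param cfg A [train_config()].
#' @param eval_data Optional held-out matrix logged during fine-tuning.
#' @return A fine-tuned \code{dbn_model}.
#' @export
train_dbn <- function(data, cfg, eval_data = NULL) {
  rbms <- stack_pretrain(data, cfg)
  model <- unfold(rbms, gene_ids = colnames(data))
  finetune(model, data, cfg, eval_data = eval_data)
}

#' Serialize / restore a DBN model as JSON
#'
#' Plain-text container holding every layer matrix at full precision plus
#' the layer sizes, gene ids and training log; round-trips bit-exactly.
#'
#' @param model A \code{dbn_model}.
#' @param path File path.
#' @return \code{path} (write) or the restored \code{dbn_model} (read).
#' @export
write_dbn <- function(model, path) {
  flat <- function(l) list(w = as.numeric(l$W), nrow = nrow(l$W),
                           ncol = ncol(l$W), b = as.numeric(l$b))
  payload <- list(
    layer_sizes = model$layer_sizes, n_visible = model$n_visible,
    gene_ids = model$gene_ids,
    encoder = lapply(model$encoder, flat),
    decoder = lapply(model$decoder, flat),
    training_log = model$training_log)
  jsonlite::write_json(payload, path, digits = I(17))
  invisible(path)
}

#' @rdname write_dbn
#' @export
read_dbn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) vapply(x, as.numeric, numeric(1))
  relayer <- function(l)
    list(W = matrix(num(l$w), l$nrow[[1L]], l$ncol[[1L]]), b = num(l$b))
  log_df <- as.data.frame(lapply(p$training_log, unlist))
  model <- list(encoder = lapply(p$encoder, relayer),
                decoder = lapply(p$decoder, relayer),
                layer_sizes = vapply(p$layer_sizes, as.integer, 1L),
                n_visible = as.integer(p$n_visible[[1L]]),
                gene_ids = if (length(p$gene_ids))
                  vapply(p$gene_ids, as.character, "") else NULL,
                training_log = log_df)
  class(model) <- "dbn_model"
  model
}
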