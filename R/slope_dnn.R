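# Vertebral-slope regression network.
#
# The network maps a 2500-element patch vector P to a slope in degrees:
#
#   A(P) = b4 + W4 tanh(b3 + W3 tanh(b2 + W2 W1 (P - b1)))
#
# The first layer is fixed: b1 is the mean patch and the rows of W1 are the
# leading eigenvectors of the patch covariance (a PCA projection acting as a
# low-pass dimensionality reduction); it is frozen during training.  The two
# tanh hidden layers and the linear output are initialized by layer-wise
# autoencoder pretraining and then fine-tuned by backpropagation.

#' Training configuration for the slope network
#'
#' @param h2_size,h3_size hidden-layer widths (defaults 500 and 50; the
#'   alternatives 800/100 and 500/250 form the architecture comparison
#'   grid).
#' @param n_components retained principal components (default 100).
#' @param pretrain_learning_rate autoencoder gradient-descent rate
#'   (default 0.1).
#' @param pretrain_epochs epochs per autoencoder layer (default 20).
#' @param finetune_learning_rate backpropagation rate (default 0.01, applied
#'   to internally standardized labels).
#' @param finetune_epochs backpropagation epochs (default 50).
#' @param batch_size mini-batch size (default 128).
#' @param momentum classical momentum coefficient for both phases
#'   (default 0.9).
#' @param seed integer; training is fully determined by it.
#' @return validated list of class `training_config`.
#' @export
training_config <- function(h2_size = 500L, h3_size = 50L,
                            n_components = 100L,
                            pretrain_learning_rate = 0.1,
                            pretrain_epochs = 20L,
                            finetune_learning_rate = 0.01,
                            finetune_epochs = 50L,
                            batch_size = 128L, momentum = 0.9,
                            seed = 1L) {
  cfg <- list(h2_size = as.integer(h2_size), h3_size = as.integer(h3_size),
              n_components = as.integer(n_components),
              pretrain_learning_rate = pretrain_learning_rate,
              pretrain_epochs = as.integer(pretrain_epochs),
              finetune_learning_rate = finetune_learning_rate,
              finetune_epochs = as.integer(finetune_epochs),
              batch_size = as.integer(batch_size), momentum = momentum,
              seed = as.integer(seed))
  for (nm in c("h2_size", "h3_size", "n_components", "pretrain_epochs",
               "finetune_epochs", "batch_size")) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      stop("training_config: ", nm, " must be a count >= 1, got ", cfg[[nm]])
    }
  }
  for (nm in c("pretrain_learning_rate", "finetune_learning_rate")) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("training_config: ", nm, " must be > 0, got ", cfg[[nm]])
    }
  }
  if (cfg$momentum < 0 || cfg$momentum >= 1) {
    stop("training_config: momentum must be in [0, 1), got ", cfg$momentum)
  }
  structure(cfg, class = "training_config")
}

patch_matrix <- function(patches) {
  if (inherits(patches, "patch_set")) {
    if (is.null(patches$vectors)) {
      stop("patch_set carries no pixel vectors (sampled with vectors = FALSE)")
    }
    patches$vectors
  } else if (is.matrix(patches)) {
    patches
  } else if (is.numeric(patches)) {
    matrix(patches, nrow = 1)
  } else {
    stop("expected a patch_set, a patch matrix, or a single patch vector")
  }
}

patch_labels <- function(patches) {
  if (inherits(patches, "patch_set")) patches$meta$label else attr(patches, "labels")
}

#' Fit the PCA first layer
#'
#' Computes the mean patch `b1` and the weight matrix `W1` whose rows are
#' the leading `n_components` eigenvectors of the patch covariance matrix,
#' ordered by decreasing eigenvalue.  Eigenvector signs are fixed (largest
#' absolute component positive) so the layer is deterministic.
#'
#' @param patches a `patch_set` or an N x 2500 matrix (N > `n_components`).
#' @param n_components number of eigenvectors retained (default 100).
#' @return list with `W1` (n_components x 2500), `b1` (length 2500), and
#'   `eigenvalues` (decreasing, length n_components).
#' @export
fit_pca_layer <- function(patches, n_components = 100L) {
  X <- patch_matrix(patches)
  n <- nrow(X); d <- ncol(X)
  if (n < n_components + 1L) {
    stop("fit_pca_layer needs at least ", n_components + 1L,
         " patches for a rank-", n_components, " basis, got ", n)
  }
  b1 <- colMeans(X)
  # covariance without materializing the centered matrix
  C <- (crossprod(X) - n * tcrossprod(b1)) / (n - 1)
  eig <- eigen(C, symmetric = TRUE)
  V <- eig$vectors[, seq_len(n_components), drop = FALSE]
  # deterministic sign: largest-magnitude component of each eigenvector > 0
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  list(W1 = t(V), b1 = b1,
       eigenvalues = eig$values[seq_len(n_components)])
}

# project patch rows onto the PCA layer: rows of X -> rows of Z (N x h1)
pca_project <- function(X, W1, b1) {
  X %*% t(W1) - rep(1, nrow(X)) %o% as.vector(W1 %*% b1)
}

new_dnn_parameters <- function(W1, b1, W2, b2, W3, b3, W4, b4, config,
                               history = list()) {
  structure(
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3,
         W4 = W4, b4 = b4,
         sizes = list(n_components = nrow(W1), h2 = nrow(W2), h3 = nrow(W3)),
         config = config, history = history,
         pipeline_version = as.character(utils::packageVersion("cobbnet"))),
    class = "dnn_parameters"
  )
}

#' @export
print.dnn_parameters <- function(x, ...) {
  s <- x$sizes
  cat(sprintf("Slope network: 2500 -> %d (PCA) -> %d -> %d -> 1\n",
              s$n_components, s$h2, s$h3))
  if (length(x$history$finetune)) {
    cat(sprintf("  final fine-tuning MSE %.3f deg^2 (%d epochs)\n",
                tail(x$history$finetune, 1), length(x$history$finetune)))
  }
  invisible(x)
}

validate_dnn_shapes <- function(p) {
  d <- ncol(p$W1)
  if (length(p$b1) != d) stop("layer 1 shape mismatch: b1 vs W1")
  if (ncol(p$W2) != nrow(p$W1)) stop("layer 2 shape mismatch: W2 vs W1")
  if (length(p$b2) != nrow(p$W2)) stop("layer 2 shape mismatch: b2 vs W2")
  if (ncol(p$W3) != nrow(p$W2)) stop("layer 3 shape mismatch: W3 vs W2")
  if (length(p$b3) != nrow(p$W3)) stop("layer 3 shape mismatch: b3 vs W3")
  if (ncol(p$W4) != nrow(p$W3)) stop("layer 4 shape mismatch: W4 vs W3")
  if (length(p$b4) != 1) stop("layer 4 shape mismatch: b4 must be scalar")
  invisible(p)
}

#' Evaluate the slope network
#'
#' Computes `b4 + W4 tanh(b3 + W3 tanh(b2 + W2 W1 (P - b1)))` for one patch
#' vector or for every row of a patch matrix.
#'
#' @param params a `dnn_parameters` object.
#' @param patches length-2500 vector, N x 2500 matrix, or `patch_set`.
#' @return numeric vector of slopes in degrees (length N).
#' @export
forward_dnn <- function(params, patches) {
  validate_dnn_shapes(params)
  X <- patch_matrix(patches)
  if (ncol(X) != ncol(params$W1)) {
    stop("layer 1 shape mismatch: patch length ", ncol(X),
         " but W1 expects ", ncol(params$W1))
  }
  Z <- pca_project(X, params$W1, params$b1)
  forward_from_latent(params, Z)
}

forward_from_latent <- function(params, Z) {
  ones <- rep(1, nrow(Z))
  A2 <- tanh(Z %*% t(params$W2) + ones %o% params$b2)
  A3 <- tanh(A2 %*% t(params$W3) + ones %o% params$b3)
  as.vector(A3 %*% t(params$W4) + params$b4)
}

#' @export
predict.dnn_parameters <- function(object, newdata, ...) {
  forward_dnn(object, newdata)
}

# one tied-weight autoencoder layer trained by mini-batch gradient descent
# with momentum; returns encoder weights/biases and the per-epoch mean
# reconstruction loss. RNG is the caller's (pretrain seeds it once).
train_autoencoder <- function(Z, hidden, lr, epochs, batch_size, momentum) {
  n <- nrow(Z); d <- ncol(Z)
  lim <- 1 / sqrt(d)
  W <- matrix(stats::runif(hidden * d, -lim, lim), nrow = hidden)
  bE <- numeric(hidden); bD <- numeric(d)
  vW <- W * 0; vbE <- bE; vbD <- bD
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Xb <- Z[idx, , drop = FALSE]
      B <- nrow(Xb)
      H <- tanh(Xb %*% t(W) + rep(1, B) %o% bE)
      R <- H %*% W + rep(1, B) %o% bD
      E <- R - Xb
      ep_loss <- ep_loss + mean(E^2); n_batches <- n_batches + 1L
      dR <- 2 * E / (B * d)
      gW <- crossprod(H, dR)                     # decoder part, hidden x d
      dH <- dR %*% t(W)
      dA <- dH * (1 - H^2)
      gW <- gW + crossprod(dA, Xb)               # + encoder part
      gbE <- colSums(dA); gbD <- colSums(dR)
      vW <- momentum * vW - lr * gW
      vbE <- momentum * vbE - lr * gbE
      vbD <- momentum * vbD - lr * gbD
      W <- W + vW; bE <- bE + vbE; bD <- bD + vbD
    }
    losses[ep] <- ep_loss / n_batches
  }
  list(W = W, b = bE, losses = losses)
}

#' Initialize the network by PCA and layer-wise autoencoder pretraining
#'
#' Fits (or reuses) the PCA first layer, then trains one tied-weight
#' autoencoder per hidden layer on the previous layer's outputs (squared
#' reconstruction error, mini-batch gradient descent at the pretraining
#' learning rate); the decoder halves are discarded.  The output layer is
#' initialized small-random.
#'
#' @param patches a `patch_set` (or patch matrix) of at least
#'   `n_components + 1` patches.
#' @param config a [training_config()].
#' @param pca optional precomputed [fit_pca_layer()] result.
#' @return a `dnn_parameters` object (initialized, not yet fine-tuned);
#'   `$history$pretrain` holds each layer's reconstruction-loss curve.
#' @export
pretrain <- function(patches, config = training_config(), pca = NULL) {
  X <- patch_matrix(patches)
  if (nrow(X) == 0) stop("pretrain: empty patch set")
  if (is.null(pca)) pca <- fit_pca_layer(X, config$n_components)
  Z <- pca_project(X, pca$W1, pca$b1)

  with_seed(config$seed, {
    ae2 <- train_autoencoder(Z, config$h2_size, config$pretrain_learning_rate,
                             config$pretrain_epochs, config$batch_size,
                             config$momentum)
    A2 <- tanh(Z %*% t(ae2$W) + rep(1, nrow(Z)) %o% ae2$b)
    ae3 <- train_autoencoder(A2, config$h3_size, config$pretrain_learning_rate,
                             config$pretrain_epochs, config$batch_size,
                             config$momentum)
    W4 <- matrix(stats::runif(config$h3_size, -0.01, 0.01), nrow = 1)
    new_dnn_parameters(pca$W1, pca$b1, ae2$W, ae2$b, ae3$W, ae3$b, W4, 0,
                       config,
                       history = list(pretrain = list(h2 = ae2$losses,
                                                      h3 = ae3$losses)))
  })
}

#' Fine-tune the network by backpropagation
#'
#' Minimizes the mean squared error between predicted and ground-truth
#' slopes by mini-batch gradient descent with momentum on layers 2-4; the
#' PCA layer (`W1`, `b1`) stays frozen.  Labels are standardized internally
#' (the scale is folded back into `W4`, `b4` afterwards, so the returned
#' network still predicts degrees).
#'
#' @param params initialized `dnn_parameters` (from [pretrain()]).
#' @param patches labeled `patch_set`, or patch matrix with a `labels`
#'   attribute.
#' @param config a [training_config()].
#' @param unfreeze_pca if `TRUE`, also update `W1`/`b1` by backpropagation
#'   (off by default; the PCA layer is treated as a fixed low-pass filter).
#' @return trained `dnn_parameters`; `$history$finetune` holds the per-epoch
#'   training MSE in squared degrees.
#' @export
finetune <- function(params, patches, config = training_config(),
                     unfreeze_pca = FALSE) {
  validate_dnn_shapes(params)
  X <- patch_matrix(patches)
  y <- patch_labels(patches)
  if (is.null(y) || anyNA(y)) {
    bad <- if (is.null(y)) "all" else paste(which(is.na(y)), collapse = ", ")
    stop("finetune: unlabeled patches encountered (indices: ", bad, ")")
  }
  if (length(y) != nrow(X)) stop("finetune: ", length(y), " labels for ",
                                 nrow(X), " patches")
  n <- nrow(X)
  if (unfreeze_pca) {
    # gradient path through the first layer needs the raw patches each step;
    # supported for experimentation at small scales
    return(finetune_unfrozen(params, X, y, config))
  }
  Z <- pca_project(X, params$W1, params$b1)

  m <- mean(y); s <- stats::sd(y); if (!is.finite(s) || s < 1e-8) s <- 1
  ys <- (y - m) / s
  W2 <- params$W2; b2 <- params$b2
  W3 <- params$W3; b3 <- params$b3
  W4 <- params$W4 / s; b4 <- (params$b4 - m) / s
  vW2 <- W2 * 0; vb2 <- b2 * 0; vW3 <- W3 * 0; vb3 <- b3 * 0
  vW4 <- W4 * 0; vb4 <- 0
  lr <- config$finetune_learning_rate; mom <- config$momentum
  losses <- numeric(config$finetune_epochs)

  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$finetune_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_batches <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        Zb <- Z[idx, , drop = FALSE]
        yb <- ys[idx]
        B <- nrow(Zb)
        ones <- rep(1, B)
        A2 <- tanh(Zb %*% t(W2) + ones %o% b2)
        A3 <- tanh(A2 %*% t(W3) + ones %o% b3)
        out <- as.vector(A3 %*% t(W4) + b4)
        err <- out - yb
        ep_loss <- ep_loss + mean(err^2); n_batches <- n_batches + 1L
        dout <- matrix(2 * err / B, ncol = 1)
        gW4 <- crossprod(dout, A3); gb4 <- sum(dout)
        dA3 <- dout %*% W4
        dZ3 <- dA3 * (1 - A3^2)
        gW3 <- crossprod(dZ3, A2); gb3 <- colSums(dZ3)
        dA2 <- dZ3 %*% W3
        dZ2 <- dA2 * (1 - A2^2)
        gW2 <- crossprod(dZ2, Zb); gb2 <- colSums(dZ2)
        vW4 <- mom * vW4 - lr * gW4; W4 <- W4 + vW4
        vb4 <- mom * vb4 - lr * gb4; b4 <- b4 + vb4
        vW3 <- mom * vW3 - lr * gW3; W3 <- W3 + vW3
        vb3 <- mom * vb3 - lr * gb3; b3 <- b3 + vb3
        vW2 <- mom * vW2 - lr * gW2; W2 <- W2 + vW2
        vb2 <- mom * vb2 - lr * gb2; b2 <- b2 + vb2
      }
      losses[ep] <- ep_loss / n_batches * s^2  # report in squared degrees
    }
  })

  out <- new_dnn_parameters(params$W1, params$b1, W2, b2, W3, b3,
                            W4 * s, b4 * s + m, config,
                            history = c(params$history,
                                        list(finetune = losses)))
  out
}

# full-backprop variant that also updates the PCA layer
finetune_unfrozen <- function(params, X, y, config) {
  m <- mean(y); s <- stats::sd(y); if (!is.finite(s) || s < 1e-8) s <- 1
  ys <- (y - m) / s
  W1 <- params$W1; b1 <- params$b1
  W2 <- params$W2; b2 <- params$b2
  W3 <- params$W3; b3 <- params$b3
  W4 <- params$W4 / s; b4 <- (params$b4 - m) / s
  lr <- config$finetune_learning_rate; mom <- config$momentum
  vW1 <- W1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
  vW3 <- W3 * 0; vb3 <- b3 * 0; vW4 <- W4 * 0; vb4 <- 0
  n <- nrow(X)
  losses <- numeric(config$finetune_epochs)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$finetune_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_batches <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- ys[idx]
        B <- nrow(Xb); ones <- rep(1, B)
        Zb <- Xb %*% t(W1) - ones %o% as.vector(W1 %*% b1)
        A2 <- tanh(Zb %*% t(W2) + ones %o% b2)
        A3 <- tanh(A2 %*% t(W3) + ones %o% b3)
        out <- as.vector(A3 %*% t(W4) + b4)
        err <- out - yb
        ep_loss <- ep_loss + mean(err^2); n_batches <- n_batches + 1L
        dout <- matrix(2 * err / B, ncol = 1)
        gW4 <- crossprod(dout, A3); gb4 <- sum(dout)
        dZ3 <- (dout %*% W4) * (1 - A3^2)
        gW3 <- crossprod(dZ3, A2); gb3 <- colSums(dZ3)
        dZ2 <- (dZ3 %*% W3) * (1 - A2^2)
        gW2 <- crossprod(dZ2, Zb); gb2 <- colSums(dZ2)
        dZ1 <- dZ2 %*% W2
        gW1 <- crossprod(dZ1, sweep(Xb, 2, b1))
        vW4 <- mom * vW4 - lr * gW4; W4 <- W4 + vW4
        vb4 <- mom * vb4 - lr * gb4; b4 <- b4 + vb4
        vW3 <- mom * vW3 - lr * gW3; W3 <- W3 + vW3
        vb3 <- mom * vb3 - lr * gb3; b3 <- b3 + vb3
        vW2 <- mom * vW2 - lr * gW2; W2 <- W2 + vW2
        vb2 <- mom * vb2 - lr * gb2; b2 <- b2 + vb2
        vW1 <- mom * vW1 - lr * gW1; W1 <- W1 + vW1
      }
      losses[ep] <- ep_loss / n_batches * s^2
    }
  })
  new_dnn_parameters(W1, b1, W2, b2, W3, b3, W4 * s, b4 * s + m, config,
                     history = c(params$history, list(finetune = losses)))
}

#' Train the slope network end to end
#'
#' Convenience wrapper: [fit_pca_layer()] then [pretrain()] then
#' [finetune()] on the same labeled patches.
#'
#' @inheritParams finetune
#' @return trained `dnn_parameters`.
#' @export
train_slope_dnn <- function(patches, config = training_config()) {
  params <- pretrain(patches, config)
  finetune(params, patches, config)
}

#' Predict the slope of the vertebra at a clicked point
#'
#' Extracts the 150x150 patch at the click, downsamples it to the
#' 2500-element feature vector, and evaluates the network.
#'
#' @param params trained `dnn_parameters`.
#' @param image standardized grayscale matrix (1000 rows).
#' @param click numeric (x, y), 1-based.
#' @return predicted slope in degrees.
#' @export
predict_slope <- function(params, image, click) {
  forward_dnn(params, patch_vector_at(image, click))
}

#' Mean absolute slope error of a network on labeled patches
#'
#' @param params trained `dnn_parameters`.
#' @param patches labeled `patch_set`.
#' @return mean absolute error in degrees.
#' @export
evaluate_slope_mae <- function(params, patches) {
  y <- patch_labels(patches)
  if (is.null(y)) stop("evaluate_slope_mae: patches carry no labels")
  mean(abs(forward_dnn(params, patches) - y))
}
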