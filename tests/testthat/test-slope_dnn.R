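# The slope regression network: PCA layer, forward pass, autoencoder
# pretraining, and backpropagation fine-tuning.

test_that("the PCA layer is orthonormal, centred, and variance-ordered", {
  ps <- fixture_patchset()
  pca <- fit_pca_layer(ps, n_components = 60)
  G <- pca$W1 %*% t(pca$W1)
  expect_equal(G, diag(60), tolerance = 1e-6)
  # the mean patch projects to the origin
  z0 <- cobbnet:::pca_project(matrix(pca$b1, nrow = 1), pca$W1, pca$b1)
  expect_equal(as.vector(z0), rep(0, 60), tolerance = 1e-8)
  expect_true(all(diff(pca$eigenvalues) <= 1e-10))
})

test_that("the PCA layer spans the same subspace as a dense eigendecomposition oracle", {
  rgs <- lapply(1:3, function(s) {
    render_radiograph(generate_spine_spec(seed = 150 + s), noise_level = 0,
                      seed = 1)
  })
  ps <- sample_training_patches(rgs, 10, 12, seed = 2)
  k <- 40
  pca <- fit_pca_layer(ps, n_components = k)
  # oracle: explicitly centred matrix, explicitly formed covariance
  X <- ps$vectors
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / (nrow(X) - 1)
  V <- eigen(C, symmetric = TRUE)$vectors[, 1:k]
  sv <- svd(pca$W1 %*% V)$d
  principal_angles <- acos(pmin(1, sv))
  expect_lt(max(principal_angles), 1e-4)
})

test_that("fit_pca_layer rejects rank-deficient patch sets", {
  X <- matrix(runif(50 * 2500), nrow = 50)
  expect_error(fit_pca_layer(X, n_components = 100), "at least 101")
})

test_that("the forward pass reproduces a hand-evaluated toy composition", {
  p <- toy_params()
  patch <- c(2, 5, 1, -1)
  # by hand: z = W1 (P - b1); a2 = tanh(b2 + W2 z); a3 = tanh(b3 + W3 a2)
  z <- c((2 - 1) + 0 + 0 + 0, 0 + (5 - 2) + 0 + 0)      # (1, 3)
  a2 <- tanh(c(0.5 + 1 * 1 - 1 * 3, -0.5 + 2 * 1 + 0 * 3))
  a3 <- tanh(c(0 + a2[1] + a2[2], 1 - a2[1] + 2 * a2[2]))
  expected <- 0.25 + 3 * a3[1] - 2 * a3[2]
  expect_equal(forward_dnn(p, patch), expected, tolerance = 1e-12)
})

test_that("a zero-weight network is constant and tanh bounds the output", {
  p <- toy_params()
  p$W2[] <- 0; p$W3[] <- 0; p$W4[] <- 0; p$b4 <- 7
  for (patch in list(c(0, 0, 0, 0), c(100, -3, 2, 9))) {
    expect_equal(forward_dnn(p, patch), 7)
  }
  set.seed(41)
  q <- toy_params()
  for (i in 1:20) {
    patch <- runif(4, -50, 50)
    expect_lte(abs(forward_dnn(q, patch) - q$b4), sum(abs(q$W4)) + 1e-12)
  }
})

test_that("the forward pass rejects shape mismatches naming the layer", {
  p <- toy_params()
  expect_error(forward_dnn(p, c(1, 2, 3)), "layer 1")
  bad <- p; bad$W3 <- matrix(1, 2, 3)
  expect_error(forward_dnn(bad, c(1, 2, 3, 4)), "layer 3")
})

test_that("autoencoder pretraining reduces reconstruction loss and is deterministic", {
  ps <- fixture_patchset()
  cfg <- training_config(h2_size = 80, h3_size = 12, pretrain_epochs = 8,
                         n_components = 60, seed = 3)
  expect_equal(cfg$pretrain_learning_rate, 0.1)
  params <- pretrain(ps, cfg)
  h <- params$history$pretrain
  expect_lt(tail(h$h2, 1), h$h2[1])
  expect_lt(tail(h$h3, 1), h$h3[1])
  params2 <- pretrain(ps, cfg)
  expect_identical(params$W2, params2$W2)
  expect_identical(params$W4, params2$W4)
})

test_that("an over-parameterized network memorizes a tiny training set", {
  ps <- fixture_patchset()
  idx <- seq(1, n_patches(ps), length.out = 20)
  tiny <- ps
  tiny$vectors <- ps$vectors[idx, ]
  tiny$meta <- ps$meta[idx, ]
  cfg <- training_config(n_components = 60, pretrain_epochs = 10,
                         finetune_epochs = 2000, batch_size = 20, seed = 4)
  pca <- fit_pca_layer(ps, 60)  # PCA basis from the wider pool
  params <- pretrain(tiny, cfg, pca = pca)
  params <- finetune(params, tiny, cfg)
  mse <- mean((forward_dnn(params, tiny$vectors) - tiny$meta$label)^2)
  expect_lt(mse, 0.1)
})

test_that("the smoothed fine-tuning loss curve is nonincreasing", {
  m <- fixture_model()
  loss <- m$history$finetune
  sm <- stats::filter(loss, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 0.05 * sm[-length(sm)]))
})

test_that("labels linear in the first principal coordinate are recovered", {
  # the target function lies inside the model class; held-out MAE < 0.5 deg
  set.seed(17)
  X <- matrix(runif(3500 * 2500), nrow = 3500)
  pca <- fit_pca_layer(X[1:500, ], n_components = 20)
  z1 <- cobbnet:::pca_project(X, pca$W1, pca$b1)[, 1]
  y <- 30 * z1 + 5
  tr <- X[1:3000, ]; attr(tr, "labels") <- y[1:3000]
  cfg <- training_config(h2_size = 40, h3_size = 10, n_components = 20,
                         pretrain_epochs = 5, finetune_epochs = 200,
                         finetune_learning_rate = 0.05, seed = 6)
  params <- pretrain(tr, cfg, pca = pca)
  params <- finetune(params, tr, cfg)
  mae <- mean(abs(forward_dnn(params, X[3001:3500, ]) - y[3001:3500]))
  expect_lt(mae, 0.5)
})

test_that("finetune rejects unlabeled patches", {
  ps <- fixture_patchset()
  cfg <- training_config(n_components = 60, pretrain_epochs = 2,
                         finetune_epochs = 2, seed = 1)
  params <- pretrain(ps, cfg)
  bad <- ps
  bad$meta$label[3] <- NA
  expect_error(finetune(params, bad, cfg), "unlabeled")
})

test_that("predict_slope is exactly the extract-downsample-forward composition", {
  m <- fixture_model()
  rg <- fixture_clean_radiograph()
  v <- rg$truth$vertebrae
  click <- c(v$center_x[5], v$center_y[5])
  direct <- forward_dnn(m, downsample_patch(extract_patch(rg$image, click)))
  expect_identical(predict_slope(m, rg$image, click), direct)
})

test_that("trained predictions are locally stable under 1-px click shifts", {
  m <- fixture_model()
  rg <- fixture_clean_radiograph()
  v <- rg$truth$vertebrae
  for (i in c(2, 8, 15)) {
    click <- c(round(v$center_x[i]), round(v$center_y[i]))
    p0 <- predict_slope(m, rg$image, click)
    p1 <- predict_slope(m, rg$image, click + c(1, 0))
    p2 <- predict_slope(m, rg$image, click + c(0, 1))
    expect_lt(max(abs(c(p1, p2) - p0)), 1)
  }
})

test_that("the trained network generalizes to held-out phantoms", {
  m <- fixture_model()
  rgs <- fixture_radiographs(5, seed0 = 900)
  te <- sample_training_patches(rgs, 1, 0, seed = 2)
  expect_lt(evaluate_slope_mae(m, te), 2.0)
})
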