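test_that("autoencoder forward passes follow the sigmoid closed forms", {
  ly <- ae_layer(matrix(0, 10, 4), numeric(4), numeric(10))
  expect_equal(ae_encode(ly, runif(10)), rep(0.5, 4))
  expect_equal(ae_reconstruct(ly, runif(10)), rep(0.5, 10))
  ly2 <- ae_layer(matrix(0, 10, 4), rep(100, 4), numeric(10))
  expect_true(all(ae_encode(ly2, runif(10)) > 0.999))
  ly3 <- ae_layer(matrix(1, 1, 1), 0, 0)
  expect_equal(ae_encode(ly3, 0), 0.5)
  expect_error(ae_encode(ly, runif(7)), "features")
})

test_that("the analytic reconstruction gradient matches finite differences", {
  set.seed(2)
  X <- matrix(runif(60), 6, 10)
  ly <- saetm:::.init_ae(10, 3, 5)
  g <- saetm:::.ae_loss_grad(ly, X)
  eps <- 1e-6
  loss_at <- function(l) sum((ae_reconstruct(l, X) - X)^2)
  for (probe in list(c(1, 1), c(5, 2), c(10, 3))) {
    lp <- ly; lp$W[probe[1], probe[2]] <- lp$W[probe[1], probe[2]] + eps
    lm <- ly; lm$W[probe[1], probe[2]] <- lm$W[probe[1], probe[2]] - eps
    num <- (loss_at(lp) - loss_at(lm)) / (2 * eps)
    expect_equal(g$dW[probe[1], probe[2]], num, tolerance = 1e-5)
  }
  lpb <- ly; lpb$b[2] <- lpb$b[2] + eps
  lmb <- ly; lmb$b[2] <- lmb$b[2] - eps
  expect_equal(g$db[2], (loss_at(lpb) - loss_at(lmb)) / (2 * eps),
               tolerance = 1e-5)
})

test_that("training reconstructs representable data and is deterministic", {
  set.seed(4)
  Xc <- matrix(rep(runif(10, 0.2, 0.8), each = 40), 40, 10)
  ly <- train_ae(Xc, 1, epochs = 500, lr = 0.8, batch = 32, seed = 3)
  expect_lt(mean(rowMeans((ae_reconstruct(ly, Xc) - Xc)^2)), 1e-3)

  X <- matrix(runif(320), 32, 10)
  a <- train_ae(X, 4, epochs = 20, seed = 9)
  b <- train_ae(X, 4, epochs = 20, seed = 9)
  expect_identical(a$W, b$W)
  expect_identical(a$b, b$b)
  expect_identical(a$c, b$c)
  expect_false(identical(a$W, train_ae(X, 4, epochs = 20, seed = 10)$W))
})

test_that("trained layers beat random initialization on held-out rows", {
  set.seed(6)
  Z <- matrix(runif(200 * 2), 200, 2)
  X <- plogis(scale(Z %*% matrix(rnorm(20), 2, 10)))
  tr <- X[1:150, ]; te <- X[151:200, ]
  trained <- train_ae(tr, 3, epochs = 100, seed = 1)
  random <- saetm:::.init_ae(10, 3, 1)
  expect_lt(sum((ae_reconstruct(trained, te) - te)^2),
            sum((ae_reconstruct(random, te) - te)^2))
})

test_that("the training loss settles and never explodes", {
  set.seed(8)
  X <- matrix(runif(640), 64, 10)
  ly <- train_ae(X, 5, epochs = 60, lr = 0.5, batch = 32, seed = 2)
  lc <- attr(ly, "loss_curve")
  expect_true(all(is.finite(lc)))
  expect_lt(lc[60], lc[1])
  ## after the initial descent the curve is non-increasing up to jitter
  expect_true(all(diff(lc[5:60]) <= 1e-6 + 0.01 * lc[5]))
})

test_that("the structural loss matches its closed forms", {
  set.seed(10)
  Dx <- matrix(runif(40), 8, 5)
  expect_equal(slf(Dx, Dx), 0)
  expect_equal(slf(Dx, -Dx), 4)
  ## a monotone transform preserves ranks: only the Pearson term remains
  Dz <- Dx^3
  rho1 <- sum((Dx - mean(Dx)) * (Dz - mean(Dz))) /
    sqrt(sum((Dx - mean(Dx))^2) * sum((Dz - mean(Dz))^2))
  expect_equal(slf(Dx, Dz), 0.5 * (1 - rho1)^2)
  expect_error(slf(Dx, matrix(1, 8, 5)), "zero variance")
  v <- slf(Dx, matrix(runif(40), 8, 5))
  expect_gte(v, 0); expect_lte(v, 4)
})

test_that("width selection honours contracts and recovers a planted rank", {
  set.seed(12)
  X <- matrix(runif(300), 30, 10)
  only <- select_width(X, 10, saetm_config(epochs = 5, seed = 1))
  expect_identical(only$best_width, 10L)
  sel <- select_width(X, c(2, 5, 8), saetm_config(epochs = 5, seed = 1))
  expect_length(sel$slf_curve, 3)

  ## sigmoid(rank-3 linear map) + small noise: the chosen width sits at
  ## the SLF knee near 3
  set.seed(14)
  Z <- matrix(runif(400 * 3), 400, 3)
  A <- matrix(rnorm(30, sd = 1.5), 3, 10)
  Xr <- plogis(scale(Z %*% A) + rnorm(4000, sd = 0.01))
  got <- select_width(Xr, 1:10, saetm_config(epochs = 150, seed = 5))$best_width
  expect_true(got %in% 2:4)
})

test_that("channel stacks shrink monotonically and reject degenerate input", {
  set.seed(16)
  Z <- matrix(runif(300 * 2), 300, 2)
  X <- plogis(scale(Z %*% matrix(rnorm(20), 2, 10)) + rnorm(3000, sd = 0.05))
  cs <- build_channel_sae(X, saetm_config(epochs = 40, seed = 3),
                          channel = "F3")
  expect_length(cs$layers, 3)
  expect_true(all(diff(cs$widths) <= 0))
  expect_true(all(cs$widths >= 1))
  ## hidden activations stay in (0, 1)
  h <- ae_encode(cs$layers[[1]], X)
  expect_true(all(h > 0 & h < 1))
  expect_error(build_channel_sae(matrix(0.5, 50, 10),
                                 saetm_config(epochs = 2, seed = 1)),
               "zero variance")
})

test_that("fine-tuning is deterministic and rejects single-class labels", {
  tens <- make_tiny_tensors(n_per_class = 3, seed = 20)
  cfg <- saetm_config(epochs = 5, seed = 2, max_rows = 200)
  pre <- pretrain_saetm(tens, cfg)
  m1 <- train_saetm(tens, "valence", cfg, finetune_epochs = 4,
                    pretrained = pre)
  m2 <- train_saetm(tens, "valence", cfg, finetune_epochs = 4,
                    pretrained = pre)
  expect_identical(m1$out_beta, m2$out_beta)
  expect_identical(m1$channel_saes[[1]]$layers[[1]]$W,
                   m2$channel_saes[[1]]$layers[[1]]$W)
  high_only <- Filter(function(tt) tt$label$valence_bin == "high", tens)
  model <- saetm_model(pre, "valence")
  expect_error(finetune(model, high_only, epochs = 1), "both label classes")
})

test_that("map values are head means, order-invariant and centred at 0.5 for null heads", {
  tens <- make_tiny_tensors(n_per_class = 2, seed = 24)
  cfg <- saetm_config(epochs = 4, seed = 3, max_rows = 200)
  pre <- pretrain_saetm(tens, cfg)
  model <- saetm_model(pre, "valence")
  ## zero heads -> sigmoid(0) = 0.5 everywhere
  for (ch in 1:32) {
    model$channel_saes[[ch]]$head_mu[] <- 0
    model$channel_saes[[ch]]$head_bias <- 0
  }
  v <- channel_map_values(model, tens[[1]])
  expect_equal(unname(v), rep(0.5, 32))
  ## permuting windows leaves the mean unchanged
  model2 <- train_saetm(tens, "valence", cfg, finetune_epochs = 3,
                        pretrained = pre)
  tt <- tens[[1]]
  perm <- tt
  set.seed(1)
  perm$tensor <- perm$tensor[sample(dim(perm$tensor)[1]), , , drop = FALSE]
  expect_equal(channel_map_values(model2, tt), channel_map_values(model2, perm))
  expect_named(v, canonical_channels())
})

test_that("models round-trip exactly through serialization", {
  tens <- make_tiny_tensors(n_per_class = 2, seed = 28)
  cfg <- saetm_config(epochs = 3, seed = 4, max_rows = 150)
  model <- train_saetm(tens, "arousal", cfg, finetune_epochs = 2)
  dir <- file.path(tempdir(), "saetm_model")
  save_saetm(model, dir)
  back <- load_saetm(dir)
  expect_identical(back$dimension, model$dimension)
  expect_identical(back$out_beta, model$out_beta)
  expect_identical(back$out_alpha, model$out_alpha)
  for (ch in c(1, 17, 32)) {
    expect_identical(back$channel_saes[[ch]]$layers[[2]]$W,
                     model$channel_saes[[ch]]$layers[[2]]$W)
    expect_identical(back$channel_saes[[ch]]$head_mu,
                     model$channel_saes[[ch]]$head_mu)
  }
  expect_equal(channel_map_values(back, tens[[1]]),
               channel_map_values(model, tens[[1]]))
})
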