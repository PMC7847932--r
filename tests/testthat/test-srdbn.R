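test_that("stack construction chains layer shapes and is seeded", {
  m <- build_dbn(20, 10, seed = 2)
  expect_equal(m$layer_sizes, c(20, 10, 10, 10))
  expect_equal(dim(m$layers[[1]]$W), c(20L, 10L))
  expect_equal(dim(m$layers[[2]]$W), c(10L, 10L))
  expect_equal(dim(m$layers[[3]]$W), c(10L, 10L))
  expect_identical(build_dbn(20, 10, seed = 2), m)
  m1 <- build_dbn(6, 4, n_hidden_layers = 1, seed = 1)
  expect_length(m1$layers, 1)
  expect_error(build_dbn(0, 4), class = "srdbnelm_validation_error")
})

test_that("a one-layer stack pretrains exactly like a lone RBM", {
  X <- prototype_data(10)
  cfg <- sr_train_config(epochs = 20, batch_size = 8, seed = 6)
  m <- build_dbn(8, 4, n_hidden_layers = 1, weight_init_sd = cfg$weight_init_sd,
                 seed = 3)
  m <- pretrain(m, X, cfg)
  lone_cfg <- cfg
  lone_cfg$seed <- srdbnelm:::derive_seed(cfg$seed, "pretrain_layer1")
  lone <- train_srrbm(X, lone_cfg, params = build_dbn(
    8, 4, n_hidden_layers = 1, weight_init_sd = cfg$weight_init_sd,
    seed = 3)$layers[[1]])
  expect_identical(m$layers[[1]], lone$params)
})

test_that("greedy pretraining propagates exact hidden probabilities upward", {
  ## two-block structured data so each layer has redundancy to model
  set.seed(20)
  X <- matrix(runif(300), 30, 10)
  X[1:15, 1:5] <- X[1:15, 1:5] * 0.2
  X[16:30, 6:10] <- X[16:30, 6:10] * 0.2
  cfg <- sr_train_config(epochs = 30, batch_size = 10, seed = 4)
  m <- build_dbn(10, 6, n_hidden_layers = 2, seed = 9)
  m0 <- m
  mt <- pretrain(m, X, cfg)
  ## every layer's reconstruction error fell over its epochs
  for (t in 1:2)
    expect_lt(mt$traces[[t]]$recon_error[30], mt$traces[[t]]$recon_error[1])
  ## retraining layer 2 separately on layer 1's deterministic output
  ## reproduces the stacked result bit-exactly
  H1 <- hidden_probs(mt$layers[[1]], X)
  cfg2 <- cfg
  cfg2$seed <- srdbnelm:::derive_seed(cfg$seed, "pretrain_layer2")
  lone2 <- train_srrbm(H1, cfg2, params = m0$layers[[2]])
  expect_identical(mt$layers[[2]], lone2$params)
})

test_that("feature extraction is a pure deterministic forward pass", {
  m <- build_dbn(5, 3, seed = 1)
  for (t in 1:3) m$layers[[t]]$W[] <- 0
  m$pretrained <- TRUE
  X <- matrix(runif(20), 4, 5)
  Fx <- extract_features(m, X)
  expect_equal(Fx, matrix(0.5, 4, 3))
  m2 <- pretrain(build_dbn(5, 3, seed = 1),
                 matrix(runif(40), 8, 5), sr_train_config(epochs = 5, seed = 2))
  F1 <- extract_features(m2, X)
  expect_equal(dim(F1), c(4L, 3L))
  expect_true(all(F1 > 0 & F1 < 1))
  expect_identical(F1, extract_features(m2, X))
  expect_identical(F1[c(1, 1), ], extract_features(m2, X[c(1, 1), ]))
  expect_error(extract_features(m2, X[, 1:3]),
               class = "srdbnelm_validation_error")
})

test_that("fine-tuning requires pretraining, keeps shapes, and lr 0 is a no-op", {
  X <- prototype_data(10)
  labels <- rep(0:1, each = 10)
  expect_error(finetune(build_dbn(8, 4, seed = 1), X, labels),
               class = "srdbnelm_state_error")
  m <- pretrain(build_dbn(8, 4, seed = 1), X,
                sr_train_config(epochs = 10, seed = 3))
  m0 <- finetune(m, X, labels, lr = 0, epochs = 5, seed = 2)
  for (t in seq_along(m$layers))
    expect_identical(m0$layers[[t]]$W, m$layers[[t]]$W)
  mf <- finetune(m, X, labels, lr = 0.5, epochs = 40, seed = 2)
  expect_equal(mf$layer_sizes, m$layer_sizes)
  expect_lt(mf$finetune_loss[40], mf$finetune_loss[1])
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(31)
  X <- matrix(runif(5 * 4), 5, 4)
  Y <- matrix(0, 5, 2); Y[cbind(1:5, c(1, 2, 1, 2, 1))] <- 1
  m <- pretrain(build_dbn(4, 3, n_hidden_layers = 2, seed = 7), X,
                sr_train_config(epochs = 5, seed = 5))
  set.seed(8)
  head <- list(W = matrix(rnorm(6, sd = 0.5), 3, 2), b = rnorm(2, sd = 0.1))
  fg <- srdbnelm:::dbn_loss_grad(m, head, X, Y)
  h <- 1e-5
  loss_at <- function(model, hd) srdbnelm:::dbn_loss_grad(model, hd, X, Y)$loss
  ## spot-check every parameter block
  for (t in 1:2) {
    for (idx in list(c(1, 1), c(2, 3), c(4, 2))) {
      if (idx[1] > nrow(m$layers[[t]]$W)) next
      mp <- m; mp$layers[[t]]$W[idx[1], idx[2]] <-
        mp$layers[[t]]$W[idx[1], idx[2]] + h
      mm <- m; mm$layers[[t]]$W[idx[1], idx[2]] <-
        mm$layers[[t]]$W[idx[1], idx[2]] - h
      fd <- (loss_at(mp, head) - loss_at(mm, head)) / (2 * h)
      expect_equal(fg$dW[[t]][idx[1], idx[2]], fd, tolerance = 1e-5)
    }
    mp <- m; mp$layers[[t]]$b_hid[1] <- mp$layers[[t]]$b_hid[1] + h
    mm <- m; mm$layers[[t]]$b_hid[1] <- mm$layers[[t]]$b_hid[1] - h
    expect_equal(fg$db[[t]][1],
                 (loss_at(mp, head) - loss_at(mm, head)) / (2 * h),
                 tolerance = 1e-5)
  }
  hp <- head; hp$W[2, 1] <- hp$W[2, 1] + h
  hm <- head; hm$W[2, 1] <- hm$W[2, 1] - h
  expect_equal(fg$dheadW[2, 1], (loss_at(m, hp) - loss_at(m, hm)) / (2 * h),
               tolerance = 1e-5)
  hp <- head; hp$b[2] <- hp$b[2] + h
  hm <- head; hm$b[2] <- hm$b[2] - h
  expect_equal(fg$dheadb[2], (loss_at(m, hp) - loss_at(m, hm)) / (2 * h),
               tolerance = 1e-5)
})

test_that("learned features beat random weights for downstream classification", {
  acc_tr <- acc_rnd <- numeric(10)
  for (seed in 1:10) {
    d <- generate_multimodal_dataset(
      synthetic_spec(n_per_class = 20, n_modalities = 1, dims = 10,
                     latent_rank = 2, separation = 1.0, seed = seed), 2)
    X <- d$modalities[[1]]
    cfg <- sr_train_config(epochs = 20, weight_init_sd = 0.05, seed = seed)
    m_tr <- finetune(pretrain(build_dbn(10, 6, weight_init_sd = 0.05,
                                        seed = seed), X, cfg),
                     X, d$labels, lr = 0.5, epochs = 150, seed = seed)
    m_rnd <- build_dbn(10, 6, weight_init_sd = 1, seed = seed + 500)
    m_rnd$pretrained <- TRUE
    acc <- function(model) {
      Fx <- extract_features(model, X)
      e <- suppressWarnings(fit_elm(init_elm(6, 8, seed = seed), Fx,
                                    d$labels))
      mean(predict(e, Fx)$codes == d$labels)
    }
    acc_tr[seed] <- acc(m_tr)
    acc_rnd[seed] <- acc(m_rnd)
  }
  expect_gt(mean(acc_tr), mean(acc_rnd))
})
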