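test_that("conditional probabilities match hand-evaluated sigmoids", {
  p <- rbm_params(matrix(0, 3, 2), numeric(3), numeric(2))
  expect_equal(hidden_probs(p, matrix(runif(6), 2, 3)),
               matrix(0.5, 2, 2))
  expect_equal(visible_probs(p, matrix(runif(4), 2, 2)),
               matrix(0.5, 2, 3))

  pb <- rbm_params(matrix(0, 3, 2), c(-1, 0, 2), c(0.3, -0.7))
  expect_equal(hidden_probs(pb, matrix(0, 1, 3)),
               matrix(sigmoid(c(0.3, -0.7)), 1), tolerance = 1e-12)
  expect_equal(visible_probs(pb, matrix(0, 1, 2)),
               matrix(sigmoid(c(-1, 0, 2)), 1), tolerance = 1e-12)

  phand <- rbm_params(matrix(c(1, -1), 2, 1), numeric(2), 0)
  expect_equal(drop(hidden_probs(phand, c(1, 0))), 1 / (1 + exp(-1)),
               tolerance = 1e-7)
  ## mirrored visible conditional of the same hand example
  expect_equal(drop(visible_probs(phand, matrix(1))),
               sigmoid(c(1, -1)), tolerance = 1e-12)

  expect_error(hidden_probs(p, matrix(0, 1, 4)),
               class = "srdbnelm_validation_error")
})

test_that("Bernoulli sampling honours degenerate and intermediate probabilities", {
  set.seed(1)
  expect_equal(sample_bernoulli(matrix(0, 5, 5)), matrix(0, 5, 5))
  expect_equal(sample_bernoulli(matrix(1, 5, 5)), matrix(1, 5, 5))
  set.seed(2)
  draws <- sample_bernoulli(matrix(0.3, 500, 200))
  expect_lt(abs(mean(draws) - 0.3), 0.01)
  expect_error(sample_bernoulli(matrix(1.2, 2, 2)),
               class = "srdbnelm_validation_error")
})

test_that("CD statistics are deterministic and match the one-step hand case", {
  p <- random_rbm(4, 3, seed = 11)
  V <- matrix(runif(40), 10, 4)
  set.seed(7); s1 <- cd_statistics(p, V, k = 3)
  set.seed(7); s2 <- cd_statistics(p, V, k = 3)
  expect_identical(s1, s2)

  ## single visible unit clamped at 1, all parameters zero, k = 1:
  ## h ~ Bern(0.5); p(v | h) = 0.5 whatever h; so pos <vh> = 0.5 and the
  ## negative visible statistic is exactly 0.5
  p0 <- rbm_params(matrix(0, 1, 1), 0, 0)
  set.seed(1)
  s <- cd_statistics(p0, matrix(1), k = 1)
  expect_equal(drop(s$pos_vh), 0.5)
  expect_equal(s$neg_v, 0.5)
  expect_error(cd_statistics(p0, matrix(1), k = 0),
               class = "srdbnelm_validation_error")
})

test_that("CD update arithmetic follows the three update rules exactly", {
  ## forced-equal statistics are a fixed point
  p <- random_rbm(3, 2, seed = 4)
  stats_eq <- list(pos_vh = matrix(1:6 / 10, 3, 2), pos_v = c(.1, .2, .3),
                   pos_h = c(.4, .5))
  stats_eq$neg_vh <- stats_eq$pos_vh
  stats_eq$neg_v <- stats_eq$pos_v
  stats_eq$neg_h <- stats_eq$pos_h
  p_new <- srdbnelm:::apply_cd_update(p, stats_eq, epsilon = 0.3)
  expect_equal(p_new, p, tolerance = 1e-15)

  ## independent scalar recomputation of each rule against cd1_update,
  ## replaying the sampler's uniform draws to fix the hidden samples
  cfg <- sr_train_config(epsilon = 0.2, cd_steps = 1, seed = 1)
  batch <- matrix(c(1, 0, 1, 0, 0, 1), 2, 3)
  set.seed(42)
  upd <- cd1_update(p, batch, cfg)
  set.seed(42)
  ph0 <- sigmoid(sweep(batch %*% p$W, 2, p$b_hid, `+`))
  h_samp <- (matrix(runif(4), 2, 2) < ph0) + 0
  v_prob <- sigmoid(sweep(h_samp %*% t(p$W), 2, p$c_vis, `+`))
  v_samp <- (matrix(runif(6), 2, 3) < v_prob) + 0
  ph1 <- sigmoid(sweep(v_samp %*% p$W, 2, p$b_hid, `+`))
  expect_equal(upd$W,
               p$W + 0.2 * (crossprod(batch, ph0) / 2 -
                              crossprod(v_samp, ph1) / 2),
               tolerance = 1e-12)
  expect_equal(upd$c_vis,
               p$c_vis + 0.2 * (colMeans(batch) - colMeans(v_prob)),
               tolerance = 1e-12)
  expect_equal(upd$b_hid,
               p$b_hid + 0.2 * (colMeans(ph0) - colMeans(ph1)),
               tolerance = 1e-12)
})

test_that("sparsity gradient matches its closed form and finite differences", {
  m <- 5
  p0 <- rbm_params(matrix(0, 3, 2), numeric(3), numeric(2))
  g <- sparsity_gradient(p0, matrix(1, m, 3))
  expect_equal(g$db, rep(-0.25 * m, 2))
  expect_equal(g$dW, matrix(-0.25 * m, 3, 2))

  ## saturated units contribute nothing
  psat <- rbm_params(matrix(0, 3, 2), numeric(3), c(30, -30))
  gsat <- sparsity_gradient(psat, matrix(runif(15), 5, 3))
  expect_lt(max(abs(gsat$db)), 1e-10)
  expect_lt(max(abs(gsat$dW)), 1e-10)

  for (seed in 1:5) {
    p <- random_rbm(4, 3, sd = 0.8, seed = seed)
    set.seed(seed + 100)
    batch <- matrix(runif(20), 5, 4)
    g <- sparsity_gradient(p, batch)
    fd <- fd_sparsity_penalty_grad(p, batch)
    expect_equal(g$dW, -fd$dW, tolerance = 1e-6)
    expect_equal(g$db, -fd$db, tolerance = 1e-6)
  }
})

test_that("training is reproducible, reduces to plain CD at lambda 0, and learns", {
  X <- prototype_data(20)
  cfg <- sr_train_config(epsilon = 0.2, lam = 0, epochs = 200,
                         batch_size = 8, seed = 3)
  tr1 <- train_srrbm(X, cfg, n_hidden = 4)
  tr2 <- train_srrbm(X, cfg, n_hidden = 4)
  expect_identical(tr1, tr2)
  expect_lt(tr1$recon_error[200], tr1$recon_error[1])

  ## the sparsity penalty changes the learned representation and lowers
  ## the final mean hidden activation on the same data and seed
  cfg_l <- cfg; cfg_l$lam <- 0.5
  tr_l <- train_srrbm(X, cfg_l, n_hidden = 4)
  expect_false(identical(tr1$params$b_hid, tr_l$params$b_hid))
  expect_lt(tr_l$mean_activation[200], tr1$mean_activation[200])
  expect_error(train_srrbm(X * 2, cfg, n_hidden = 4),
               class = "srdbnelm_validation_error")
})

test_that("sparsity weight monotonically suppresses hidden activation", {
  set.seed(10)
  X <- pmin(pmax(matrix(rbeta(30 * 20, 2, 2), 30, 20), 0), 1)
  finals <- vapply(c(0, 0.1, 0.5), function(lam) {
    cfg <- sr_train_config(epsilon = 0.1, lam = lam, epochs = 30,
                           batch_size = 10, seed = 5)
    tr <- train_srrbm(X, cfg, n_hidden = 8)
    tr$mean_activation[length(tr$mean_activation)]
  }, 0)
  expect_true(all(diff(finals) <= 0))
})

test_that("exact enumeration agrees with an independent joint-space oracle", {
  p0 <- rbm_params(matrix(0, 1, 1), 0, 0)
  ex0 <- exact_model_statistics(p0)
  expect_equal(drop(ex0$vh), 0.25)
  expect_equal(ex0$v, 0.5)
  expect_equal(ex0$h, 0.5)
  expect_equal(ex0$log_z, 2 * log(2))
  expect_equal(exact_model_statistics(
    rbm_params(matrix(0, 3, 2), numeric(3), numeric(2)))$log_z, 5 * log(2))

  p <- random_rbm(3, 2, sd = 0.8, seed = 21)
  ex <- exact_model_statistics(p)
  or <- enum_joint_statistics(p$W, p$c_vis, p$b_hid)
  expect_equal(unname(ex$vh), unname(or$vh), tolerance = 1e-12)
  expect_equal(ex$v, unname(or$v), tolerance = 1e-12)
  expect_equal(ex$h, unname(or$h), tolerance = 1e-12)
  expect_equal(ex$log_z, or$log_z, tolerance = 1e-12)
  expect_error(exact_model_statistics(init_rbm(15, 10)),
               class = "srdbnelm_validation_error")
})

test_that("conditionals are consistent with the enumerated joint distribution", {
  p <- random_rbm(3, 2, sd = 1, seed = 33)
  states <- as.matrix(expand.grid(rep(list(c(0, 1)), 5)))
  V <- states[, 1:3, drop = FALSE]
  H <- states[, 4:5, drop = FALSE]
  w <- exp(rowSums((V %*% p$W) * H) + drop(V %*% p$c_vis) +
             drop(H %*% p$b_hid))
  joint <- w / sum(w)
  for (vi in 1:4) {                     # a few visible configurations
    v <- as.numeric(c(vi %% 2, vi %/% 2 %% 2, vi %/% 4 %% 2))
    rows <- apply(V, 1, function(r) all(r == v))
    cond <- vapply(1:2, function(j)
      sum(joint[rows & H[, j] == 1]) / sum(joint[rows]), 0)
    expect_equal(drop(hidden_probs(p, v)), cond, tolerance = 1e-10)
  }
})

test_that("negative-phase statistics converge to equilibrium as k grows", {
  p <- random_rbm(4, 3, sd = 0.5, seed = 99)
  ex <- exact_model_statistics(p)
  set.seed(5)
  V <- matrix(runif(5000 * 4), 5000, 4)
  errs <- vapply(c(1, 5, 50), function(k) {
    set.seed(17)
    max(abs(cd_statistics(p, V, k)$neg_vh - ex$vh))
  }, 0)
  expect_true(errs[3] <= errs[1] + 0.005)
  expect_lt(errs[3], 0.02)
})
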