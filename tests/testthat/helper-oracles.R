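## Independent oracles used across the suite. Each is a deliberately naive
## implementation of the quantity it checks, kept separate from the package's
## own computation path.

## Linear separator oracle: ridge-stabilised least squares on +/-1 targets
## (stable when features outnumber samples). Returns held-out accuracy; used
## as the "any linear separator" oracle for the synthetic generator.
linear_oracle_accuracy <- function(X_train, y_train, X_test, y_test,
                                   lambda = 1) {
  X1 <- cbind(1, X_train)
  beta <- solve(crossprod(X1) + lambda * diag(ncol(X1)),
                crossprod(X1, ifelse(y_train == 0, -1, 1)))
  pred <- as.integer(cbind(1, X_test) %*% beta > 0)
  mean(pred == y_test)
}

## Exhaustive enumeration of RBM moments over the full joint (v, h) state
## space -- a second, independent implementation against
## exact_model_statistics(), which sums the hidden layer out analytically.
enum_joint_statistics <- function(W, c_vis, b_hid) {
  n_v <- nrow(W)
  n_h <- ncol(W)
  states <- as.matrix(expand.grid(rep(list(c(0, 1)), n_v + n_h)))
  V <- states[, seq_len(n_v), drop = FALSE]
  H <- states[, n_v + seq_len(n_h), drop = FALSE]
  energy <- -rowSums((V %*% W) * H) - drop(V %*% c_vis) - drop(H %*% b_hid)
  w <- exp(-energy)
  z <- sum(w)
  p <- w / z
  list(vh = crossprod(V * p, H),
       v = drop(crossprod(V, p)),
       h = drop(crossprod(H, p)),
       log_z = log(z))
}

## O(n^2) Mann-Whitney concordance with half credit for ties.
pairwise_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

## Central finite differences of the penalty sum_l ||p(h | v^(l))||_1 with
## respect to every weight and hidden bias.
fd_sparsity_penalty_grad <- function(params, batch, h = 1e-5) {
  penalty <- function(W, b_hid) {
    sum(sigmoid(sweep(batch %*% W, 2L, b_hid, `+`)))
  }
  dW <- params$W
  for (i in seq_len(nrow(params$W))) {
    for (j in seq_len(ncol(params$W))) {
      Wp <- params$W; Wp[i, j] <- Wp[i, j] + h
      Wm <- params$W; Wm[i, j] <- Wm[i, j] - h
      dW[i, j] <- (penalty(Wp, params$b_hid) -
                     penalty(Wm, params$b_hid)) / (2 * h)
    }
  }
  db <- numeric(length(params$b_hid))
  for (j in seq_along(params$b_hid)) {
    bp <- params$b_hid; bp[j] <- bp[j] + h
    bm <- params$b_hid; bm[j] <- bm[j] - h
    db[j] <- (penalty(params$W, bp) - penalty(params$W, bm)) / (2 * h)
  }
  list(dW = dW, db = db)
}

## Small random RBM with all parameters drawn at a given scale.
random_rbm <- function(n_v, n_h, sd = 0.5, seed = 1) {
  set.seed(seed)
  rbm_params(matrix(rnorm(n_v * n_h, sd = sd), n_v, n_h),
             rnorm(n_v, sd = sd), rnorm(n_h, sd = sd))
}

## Tiny two-prototype binary dataset for RBM training checks.
prototype_data <- function(n_rep = 20, noise = 0) {
  proto <- rbind(c(1, 1, 1, 1, 0, 0, 0, 0),
                 c(0, 0, 0, 0, 1, 1, 1, 1))
  X <- proto[rep(1:2, each = n_rep), ]
  if (noise > 0) X <- pmin(pmax(X + matrix(rnorm(length(X), sd = noise),
                                           nrow(X)), 0), 1)
  X
}
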