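#' Construct sparse-response RBM parameters
#'
#' Bundles the weight matrix and the two bias vectors of one restricted
#' Boltzmann machine. `W[i, j]` couples visible unit `i` to hidden unit `j`;
#' `c_vis` biases the visible layer and `b_hid` the hidden layer.
#'
#' @param W numeric `n_v x n_h` weight matrix.
#' @param c_vis numeric visible bias vector, length `n_v`.
#' @param b_hid numeric hidden bias vector, length `n_h`.
#' @return An object of class `rbm_params`.
#' @export
rbm_params <- function(W, c_vis, b_hid) {
  W <- as.matrix(W)
  c_vis <- as.numeric(c_vis)
  b_hid <- as.numeric(b_hid)
  if (nrow(W) != length(c_vis) || ncol(W) != length(b_hid))
    abort_validation(sprintf(
      "inconsistent RBM shapes: W is %d x %d, c_vis length %d, b_hid length %d",
      nrow(W), ncol(W), length(c_vis), length(b_hid)))
  if (!all(is.finite(W)) || !all(is.finite(c_vis)) || !all(is.finite(b_hid)))
    abort_validation("RBM parameters must be finite")
  structure(list(W = W, c_vis = c_vis, b_hid = b_hid), class = "rbm_params")
}

#' Randomly initialise an RBM
#'
#' Weights are drawn `N(0, weight_init_sd^2)`; both bias vectors start at
#' zero.
#'
#' @param n_v,n_h visible and hidden layer sizes.
#' @param weight_init_sd standard deviation of the weight initialisation.
#' @param seed integer seed; identical seeds give identical parameters.
#' @return An `rbm_params` object.
#' @export
init_rbm <- function(n_v, n_h, weight_init_sd = 0.01, seed = 1L) {
  if (!is_count(n_v) || !is_count(n_h))
    abort_validation("n_v and n_h must be positive integers")
  set.seed(seed)
  rbm_params(matrix(stats::rnorm(n_v * n_h, sd = weight_init_sd), n_v, n_h),
             numeric(n_v), numeric(n_h))
}

#' @export
print.rbm_params <- function(x, ...) {
  cat(sprintf("<rbm_params> %d visible x %d hidden units\n",
              nrow(x$W), ncol(x$W)))
  invisible(x)
}

#' Training configuration for a sparse-response RBM
#'
#' @param epsilon learning rate, > 0.
#' @param lam weight of the L1 activation-sparsity penalty, >= 0. `lam = 0`
#'   recovers a plain CD-trained RBM.
#' @param cd_steps Gibbs steps per contrastive-divergence update (k >= 1).
#' @param epochs full passes over the data.
#' @param batch_size mini-batch size.
#' @param weight_init_sd weight initialisation standard deviation.
#' @param seed integer seed controlling initialisation, batch order, and
#'   Gibbs sampling.
#' @return An object of class `sr_train_config`.
#' @export
sr_train_config <- function(epsilon = 0.1, lam = 0.1, cd_steps = 1L,
                            epochs = 30L, batch_size = 16L,
                            weight_init_sd = 0.01, seed = 1L) {
  if (!(epsilon > 0)) abort_validation("epsilon must be > 0")
  if (lam < 0) abort_validation("lam must be >= 0")
  if (!is_count(cd_steps)) abort_validation("cd_steps must be >= 1")
  if (!is_count(epochs) || !is_count(batch_size))
    abort_validation("epochs and batch_size must be positive integers")
  structure(list(epsilon = epsilon, lam = lam, cd_steps = as.integer(cd_steps),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 weight_init_sd = weight_init_sd, seed = as.integer(seed)),
            class = "sr_train_config")
}

#' Hidden-unit conditional activation probabilities
#'
#' `p(h_j = 1 | v) = sigmoid(sum_i v_i W[i, j] + b_hid[j])`, computed row-wise
#' for a batch of visible vectors.
#'
#' @param params an `rbm_params` object.
#' @param V numeric matrix, one visible configuration per row.
#' @return Matrix of probabilities, `nrow(V) x n_h`.
#' @export
hidden_probs <- function(params, V) {
  V <- as_batch(V, nrow(params$W), "visible")
  sigmoid(add_bias(V %*% params$W, params$b_hid))
}

#' Visible-unit conditional activation probabilities
#'
#' `p(v_i = 1 | h) = sigmoid(sum_j h_j W[i, j] + c_vis[i])`.
#'
#' @param params an `rbm_params` object.
#' @param H numeric matrix, one hidden configuration per row.
#' @return Matrix of probabilities, `nrow(H) x n_v`.
#' @export
visible_probs <- function(params, H) {
  H <- as_batch(H, ncol(params$W), "hidden")
  sigmoid(add_bias(H %*% t(params$W), params$c_vis))
}

as_batch <- function(X, want_cols, layer) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != want_cols)
    abort_validation(sprintf("%s batch has %d columns, expected %d",
                             layer, ncol(X), want_cols))
  X
}

#' Sample a Bernoulli matrix
#'
#' Independent draws from the current R random stream; seed the stream with
#' [set.seed()] for reproducibility.
#'
#' @param P matrix of probabilities in \[0, 1\].
#' @return Binary matrix of the same shape.
#' @export
sample_bernoulli <- function(P) {
  P <- as.matrix(P)
  if (any(P < 0 | P > 1, na.rm = TRUE) || anyNA(P))
    abort_validation("probabilities must lie in [0, 1]")
  (matrix(stats::runif(length(P)), nrow(P), ncol(P)) < P) + 0
}

#' Contrastive-divergence sufficient statistics
#'
#' Runs the CD-k chain from a data batch and returns the positive- and
#' negative-phase expectations that drive the parameter updates. The positive
#' phase pairs the data with hidden *probabilities*. The chain is true block
#' Gibbs sampling (sampled hidden, then sampled visible states), so its
#' stationary law is the model equilibrium; the negative-phase statistics are
#' Rao-Blackwellised — the visible mean uses `p(v | h)` and the pairwise
#' statistic pairs the sampled visibles with `p(h | v)` — which keeps the
#' estimates unbiased while reducing Monte-Carlo variance.
#'
#' @param params an `rbm_params` object.
#' @param V data batch with values in \[0, 1\], one row per example.
#' @param k number of Gibbs steps (>= 1).
#' @return List with batch-averaged fields `pos_vh`, `pos_v`, `pos_h`,
#'   `neg_vh`, `neg_v`, `neg_h` and the reconstruction matrix `v_recon`.
#' @export
cd_statistics <- function(params, V, k = 1L) {
  if (!is_count(k)) abort_validation("k must be a positive integer")
  V <- as_batch(V, nrow(params$W), "visible")
  if (any(V < 0 | V > 1)) abort_validation("visible data must lie in [0, 1]")
  m <- nrow(V)
  ph0 <- hidden_probs(params, V)
  v_samp <- V
  ph <- ph0
  for (step in seq_len(k)) {
    h_samp <- sample_bernoulli(ph)
    v_prob <- visible_probs(params, h_samp)
    v_samp <- sample_bernoulli(v_prob)
    ph <- hidden_probs(params, v_samp)
  }
  list(pos_vh = crossprod(V, ph0) / m,
       pos_v = colMeans(V),
       pos_h = colMeans(ph0),
       neg_vh = crossprod(v_samp, ph) / m,
       neg_v = colMeans(v_prob),
       neg_h = colMeans(ph),
       v_recon = v_prob)
}

#' One contrastive-divergence parameter update
#'
#' Applies the three CD update rules with batch-averaged statistics:
#' `W <- W + epsilon * (<v h'>_data - <v h'>_recon)`, and likewise for the
#' visible and hidden biases.
#'
#' @param params an `rbm_params` object.
#' @param batch data matrix in \[0, 1\], one row per example.
#' @param config an [sr_train_config()]; uses `epsilon` and `cd_steps`.
#' @return Updated `rbm_params`.
#' @export
cd1_update <- function(params, batch, config) {
  batch <- as_batch(batch, nrow(params$W), "visible")
  if (nrow(batch) == 0) abort_validation("batch must be nonempty")
  s <- cd_statistics(params, batch, config$cd_steps)
  apply_cd_update(params, s, config$epsilon)
}

apply_cd_update <- function(params, s, epsilon) {
  rbm_params(params$W + epsilon * (s$pos_vh - s$neg_vh),
             params$c_vis + epsilon * (s$pos_v - s$neg_v),
             params$b_hid + epsilon * (s$pos_h - s$neg_h))
}

#' Gradient of the activation-sparsity penalty
#'
#' The sparse-response objective penalises the L1 norm of the hidden
#' conditional activation probabilities, `sum_l || p(h | v^(l)) ||_1`.
#' Because each probability is a sigmoid, the negative gradient is
#' `-sum_l p_j(l) (1 - p_j(l)) v_i(l)` for `W[i, j]` and
#' `-sum_l p_j(l) (1 - p_j(l))` for `b_hid[j]`; the visible bias does not
#' appear in the penalty. Contributions are summed (not averaged) over the
#' batch.
#'
#' @param params an `rbm_params` object.
#' @param batch data matrix, one row per example.
#' @return List with components `dW` (`n_v x n_h`) and `db` (length `n_h`),
#'   the negative gradients to be *added* (scaled by `epsilon * lam`) in a
#'   descent step on the penalised objective.
#' @export
sparsity_gradient <- function(params, batch) {
  batch <- as_batch(batch, nrow(params$W), "visible")
  if (nrow(batch) == 0) abort_validation("batch must be nonempty")
  p <- hidden_probs(params, batch)
  g <- p * (1 - p)                      # m x n_h
  list(dW = -crossprod(batch, g),       # n_v x n_h
       db = -colSums(g))
}

#' Train a sparse-response RBM
#'
#' Mini-batch contrastive divergence with an additive sparsity step: each
#' batch first applies the CD update, then adds
#' `epsilon * lam * sparsity_gradient` as a second update. With `lam = 0`
#' this is exactly plain CD training.
#'
#' @param X data matrix with values in \[0, 1\], one row per example.
#' @param config an [sr_train_config()].
#' @param params optional initial `rbm_params`; when `NULL`, initialised from
#'   `config` (`weight_init_sd`, `seed`) with `ncol(X)` visible units.
#' @param n_hidden hidden layer size used when `params` is `NULL`.
#' @return A list of class `train_trace` with elements `params` (final
#'   `rbm_params`), `recon_error` (per-epoch mean squared one-step
#'   reconstruction error) and `mean_activation` (per-epoch mean hidden
#'   activation probability).
#' @export
train_srrbm <- function(X, config, params = NULL, n_hidden = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0) abort_validation("X must be nonempty")
  if (any(X < 0 | X > 1)) abort_validation("X values must lie in [0, 1]")
  if (is.null(params)) {
    if (is.null(n_hidden)) abort_validation("supply params or n_hidden")
    params <- init_rbm(ncol(X), n_hidden, config$weight_init_sd, config$seed)
  }
  set.seed(derive_seed(config$seed, "train_srrbm"))
  n <- nrow(X)
  recon_error <- numeric(config$epochs)
  mean_act <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    err_sum <- 0
    act_sum <- 0
    for (b in starts) {
      idx <- ord[b:min(b + config$batch_size - 1, n)]
      batch <- X[idx, , drop = FALSE]
      s <- cd_statistics(params, batch, config$cd_steps)
      params <- apply_cd_update(params, s, config$epsilon)
      if (config$lam > 0) {
        ## averaged over the batch, matching the per-example scale of the
        ## batch-averaged CD statistics
        sg <- sparsity_gradient(params, batch)
        scale <- config$epsilon * config$lam / nrow(batch)
        params <- rbm_params(params$W + scale * sg$dW,
                             params$c_vis,
                             params$b_hid + scale * sg$db)
      }
      if (!all(is.finite(params$W)))
        abort_state(sprintf("non-finite parameters at epoch %d", epoch))
      err_sum <- err_sum + sum((batch - s$v_recon)^2)
      act_sum <- act_sum + sum(hidden_probs(params, batch))
    }
    recon_error[epoch] <- err_sum / (n * ncol(X))
    mean_act[epoch] <- act_sum / (n * ncol(params$W))
  }
  structure(list(params = params, recon_error = recon_error,
                 mean_activation = mean_act),
            class = "train_trace")
}

#' Exact moments of a small RBM by exhaustive enumeration
#'
#' Computes `<v_i h_j>`, `<v_i>`, `<h_j>` under the Boltzmann equilibrium
#' distribution with energy
#' `E(v, h) = -sum_ij W[i,j] v_i h_j - sum_i c_vis[i] v_i - sum_j b_hid[j] h_j`,
#' plus the log partition function. The hidden layer is summed out
#' analytically, so the cost is `2^n_v` visible configurations; intended as a
#' ground-truth oracle for contrastive-divergence convergence on tiny models.
#'
#' @param params an `rbm_params` with `n_v + n_h <= 20`.
#' @return List with `vh` (`n_v x n_h`), `v`, `h`, and `log_z`.
#' @export
exact_model_statistics <- function(params) {
  n_v <- nrow(params$W)
  n_h <- ncol(params$W)
  if (n_v + n_h > 20)
    abort_validation("exact enumeration limited to n_v + n_h <= 20")
  Vall <- as.matrix(expand.grid(rep(list(c(0, 1)), n_v)))[, seq_len(n_v),
                                                          drop = FALSE]
  storage.mode(Vall) <- "double"
  dimnames(Vall) <- NULL
  ## unnormalised log p(v): c'v + sum_j log(1 + exp(b_j + w_j'v))
  act <- add_bias(Vall %*% params$W, params$b_hid)
  log_pv <- drop(Vall %*% params$c_vis) + rowSums(log1p(exp(act)))
  log_z <- log_sum_exp(log_pv)
  pv <- exp(log_pv - log_z)
  ph <- sigmoid(act)                    # E[h_j | v]
  list(vh = crossprod(Vall * pv, ph),
       v = drop(crossprod(Vall, pv)),
       h = drop(crossprod(ph, pv)),
       log_z = log_z)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
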