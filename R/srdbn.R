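#' Build an untrained sparse-response deep belief network
#'
#' An ordered stack of RBMs whose layer dimensions chain (the hidden size of
#' layer t is the visible size of layer t + 1). The default architecture is
#' three hidden layers of one shared size.
#'
#' @param input_dim visible dimension of the first layer.
#' @param hidden_size shared hidden layer size.
#' @param n_hidden_layers number of stacked RBMs (default 3).
#' @param weight_init_sd weight initialisation standard deviation.
#' @param seed integer seed; per-layer substreams are derived from it.
#' @return An object of class `dbn_model`.
#' @export
build_dbn <- function(input_dim, hidden_size, n_hidden_layers = 3L,
                      weight_init_sd = 0.01, seed = 1L) {
  if (!is_count(input_dim) || !is_count(hidden_size) ||
      !is_count(n_hidden_layers))
    abort_validation("all sizes must be positive integers")
  sizes <- c(input_dim, rep(hidden_size, n_hidden_layers))
  layers <- lapply(seq_len(n_hidden_layers), function(t)
    init_rbm(sizes[t], sizes[t + 1], weight_init_sd,
             derive_seed(seed, paste0("dbn_layer", t))))
  structure(list(layers = layers, layer_sizes = sizes, head = NULL,
                 finetuned = FALSE, pretrained = FALSE,
                 seed = as.integer(seed)),
            class = "dbn_model")
}

#' @export
print.dbn_model <- function(x, ...) {
  cat(sprintf("<dbn_model> layers %s; %spretrained%s\n",
              paste(x$layer_sizes, collapse = " -> "),
              if (x$pretrained) "" else "not ",
              if (x$finetuned) ", fine-tuned" else ""))
  invisible(x)
}

#' Greedy layerwise pretraining
#'
#' Trains the first RBM on the data with [train_srrbm()], then propagates
#' deterministic hidden probabilities (never samples) as the next layer's
#' training data, and so on up the stack.
#'
#' @param model a `dbn_model`.
#' @param X training matrix in \[0, 1\], columns matching `input_dim`.
#' @param config an [sr_train_config()]; per-layer seeds are derived from
#'   `config$seed`.
#' @return The pretrained `dbn_model`, with per-layer [train_srrbm()] traces
#'   in `$traces`.
#' @export
pretrain <- function(model, X, config) {
  X <- as.matrix(X)
  if (ncol(X) != model$layer_sizes[1])
    abort_validation(sprintf("X has %d columns, model input_dim is %d",
                             ncol(X), model$layer_sizes[1]))
  H <- X
  traces <- vector("list", length(model$layers))
  for (t in seq_along(model$layers)) {
    layer_cfg <- config
    layer_cfg$seed <- derive_seed(config$seed, paste0("pretrain_layer", t))
    tr <- tryCatch(train_srrbm(H, layer_cfg, params = model$layers[[t]]),
                   error = function(e)
                     abort_state(sprintf("layer %d: %s", t,
                                         conditionMessage(e))))
    model$layers[[t]] <- tr$params
    traces[[t]] <- tr
    H <- hidden_probs(tr$params, H)
  }
  model$traces <- traces
  model$pretrained <- TRUE
  model
}

#' Deterministic top-layer feature extraction
#'
#' A pure forward pass of sigmoid activations through every hidden layer; no
#' sampling, so identical inputs always give identical features in (0, 1).
#'
#' @param model a pretrained `dbn_model`.
#' @param X input matrix.
#' @return `nrow(X) x hidden_size` activation matrix of the top layer.
#' @export
extract_features <- function(model, X) {
  acts <- dbn_forward(model, X)
  acts[[length(acts)]]
}

## Forward pass returning activations of every layer (input first).
dbn_forward <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$layer_sizes[1])
    abort_validation(sprintf("X has %d columns, model input_dim is %d",
                             ncol(X), model$layer_sizes[1]))
  acts <- vector("list", length(model$layers) + 1)
  acts[[1]] <- X
  for (t in seq_along(model$layers))
    acts[[t + 1]] <- hidden_probs(model$layers[[t]], acts[[t]])
  acts
}

#' Supervised fine-tuning by full-network backpropagation
#'
#' Attaches a softmax output head on the top hidden layer and runs plain
#' gradient descent on the cross-entropy of the training labels, updating
#' every layer's weights and hidden biases. The head is kept for
#' diagnostics, but classification downstream is done by the ELM on the
#' extracted features, not by this head.
#'
#' @param model a pretrained `dbn_model`.
#' @param X training matrix.
#' @param labels integer class codes `0..(K-1)` aligned with rows of `X`.
#' @param lr learning rate for gradient descent.
#' @param epochs full-batch gradient steps.
#' @param seed seed for the head initialisation.
#' @return The fine-tuned `dbn_model` with `$head` and a cross-entropy trace
#'   in `$finetune_loss`.
#' @export
finetune <- function(model, X, labels, lr = 0.1, epochs = 50L, seed = 1L) {
  if (!model$pretrained) abort_state("model must be pretrained first")
  X <- as.matrix(X)
  labels <- as.integer(labels)
  if (nrow(X) != length(labels))
    abort_validation("labels must align with rows of X")
  k <- length(unique(labels))
  top <- model$layer_sizes[length(model$layer_sizes)]
  set.seed(derive_seed(seed, "finetune_head"))
  head <- list(W = matrix(stats::rnorm(top * k, sd = 0.01), top, k),
               b = numeric(k))
  Y <- matrix(0, nrow(X), k)
  Y[cbind(seq_len(nrow(X)), labels + 1L)] <- 1
  loss_trace <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    fg <- dbn_loss_grad(model, head, X, Y)
    if (!is.finite(fg$loss))
      abort_state(sprintf("non-finite fine-tuning loss at epoch %d", epoch))
    loss_trace[epoch] <- fg$loss
    head$W <- head$W - lr * fg$dheadW
    head$b <- head$b - lr * fg$dheadb
    for (t in seq_along(model$layers)) {
      model$layers[[t]]$W <- model$layers[[t]]$W - lr * fg$dW[[t]]
      model$layers[[t]]$b_hid <- model$layers[[t]]$b_hid - lr * fg$db[[t]]
    }
  }
  model$head <- head
  model$finetuned <- TRUE
  model$finetune_loss <- loss_trace
  model
}

## Mean cross-entropy of the softmax head and its gradients w.r.t. the head
## and every layer's weights/hidden biases (visible biases do not enter the
## forward pass).
dbn_loss_grad <- function(model, head, X, Y) {
  acts <- dbn_forward(model, X)
  n <- nrow(X)
  top <- acts[[length(acts)]]
  logits <- add_bias(top %*% head$W, head$b)
  logits <- logits - apply(logits, 1L, max)
  P <- exp(logits)
  P <- P / rowSums(P)
  loss <- -sum(Y * log(pmax(P, 1e-300))) / n
  delta_out <- (P - Y) / n                       # n x k
  dheadW <- crossprod(top, delta_out)
  dheadb <- colSums(delta_out)
  delta <- tcrossprod(delta_out, head$W)         # gradient w.r.t. top acts
  nl <- length(model$layers)
  dW <- vector("list", nl)
  db <- vector("list", nl)
  for (t in rev(seq_len(nl))) {
    a <- acts[[t + 1]]
    dz <- delta * a * (1 - a)                    # through the sigmoid
    dW[[t]] <- crossprod(acts[[t]], dz)
    db[[t]] <- colSums(dz)
    if (t > 1) delta <- tcrossprod(dz, model$layers[[t]]$W)
  }
  list(loss = loss, dheadW = dheadW, dheadb = dheadb, dW = dW, db = db)
}
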