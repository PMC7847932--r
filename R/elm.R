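#' Initialise an extreme learning machine
#'
#' The input-to-hidden weights `A` and hidden biases `d_bias` are drawn
#' uniformly on \[-1, 1\] and *never trained*; only the output weights
#' `beta` are learned, in closed form, by [fit_elm()].
#'
#' @param input_dim feature dimension of the inputs.
#' @param L number of hidden nodes.
#' @param seed integer seed; identical seeds give identical weights.
#' @return An object of class `elm_model` (unfitted).
#' @export
init_elm <- function(input_dim, L, seed = 1L) {
  if (!is_count(input_dim) || !is_count(L))
    abort_validation("input_dim and L must be positive integers")
  set.seed(seed)
  structure(list(A = matrix(stats::runif(input_dim * L, -1, 1), input_dim, L),
                 d_bias = stats::runif(L, -1, 1),
                 L = as.integer(L), beta = NULL, class_names = NULL,
                 activation = "sigmoid", seed = as.integer(seed)),
            class = "elm_model")
}

#' Hidden-layer output matrix
#'
#' `H = sigmoid(X A + d_bias)`, the fixed random feature map of the ELM.
#'
#' @param model an `elm_model`.
#' @param X input matrix, `input_dim` columns.
#' @return `nrow(X) x L` matrix.
#' @export
elm_hidden <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$A))
    abort_validation(sprintf("X has %d columns, model expects %d",
                             ncol(X), nrow(model$A)))
  sigmoid(add_bias(X %*% model$A, model$d_bias))
}

#' Fit ELM output weights by Moore-Penrose pseudoinverse
#'
#' Builds the one-hot target matrix `T` (1 for the true class, 0 elsewhere)
#' and solves `beta = pinv(H) %*% T`, the minimum-norm least-squares
#' solution, via SVD with singular values below `rcond * sigma_max` treated
#' as zero.
#'
#' @param model an `elm_model` from [init_elm()].
#' @param X training inputs.
#' @param labels integer class codes `0..(K-1)` or a factor.
#' @param class_names optional ordered class vocabulary; defaults to the
#'   sorted unique labels.
#' @param rcond relative singular-value cutoff for the pseudoinverse.
#' @return The fitted `elm_model` with `beta` and `class_names` set.
#' @export
fit_elm <- function(model, X, labels, class_names = NULL, rcond = 1e-10) {
  X <- as.matrix(X)
  if (nrow(X) != length(labels))
    abort_validation("labels must align with rows of X")
  if (is.factor(labels)) {
    class_names <- class_names %||% levels(labels)
    labels <- as.integer(labels) - 1L
  }
  codes <- sort(unique(labels))
  if (length(codes) < 2) abort_validation("need at least 2 classes")
  class_names <- class_names %||% as.character(codes)
  H <- elm_hidden(model, X)
  if (qr(H)$rank < length(class_names))
    warning("hidden matrix rank below class count; minimum-norm solution returned")
  Tmat <- matrix(0, nrow(X), length(class_names))
  Tmat[cbind(seq_len(nrow(X)), labels + 1L)] <- 1
  model$beta <- pinv(H, rcond) %*% Tmat
  model$class_names <- class_names
  model
}

## Moore-Penrose pseudoinverse via SVD with relative truncation.
pinv <- function(M, rcond = 1e-10) {
  sv <- svd(M)
  keep <- sv$d > rcond * max(sv$d)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Predict classes with a fitted ELM
#'
#' Scores are `H %*% beta`; the predicted class is the arg-max score with
#' ties broken toward the lowest class code. For binary tasks the continuous
#' score of the designated positive class feeds ROC analysis.
#'
#' @param object a fitted `elm_model`.
#' @param X input matrix.
#' @param ... unused.
#' @return List with `codes` (integer class codes), `class` (class names)
#'   and `scores` (`nrow(X) x K` matrix, columns named by class).
#' @export
predict.elm_model <- function(object, X, ...) {
  if (is.null(object$beta)) abort_state("ELM model has not been fitted")
  scores <- elm_hidden(object, X) %*% object$beta
  colnames(scores) <- object$class_names
  codes <- max.col(scores, ties.method = "first") - 1L
  list(codes = codes, class = object$class_names[codes + 1L], scores = scores)
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> %d -> %d hidden nodes; %s\n", nrow(x$A), x$L,
              if (is.null(x$beta)) "unfitted" else
                paste0("fitted, classes: ",
                       paste(x$class_names, collapse = ", "))))
  invisible(x)
}
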