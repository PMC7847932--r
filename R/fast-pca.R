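#' Fit principal components via the snapshot ("fast") method
#'
#' Exact PCA of the column-centered data. When features outnumber samples
#' (`p > n`) the eigendecomposition of the `n x n` Gram matrix is used and
#' eigenvectors are mapped back to feature space — the standard snapshot
#' trick for voxel-scale data where `p` is in the tens of thousands and `n`
#' in the hundreds; otherwise a direct thin SVD is taken. Both paths give
#' the same subspace; components are sign-fixed so the largest-magnitude
#' loading of each component is positive.
#'
#' @param X numeric `n x p` data matrix, one sample per row.
#' @param k number of components to retain, `k <= min(n, p)`.
#' @return An object of class `pca_model` with fields `mean` (feature
#'   means), `components` (`k x p`, orthonormal rows), `explained_variance`
#'   (descending), and `explained_variance_ratio`.
#' @export
fit_fast_pca <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2) abort_validation("need at least 2 samples")
  if (!is_count(k) || k > min(n, p))
    abort_validation(sprintf("k must be in 1..min(n, p) = %d", min(n, p)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  total_var <- sum(Xc^2) / (n - 1)
  if (total_var < .Machine$double.eps) {
    warning("data have zero variance; returning a model with no components")
    return(structure(list(mean = mu,
                          components = matrix(0, 0, p),
                          explained_variance = numeric(0),
                          explained_variance_ratio = numeric(0)),
                     class = "pca_model"))
  }
  if (p > n) {
    G <- tcrossprod(Xc)                 # n x n Gram matrix
    eg <- eigen(G, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    keep <- seq_len(k)
    lam <- ev[keep]
    ## map Gram eigenvectors u to feature-space axes v = X' u / sqrt(lambda)
    denom <- sqrt(pmax(lam, .Machine$double.eps))
    comp <- t(crossprod(Xc, eg$vectors[, keep, drop = FALSE]) %*%
                diag(1 / denom, k, k))
    variances <- lam / (n - 1)
  } else {
    sv <- svd(Xc, nu = 0, nv = k)
    comp <- t(sv$v)
    variances <- (sv$d[seq_len(k)]^2) / (n - 1)
  }
  comp <- fix_component_signs(comp)
  structure(list(mean = mu, components = comp,
                 explained_variance = variances,
                 explained_variance_ratio = variances / total_var),
            class = "pca_model")
}

## Sign convention: the largest-|loading| entry of each component is positive.
fix_component_signs <- function(comp) {
  for (j in seq_len(nrow(comp))) {
    i <- which.max(abs(comp[j, ]))
    if (comp[j, i] < 0) comp[j, ] <- -comp[j, ]
  }
  comp
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d features; cumulative EVR %.3f\n",
              nrow(x$components), length(x$mean),
              sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project data onto fitted principal components
#'
#' @param model a `pca_model`.
#' @param X matrix with the same feature count the model was fitted on.
#' @return Score matrix, `nrow(X) x k`.
#' @export
pca_transform <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean))
    abort_validation(sprintf("X has %d columns, model expects %d",
                             ncol(X), length(model$mean)))
  sweep(X, 2L, model$mean) %*% t(model$components)
}

#' Reconstruct data from principal-component scores
#'
#' @param model a `pca_model`.
#' @param scores matrix of scores, `k` columns.
#' @return Reconstruction in the original feature space.
#' @export
pca_inverse_transform <- function(model, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != nrow(model$components))
    abort_validation("score column count does not match model components")
  sweep(scores %*% model$components, 2L, model$mean, `+`)
}

#' Smallest number of components reaching a variance threshold
#'
#' @param ratios explained-variance ratios, nonnegative and non-increasing.
#' @param threshold target cumulative ratio in (0, 1\]; default 0.90.
#' @return The smallest `k` whose cumulative ratio reaches `threshold`; if
#'   the total falls short, the full length with a warning.
#' @export
select_k_for_variance <- function(ratios, threshold = 0.90) {
  if (length(ratios) == 0) abort_validation("ratios must be nonempty")
  if (any(ratios < 0) || any(diff(ratios) > 1e-12))
    abort_validation("ratios must be nonnegative and non-increasing")
  if (!(threshold > 0 && threshold <= 1))
    abort_validation("threshold must be in (0, 1]")
  cum <- cumsum(ratios)
  hit <- which(cum >= threshold - 1e-12)
  if (length(hit) == 0) {
    warning(sprintf("total explained variance %.4f below threshold %.2f; using all components",
                    cum[length(cum)], threshold))
    return(length(ratios))
  }
  hit[1]
}
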