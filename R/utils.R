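#' @keywords internal
"_PACKAGE"

## Classed conditions so callers can distinguish bad inputs from I/O trouble.
abort_validation <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("srdbnelm_validation_error", "error"),
                      call = call))
}

abort_io <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("srdbnelm_io_error", "error"),
                      call = call))
}

abort_state <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("srdbnelm_state_error", "error"),
                      call = call))
}

#' Logistic sigmoid
#'
#' @param x numeric vector or matrix.
#' @return `1 / (1 + exp(-x))`, same shape as `x`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

## Deterministic sub-seed derivation: every source of randomness in the
## package draws from a named substream of one master seed, so that a run is
## reproducible end to end from a single integer. Polynomial string hash,
## folded with the master seed modulo a prime below 2^31.
derive_seed <- function(master, tag) {
  stopifnot(length(master) == 1, is.finite(master))
  p <- 2147483629
  h <- as.double(master %% p)
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + ch) %% p
  }
  as.integer(h)
}

## Row-wise sweep of a bias vector onto a matrix product.
add_bias <- function(M, bias) sweep(M, 2L, bias, `+`)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
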