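# Shared internal helpers.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so library calls never disturb user-level randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# One-hot encode a factor (columns in level order), values in {0, 1}.
one_hot <- function(labels) {
  f <- as.factor(labels)
  Y <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  Y[cbind(seq_along(f), as.integer(f))] <- 1
  Y
}

# Column standardization; constant columns are mapped to zero.
# Returns list(x, center, scale) so the transform can be replayed.
standardize <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  if (is.null(scale)) {
    scale <- sqrt(colMeans(Xc^2))
    scale[scale < 1e-12] <- 1
  }
  list(x = sweep(Xc, 2, scale, "/"), center = center, scale = scale)
}

# Multi-response ridge solve of (X'X + lambda I) W = X'Y, using the
# dual form X'(XX' + lambda I)^{-1} Y when p > n.
ridge_solve <- function(X, Y, lambda = 1) {
  n <- nrow(X); p <- ncol(X)
  if (p <= n) {
    solve(crossprod(X) + diag(lambda, p), crossprod(X, Y))
  } else {
    crossprod(X, solve(tcrossprod(X) + diag(lambda, n), Y))
  }
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Round half away from zero
#'
#' Presentation rounding used for reported margins and percentages;
#' unlike [round()], exact halves move away from zero (2.5 -> 3).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a stream-specific 32-bit sub-seed from a user seed.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103 + offset * 12347) %% 2147483647)
}
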