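#' PLS-SVD fusion of two feature blocks
#'
#' The two blocks (e.g. features from two different backbones, after
#' selection) are centered and the direction pairs `(u_i, v_i)`
#' maximizing the sample cross-covariance `Cov(A u, B v)` under unit
#' norm are taken simultaneously from the SVD of the cross-covariance
#' matrix `A_c' B_c / (n - 1)`. The fused representation is the
#' concatenation of the two score matrices, giving `2d` columns.
#'
#' @name fuse-module
NULL

#' Fit a PLS-SVD fusion model
#'
#' @param A,B [feature_matrix()] objects or numeric matrices with the
#'   same number of rows (same samples, same order).
#' @param d number of direction pairs; capped at
#'   `min(ncol(A), ncol(B), n - 1)` and defaulting to at most 8.
#' @return list of class `fusion_model` with block means, the
#'   cross-covariance, direction matrices `u` and `v` (unit columns;
#'   the largest-magnitude entry of each `u_i` is positive), singular
#'   values `sv` (non-increasing), `d`, and `informative` (`FALSE` when
#'   all singular values are numerically zero).
#' @export
fit_fusion <- function(A, B, d = 8L) {
  if (inherits(A, "feature_matrix")) A <- A$values
  if (inherits(B, "feature_matrix")) B <- B$values
  n <- nrow(A)
  if (nrow(B) != n)
    stop("sample-count mismatch: ", n, " vs ", nrow(B))
  dmax <- min(ncol(A), ncol(B), n - 1)
  if (d > dmax) stop("d = ", d, " exceeds the usable rank ", dmax)
  mA <- colMeans(A); mB <- colMeans(B)
  Ac <- sweep(A, 2, mA); Bc <- sweep(B, 2, mB)
  Cx <- crossprod(Ac, Bc) / (n - 1)
  sv <- svd(Cx, nu = d, nv = d)
  U <- sv$u; V <- sv$v
  for (i in seq_len(d)) {
    s <- sign(U[which.max(abs(U[, i])), i])
    if (s < 0) { U[, i] <- -U[, i]; V[, i] <- -V[, i] }
  }
  structure(list(mean_a = mA, mean_b = mB, cross_covariance = Cx,
                 u = U, v = V, sv = sv$d[seq_len(d)], d = as.integer(d),
                 informative = max(sv$d) > 1e-10),
            class = "fusion_model")
}

#' Project two blocks through a fusion model
#'
#' @param A,B blocks compatible with the model (same feature columns as
#'   at fit time).
#' @param model a `fusion_model`.
#' @param labels optional labels carried into the result.
#' @return a [feature_matrix()] with `2 * model$d` columns: the block-A
#'   scores followed by the block-B scores, row order preserved.
#' @export
fuse_blocks <- function(A, B, model, labels = NULL) {
  if (inherits(A, "feature_matrix")) { if (is.null(labels)) labels <- A$labels; A <- A$values }
  if (inherits(B, "feature_matrix")) B <- B$values
  if (ncol(A) != length(model$mean_a) || ncol(B) != length(model$mean_b))
    stop("block dimensions do not match the fusion model")
  if (nrow(A) != nrow(B)) stop("sample-count mismatch")
  TA <- sweep(A, 2, model$mean_a) %*% model$u
  TB <- sweep(B, 2, model$mean_b) %*% model$v
  vals <- cbind(TA, TB)
  colnames(vals) <- c(paste0("a", seq_len(model$d)), paste0("b", seq_len(model$d)))
  feature_matrix(vals, labels = labels, source = "pls_fusion")
}
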