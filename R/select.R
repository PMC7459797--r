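#' Correntropy-based group-sparse feature selection (CML-ELM)
#'
#' Selects whole feature columns by minimizing a correntropy-induced
#' (Welsch) multiclass regression loss plus a group-L2 penalty over
#' feature rows, using an accelerated proximal gradient method with
#' backtracking step-size search. An extreme learning machine is
#' retrained on the currently selected columns at every iteration and
#' its training mean-squared error (MSER) acts as the stopping signal.
#'
#' @name select-module
NULL

#' Configuration for [run_selection()]
#'
#' @param max_iter maximum number of proximal iterations (default 1000).
#' @param lr0 initial inverse step size (default 1).
#' @param p0 group-penalty weight; `NULL` (default) sets it to 20% of
#'   the critical penalty `max_j ||grad_j f(0)||_2` (the smallest
#'   weight at which the all-zero solution is stationary), the usual
#'   fraction-of-lambda-max choice for group-sparse fits.
#' @param sigma correntropy kernel width, on the scale of the one-hot
#'   targets. The default 1 makes the loss near-quadratic for residuals
#'   within the unit target range while damping gross outliers;
#'   residual-based estimates are unreliable here because residual
#'   magnitudes grow as feature rows are eliminated.
#' @param mser_target MSER stopping threshold in `(0, 1]` (default 0.1).
#' @param momentum_rule `"paper_literal"` (momentum scalar driven by the
#'   iteration counter) or `"fista_standard"` (driven by the previous
#'   scalar).
#' @param select_eps row-norm threshold deciding whether a feature
#'   counts as selected (default 1e-6).
#' @param w_tol relative weight-change level below which the iterate is
#'   considered stable; the MSER stop only fires once iterates are
#'   stable so that the sparsity pattern has settled (default 1e-3).
#' @param elm_nodes,elm_c hyper-parameters of the in-loop ELM (shared
#'   with the final classifier by default).
#' @param seed integer seed (in-loop ELM hidden layer).
#' @return list of class `selection_config`.
#' @export
selection_config <- function(max_iter = 1000L, lr0 = 1, p0 = NULL, sigma = 1,
                             mser_target = 0.1,
                             momentum_rule = c("paper_literal", "fista_standard"),
                             select_eps = 1e-6, w_tol = 1e-3,
                             elm_nodes = 1000L, elm_c = 1, seed = 1L) {
  momentum_rule <- match.arg(momentum_rule)
  if (max_iter < 1 || lr0 <= 0 || select_eps <= 0 || w_tol <= 0 ||
      elm_nodes < 1 || elm_c <= 0)
    stop("selection_config parameters must be positive")
  if (mser_target <= 0 || mser_target > 1) stop("mser_target must be in (0, 1]")
  if (!is.null(p0) && p0 < 0) stop("p0 must be non-negative")
  if (!is.null(sigma) && sigma <= 0) stop("sigma must be positive")
  structure(list(max_iter = as.integer(max_iter), lr0 = lr0, p0 = p0,
                 sigma = sigma, mser_target = mser_target,
                 momentum_rule = momentum_rule, select_eps = select_eps,
                 w_tol = w_tol, elm_nodes = as.integer(elm_nodes),
                 elm_c = elm_c, seed = as.integer(seed)),
            class = "selection_config")
}

#' Correntropy (Welsch) loss and gradient
#'
#' `loss = sum over entries of 1 - exp(-r^2 / (2 sigma^2))` with
#' residual `R = Y - X W`. Behaves like `sum(R^2) / (2 sigma^2)` for
#' small residuals and saturates at 1 per entry for outliers, giving
#' robustness to grossly mislabeled samples. The gradient is the exact
#' analytic derivative `-(1/sigma^2) X' (R * exp(-R^2 / (2 sigma^2)))`.
#'
#' @param W weight matrix (features x classes).
#' @param X standardized feature matrix (samples x features).
#' @param Y one-hot target matrix (samples x classes).
#' @param sigma positive kernel width.
#' @return list with `loss` (scalar, non-negative) and `gradient`
#'   (same shape as `W`).
#' @export
correntropy_loss <- function(W, X, Y, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  R <- Y - X %*% W
  Z <- R^2 / (2 * sigma^2)
  # -expm1(-z) = 1 - exp(-z) without catastrophic cancellation for
  # small z (the wide-kernel, near-quadratic regime)
  list(loss = sum(-expm1(-Z)),
       gradient = -crossprod(X, R * exp(-Z)) / sigma^2)
}

#' Group-soft-threshold proximal operator
#'
#' Exact minimizer of `0.5 * ||W - V||_F^2 + t * sum_j ||W_j||_2` over
#' feature rows `j`: a row with norm at most `t` is zeroed, otherwise
#' shrunk radially by `t`.
#'
#' @param V numeric matrix (features x classes).
#' @param t non-negative threshold.
#' @return matrix of the same shape; row norms equal
#'   `max(0, ||V_j|| - t)` exactly.
#' @export
group_prox <- function(V, t) {
  if (t < 0) stop("threshold must be non-negative")
  if (t == 0) return(V)
  nrm <- sqrt(rowSums(V^2))
  shrink <- pmax(0, 1 - t / pmax(nrm, 1e-300))
  V * shrink
}

#' Backtracking inverse-step-size search
#'
#' Scans candidates `lr_prev * {1, 2, 3, ...}` (capped at
#' `32 * lr_prev`) and returns the smallest whose proximal step from
#' `V = A - grad/LR` satisfies the quadratic majorization
#' `f(W+) <= f(A) + <grad, W+ - A> + (LR/2) ||W+ - A||^2`. If no
#' candidate in range qualifies, the cap is returned with a warning.
#'
#' @param A extrapolation point (features x classes).
#' @param fgrad function of `W` returning `list(loss, gradient)`.
#' @param lr_prev previous inverse step size.
#' @param p0 group-penalty weight; the prox threshold at candidate `LR`
#'   is `p0 / LR`.
#' @param max_mult cap multiplier (default 32).
#' @return list with `lr`, the accepted step `W` and its loss `f`, plus
#'   `capped` (logical).
#' @export
backtrack_lr <- function(A, fgrad, lr_prev, p0, max_mult = 32L) {
  fa <- fgrad(A)
  if (!is.finite(fa$loss)) stop("non-finite loss at the extrapolation point")
  for (mult in seq_len(max_mult)) {
    lr <- lr_prev * mult
    W <- group_prox(A - fa$gradient / lr, p0 / lr)
    fw <- fgrad(W)$loss
    D <- W - A
    if (fw <= fa$loss + sum(fa$gradient * D) + lr / 2 * sum(D^2))
      return(list(lr = lr, W = W, f = fw, capped = FALSE))
  }
  warning("backtracking reached the 32x step-size cap")
  list(lr = lr, W = W, f = fw, capped = TRUE)
}

#' Momentum scalar update
#'
#' `paper_literal` drives the extrapolation scalar from the iteration
#' counter, `alpha_{i+1} = (1 + sqrt(1 + 4 i^2)) / 2`;
#' `fista_standard` drives it from the previous scalar,
#' `alpha_{i+1} = (1 + sqrt(1 + 4 alpha_i^2)) / 2`.
#'
#' @param i iteration index (>= 1).
#' @param alpha_i current scalar (used by `fista_standard`).
#' @param rule `"paper_literal"` or `"fista_standard"`.
#' @return the next momentum scalar.
#' @export
momentum_update <- function(i, alpha_i, rule = c("paper_literal", "fista_standard")) {
  rule <- match.arg(rule)
  if (rule == "paper_literal") (1 + sqrt(1 + 4 * i^2)) / 2
  else (1 + sqrt(1 + 4 * alpha_i^2)) / 2
}

#' Mean squared error between prediction and target grids
#'
#' @param predicted,observed equal-shaped numeric arrays (one-hot
#'   prediction/label matrices in the selection loop).
#' @return mean over all entries of the squared difference.
#' @export
mser <- function(predicted, observed) {
  if (!identical(dim(predicted), dim(observed)) ||
      length(predicted) != length(observed))
    stop("shape mismatch between predicted and observed")
  mean((predicted - observed)^2)
}

#' Run CML-ELM feature selection
#'
#' Columns of `X` are standardized; the weight matrix is initialized by
#' a ridge fit of the one-hot labels. Each iteration forms the
#' extrapolation point from the previous two iterates, backtracks the
#' inverse step size, takes a group-soft-threshold proximal step, and
#' updates the momentum scalar. If the penalized objective increases,
#' the step is retaken without extrapolation and the momentum is
#' restarted, which makes the objective trace non-increasing. An ELM is
#' trained on the currently selected columns every iteration; the run
#' stops when its training MSER falls below `mser_target` *and* the
#' iterate has stabilized (relative change below `w_tol`), or at
#' `max_iter`. If no column survives the penalty, the single column
#' with the largest row norm before thresholding is kept.
#'
#' @param X a [feature_matrix()] or numeric matrix (samples x features).
#' @param labels per-sample class labels (taken from `X` if absent).
#' @param config a [selection_config()].
#' @return list of class `selection_result`: `weights` (features x
#'   classes), `selected` (integer column indices), `trace` (data frame
#'   with per-iteration loss, penalized objective, LR, MSER, selected
#'   count), `stop_reason` (`"mser_met"` or `"max_iter"`), `sigma`,
#'   `p0`, and the standardization used.
#' @export
run_selection <- function(X, labels = NULL, config = selection_config()) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(labels)) labels <- X$labels
    X <- X$values
  }
  if (is.null(labels)) stop("labels are required")
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (min(table(labels)) < 2) stop("need at least 2 samples per class")
  if (nrow(X) != length(labels)) stop("row count does not match labels")
  sd0 <- sqrt(apply(X, 2, stats::var))
  if (all(sd0 < 1e-12)) stop("all features are constant")

  st <- standardize(X)
  Xs <- st$x
  Y <- one_hot(labels)
  n <- nrow(Xs); p <- ncol(Xs); C <- ncol(Y)

  W <- ridge_solve(Xs, Y, lambda = 1)
  sigma <- if (is.null(config$sigma)) 1 else config$sigma
  fgrad <- function(W) correntropy_loss(W, Xs, Y, sigma)

  lr <- config$lr0
  p0 <- config$p0
  if (is.null(p0)) {
    # 20% of the critical penalty: gradient row norms at W = 0
    G0 <- fgrad(matrix(0, p, C))$gradient
    p0 <- 0.2 * max(sqrt(rowSums(G0^2)))
  }
  penalized <- function(W, f = NULL) {
    if (is.null(f)) f <- fgrad(W)$loss
    f + p0 * sum(sqrt(rowSums(W^2)))
  }

  selected_of <- function(W) {
    idx <- which(sqrt(rowSums(W^2)) > config$select_eps)
    if (length(idx) == 0) which.max(sqrt(rowSums(W^2)))  # fallback: top-1 row
    else idx
  }
  elm_mser <- function(idx) {
    m <- train_elm(Xs[, idx, drop = FALSE], labels,
                   L_nodes = config$elm_nodes, c = config$elm_c,
                   seed = config$seed)
    pr <- predict(m, Xs[, idx, drop = FALSE])
    mser(one_hot(factor(pr$labels, levels = levels(labels))), Y)
  }

  W_prev <- W
  a_im2 <- 0; a_im1 <- 1; a_i <- 1   # alpha_{-1}, alpha_0, alpha_1
  F_curr <- penalized(W)
  trace <- vector("list", config$max_iter)
  stop_reason <- "max_iter"

  for (i in seq_len(config$max_iter)) {
    b <- (a_im2 - 1) / a_im1
    A <- W + b * (W - W_prev)
    step <- backtrack_lr(A, fgrad, lr, p0)
    F_new <- penalized(step$W, step$f)
    if (F_new > F_curr + 1e-12) {
      # momentum overshoot: retake the step from W and restart momentum
      step <- backtrack_lr(W, fgrad, step$lr, p0)
      F_new <- penalized(step$W, step$f)
      a_im2 <- 0; a_im1 <- 1; a_i <- 1
    }
    lr <- step$lr
    relchange <- sqrt(sum((step$W - W)^2)) / max(sqrt(sum(W^2)), 1e-12)
    W_prev <- W
    W <- step$W
    F_curr <- min(F_curr, F_new)

    idx <- selected_of(W)
    ms <- elm_mser(idx)
    trace[[i]] <- data.frame(iter = i, loss = step$f, objective = F_new,
                             lr = lr, mser = ms, n_selected = length(idx))
    if (ms < config$mser_target && relchange < config$w_tol) {
      stop_reason <- "mser_met"
      break
    }
    a_next <- momentum_update(i, a_i, config$momentum_rule)
    a_im2 <- a_im1; a_im1 <- a_i; a_i <- a_next
  }

  idx <- selected_of(W)
  structure(list(weights = W, selected = sort(idx),
                 trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))]),
                 stop_reason = stop_reason, sigma = sigma, p0 = p0,
                 center = st$center, scale = st$scale),
            class = "selection_result")
}

#' Apply a selection result to a feature matrix
#'
#' @param result a `selection_result`.
#' @param X a [feature_matrix()] or numeric matrix with the same
#'   feature columns as the selection input.
#' @return a [feature_matrix()] restricted to the selected columns.
#' @export
apply_selection <- function(result, X) {
  labels <- NULL; src <- "selected"
  if (inherits(X, "feature_matrix")) {
    labels <- X$labels; src <- paste0(X$source, "+selected")
    X <- X$values
  }
  if (ncol(X) != length(result$center))
    stop("feature count does not match the selection result")
  feature_matrix(X[, result$selected, drop = FALSE], labels = labels,
                 source = src)
}
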