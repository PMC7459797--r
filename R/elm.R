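#' Regularized extreme learning machine
#'
#' A single random hidden layer whose input weights and biases are
#' drawn once (uniform on `[-1, 1]`) and never trained; only the output
#' weights are solved, in closed form, from the ridge-regularized
#' least-squares system `beta = (H'H + I/c)^{-1} H'T` (or the
#' equivalent dual form `H'(HH' + I/c)^{-1}T` when the sample count is
#' below the node count). Larger penalty parameters `c` weaken the
#' ridge and fit the training targets more tightly.
#'
#' @param X a [feature_matrix()] or numeric matrix (samples x features).
#' @param labels per-sample class labels (taken from `X` if absent).
#' @param L_nodes hidden-node count (default 1000).
#' @param c positive penalty parameter (default 1).
#' @param activation hidden activation: `"sigmoid"` (default),
#'   `"relu"`, or `"tanh"`.
#' @param seed integer seed for the hidden layer.
#' @return object of class `elm_model` with the input weights `u`,
#'   biases `B`, output weights `beta`, the activation name, penalty,
#'   class levels, input standardization, and seed.
#' @export
train_elm <- function(X, labels = NULL, L_nodes = 1000L, c = 1,
                      activation = c("sigmoid", "relu", "tanh"), seed = 1L) {
  activation <- match.arg(activation)
  if (inherits(X, "feature_matrix")) {
    if (is.null(labels)) labels <- X$labels
    X <- X$values
  }
  if (is.null(labels)) stop("labels are required")
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (L_nodes < 1) stop("L_nodes must be at least 1")
  if (c <= 0) stop("penalty c must be positive")
  if (nrow(X) != length(labels)) stop("row count does not match labels")

  st <- standardize(X)
  n <- nrow(X); p <- ncol(X)
  hw <- with_seed(seed, list(
    u = matrix(stats::runif(p * L_nodes, -1, 1), p, L_nodes),
    B = stats::runif(L_nodes, -1, 1)))
  H <- elm_hidden(st$x, hw$u, hw$B, activation)
  T_ <- one_hot(labels)
  beta <- if (n >= L_nodes) {
    solve(crossprod(H) + diag(1 / c, L_nodes), crossprod(H, T_))
  } else {
    crossprod(H, solve(tcrossprod(H) + diag(1 / c, n), T_))
  }
  structure(list(u = hw$u, B = hw$B, beta = beta, activation = activation,
                 c = c, L_nodes = as.integer(L_nodes),
                 classes = levels(labels), center = st$center,
                 scale = st$scale, seed = as.integer(seed)),
            class = "elm_model")
}

elm_hidden <- function(Xs, u, B, activation) {
  Z <- sweep(Xs %*% u, 2, B, "+")
  switch(activation,
         sigmoid = sigmoid(Z),
         relu = pmax(Z, 0),
         tanh = tanh(Z))
}

#' Predict classes with a trained ELM
#'
#' Scores are the hidden activations times the output weights; the
#' predicted label is the argmax, with ties broken in favor of the
#' lowest class index.
#'
#' @param object an `elm_model`.
#' @param newdata a [feature_matrix()] or numeric matrix whose feature
#'   dimension matches the training data.
#' @param ... unused.
#' @return list with `labels` (character vector) and `scores`
#'   (samples x classes matrix).
#' @export
predict.elm_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$center))
    stop("feature dimension ", ncol(newdata), " does not match model (",
         length(object$center), ")")
  Xs <- standardize(newdata, object$center, object$scale)$x
  H <- elm_hidden(Xs, object$u, object$B, object$activation)
  scores <- H %*% object$beta
  colnames(scores) <- object$classes
  # which.max returns the first maximum: lowest class index on ties
  labels <- object$classes[apply(scores, 1, which.max)]
  list(labels = labels, scores = scores)
}

#' @export
print.elm_model <- function(x, ...) {
  cat("<elm_model> ", length(x$center), " features -> ", x$L_nodes,
      " hidden (", x$activation, ") -> ", length(x$classes),
      " classes, c = ", x$c, "\n", sep = "")
  invisible(x)
}
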