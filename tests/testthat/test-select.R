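test_that("correntropy loss is exact at zero residual and quadratic in the wide limit", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4)
  W <- matrix(rnorm(8), 4, 2)
  Y <- X %*% W
  at <- correntropy_loss(W, X, Y, sigma = 0.7)
  expect_equal(at$loss, 0)
  expect_true(all(at$gradient == 0))
  # sigma -> Inf: 2 sigma^2 * loss approaches the plain SSE
  W2 <- W + 0.3
  R <- Y - X %*% W2
  big <- correntropy_loss(W2, X, Y, sigma = 1e6)
  expect_equal(2 * 1e12 * big$loss, sum(R^2), tolerance = 1e-4)
  expect_error(correntropy_loss(W, X, Y, sigma = 0), "positive")
})

test_that("correntropy gradient matches central finite differences", {
  set.seed(2)
  X <- matrix(rnorm(30), 6, 5)
  Y <- matrix(rnorm(12), 6, 2)
  W <- matrix(rnorm(10), 5, 2)
  sigma <- 0.8
  an <- correntropy_loss(W, X, Y, sigma)$gradient
  h <- 1e-6
  num <- matrix(0, 5, 2)
  for (i in 1:5) for (j in 1:2) {
    Wp <- W; Wp[i, j] <- W[i, j] + h
    Wm <- W; Wm[i, j] <- W[i, j] - h
    num[i, j] <- (correntropy_loss(Wp, X, Y, sigma)$loss -
                  correntropy_loss(Wm, X, Y, sigma)$loss) / (2 * h)
  }
  expect_equal(an, num, tolerance = 1e-5)
})

test_that("group_prox matches the numeric minimizer of its objective", {
  V <- rbind(c(3, 4), c(0.3, 0.4), c(-1, 2))
  W <- group_prox(V, t = 1)
  expect_equal(W[1, ], c(2.4, 3.2))          # (1 - 1/5) * (3, 4)
  expect_equal(W[2, ], c(0, 0))              # ||row|| = 0.5 <= t
  # numeric minimization of 0.5||w - v||^2 + t ||w||_2 for the smooth
  # rows; the zeroed row is checked against perturbations around 0
  for (r in c(1, 3)) {
    ob <- function(w) 0.5 * sum((w - V[r, ])^2) + 1 * sqrt(sum(w^2))
    opt <- optim(V[r, ] * 0.5, ob, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000))
    expect_equal(W[r, ], opt$par, tolerance = 1e-5)
  }
  ob2 <- function(w) 0.5 * sum((w - V[2, ])^2) + 1 * sqrt(sum(w^2))
  set.seed(8)
  for (k in 1:50) expect_gte(ob2(rnorm(2) * 0.2), ob2(c(0, 0)))
  # exact row-norm identity and edge cases
  set.seed(3)
  V2 <- matrix(rnorm(40), 10, 4)
  W2 <- group_prox(V2, t = 0.7)
  expect_equal(sqrt(rowSums(W2^2)),
               pmax(0, sqrt(rowSums(V2^2)) - 0.7), tolerance = 1e-12)
  expect_identical(group_prox(V2, 0), V2)
})

test_that("backtracking accepts the Lipschitz-satisfying first candidate", {
  set.seed(4)
  X <- matrix(rnorm(60), 12, 5)
  Y <- matrix(rnorm(24), 12, 2)
  quad <- function(W) list(loss = 0.5 * sum((X %*% W - Y)^2),
                           gradient = crossprod(X, X %*% W - Y))
  L <- norm(crossprod(X), "2")
  A <- matrix(0, 5, 2)
  step <- backtrack_lr(A, quad, lr_prev = L * 1.01, p0 = 0.1)
  expect_equal(step$lr, L * 1.01)
  expect_false(step$capped)
  # tiny lr on a steep loss: a larger multiple is chosen and the
  # majorization inequality holds at the returned point
  step2 <- backtrack_lr(A, quad, lr_prev = L / 8, p0 = 0.1)
  expect_gt(step2$lr, L / 8)
  fa <- quad(A); D <- step2$W - A
  expect_lte(quad(step2$W)$loss,
             fa$loss + sum(fa$gradient * D) + step2$lr / 2 * sum(D^2) + 1e-10)
  # cap contract
  expect_warning(cap <- backtrack_lr(A, quad, lr_prev = L * 1e-4, p0 = 0.1),
                 "cap")
  expect_equal(cap$lr, L * 1e-4 * 32)
  expect_true(cap$capped)
})

test_that("momentum updates follow both rules", {
  expect_equal(momentum_update(1, 1, "paper_literal"), (1 + sqrt(5)) / 2)
  expect_equal(momentum_update(2, 1, "paper_literal"), (1 + sqrt(17)) / 2)
  # iterate the fista recurrence from 1 as an oracle
  a <- 1
  for (k in 1:2) a <- (1 + sqrt(1 + 4 * a^2)) / 2
  expect_equal(momentum_update(1, 1, "fista_standard"), (1 + sqrt(5)) / 2)
  expect_equal(momentum_update(2, momentum_update(1, 1, "fista_standard"),
                               "fista_standard"), a)
})

test_that("mser is the elementwise mean squared difference", {
  A <- matrix(1:6 / 6, 2, 3)
  expect_equal(mser(A, A), 0)
  onehot <- diag(4)
  expect_equal(mser(onehot, matrix(0, 4, 4)), 1 / 4)
  set.seed(5)
  P <- matrix(rnorm(12), 3, 4); O <- matrix(rnorm(12), 3, 4)
  expect_equal(mser(P, O), sum((P - O)^2) / 12)
  expect_error(mser(P, matrix(0, 2, 2)), "shape")
})

test_that("run_selection recovers informative columns and honors p0 extremes", {
  ds <- generate_feature_dataset(n_samples = 80, n_features = 120,
                                 n_informative = 6, delta = 5, seed = 9)
  res <- suppressWarnings(run_selection(ds$features,
                                        config = selection_config(seed = 9)))
  expect_gte(length(intersect(res$selected, ds$informative)), 5)
  expect_lte(length(res$selected), 12)
  expect_true(res$stop_reason %in% c("mser_met", "max_iter"))
  expect_lte(nrow(res$trace), 1000)
  # p0 = 0: no sparsity, everything stays selected
  res0 <- suppressWarnings(run_selection(ds$features,
    config = selection_config(p0 = 0, max_iter = 5, mser_target = 1e-9, seed = 9)))
  expect_identical(res0$selected, seq_len(120))
  # huge p0: everything zeroed, top-1 fallback keeps a single column
  resh <- suppressWarnings(run_selection(ds$features,
    config = selection_config(p0 = 1e9, max_iter = 3, seed = 9)))
  expect_identical(length(resh$selected), 1L)
})

test_that("run_selection is deterministic and its objective non-increasing", {
  ds <- generate_feature_dataset(n_samples = 40, n_features = 60,
                                 n_informative = 4, delta = 4, seed = 21)
  r1 <- suppressWarnings(run_selection(ds$features,
                                       config = selection_config(seed = 2)))
  r2 <- suppressWarnings(run_selection(ds$features,
                                       config = selection_config(seed = 2)))
  expect_identical(r1$weights, r2$weights)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace$objective) <= 1e-9))
})

test_that("quadratic limit with p0 = 0 converges to the least-squares fit", {
  set.seed(6)
  X <- matrix(rnorm(100), 20, 5)
  labels <- factor(rep(c("a", "b"), each = 10))
  sigma <- 1e6
  # inverse step sized to the quadratic Lipschitz constant of the
  # wide-kernel loss so progress is not throttled
  res <- suppressWarnings(run_selection(X, labels,
    selection_config(p0 = 0, sigma = sigma, lr0 = norm(crossprod(X), "2") / sigma^2,
                     mser_target = 1e-6, w_tol = 1e-8, max_iter = 3000, seed = 1)))
  Xs <- sweep(sweep(X, 2, res$center), 2, res$scale, "/")
  Y <- cbind(a = as.numeric(labels == "a"), b = as.numeric(labels == "b"))
  W_ls <- solve(crossprod(Xs), crossprod(Xs, Y))
  expect_equal(res$weights, W_ls, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("run_selection validates degenerate inputs", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(run_selection(X, factor(rep("a", 10))), "2 classes")
  expect_error(run_selection(X, factor(c(rep("a", 9), "b"))), "per class")
  expect_error(run_selection(matrix(1, 10, 4),
                             factor(rep(c("a", "b"), 5))), "constant")
})
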