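# Shared fixtures, all generated in code.

# Deterministic random image in [0, 1].
rand_image <- function(n, m = n, seed = 1) {
  set.seed(seed)
  matrix(runif(n * m), n, m)
}

# Two-intensity half/half image.
two_level_image <- function(n = 8, lo = 0.1, hi = 0.9) {
  img <- matrix(lo, n, n)
  img[, (n %/% 2 + 1):n] <- hi
  img
}

# Naive O(N^4) orthonormal DCT-II, written directly from the basis
# definition as an independent transform oracle.
naive_dct2 <- function(x) {
  N <- nrow(x); M <- ncol(x)
  a <- function(k, n) if (k == 0) sqrt(1 / n) else sqrt(2 / n)
  out <- matrix(0, N, M)
  for (k in 0:(N - 1)) for (l in 0:(M - 1)) {
    s <- 0
    for (i in 0:(N - 1)) for (j in 0:(M - 1)) {
      s <- s + x[i + 1, j + 1] *
        cos(pi * (2 * i + 1) * k / (2 * N)) *
        cos(pi * (2 * j + 1) * l / (2 * M))
    }
    out[k + 1, l + 1] <- a(k, N) * a(l, M) * s
  }
  out
}

# Finite-difference gradient oracle mirroring the documented stencil.
naive_gradient <- function(img) {
  n <- nrow(img); m <- ncol(img)
  g <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    gx <- if (j == 1) img[i, 2] - img[i, 1]
          else if (j == m) img[i, m] - img[i, m - 1]
          else (img[i, j + 1] - img[i, j - 1]) / 2
    gy <- if (i == 1) img[2, j] - img[1, j]
          else if (i == n) img[n, j] - img[n - 1, j]
          else (img[i + 1, j] - img[i - 1, j]) / 2
    g[i, j] <- sqrt(gx^2 + gy^2)
  }
  g
}

# Small labeled Gaussian-blob dataset, linearly separable.
blob_data <- function(n_per_class = 20, p = 5, gap = 4, classes = c("a", "b"),
                      seed = 1) {
  set.seed(seed)
  C <- length(classes)
  X <- do.call(rbind, lapply(seq_len(C), function(k) {
    mu <- rep(0, p); mu[k] <- gap
    matrix(rnorm(n_per_class * p), n_per_class, p) +
      matrix(mu, n_per_class, p, byrow = TRUE)
  }))
  list(X = X, labels = factor(rep(classes, each = n_per_class)))
}
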