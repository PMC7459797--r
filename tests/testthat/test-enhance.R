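test_that("kmeans_split partitions two-mode data exactly", {
  img <- two_level_image(8, 0.1, 0.9)
  cs <- kmeans_split(img, K = 2)
  expect_equal(cs$centroids, c(0.1, 0.9))
  expect_equal(cs$sse, 0)
  expect_true(all(cs$assignment[img == 0.1] == 1))
  expect_true(all(cs$assignment[img == 0.9] == 2))
})

test_that("kmeans_split rejects degenerate input", {
  expect_error(kmeans_split(matrix(0.5, 4, 4), K = 2), "degenerate")
  expect_error(kmeans_split(two_level_image(4), K = 3), "degenerate")
})

test_that("kmeans_split finds the optimum confirmed by brute force", {
  # six intensities with a clear two-group structure
  v <- c(0, 0, 1, 9, 9, 10) / 10
  img <- matrix(c(v, v), 2, 6, byrow = TRUE)
  cs <- kmeans_split(img, K = 2)
  expect_equal(cs$centroids, c(1 / 30, 28 / 30), tolerance = 1e-12)
  expect_equal(cs$sse, 2 * (2 / 3 + 2 / 3) / 100, tolerance = 1e-12)
  # brute force over all 2^12 pixel 2-partitions confirms the optimum
  vals <- as.vector(img)
  best <- Inf
  for (mask in 1:(2^12 - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:11)))
    a <- vals[grp]; b <- vals[!grp]
    sse <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    best <- min(best, sse)
  }
  expect_equal(cs$sse, best, tolerance = 1e-12)
})

test_that("kmeans_split sse does not exceed a random assignment", {
  img <- rand_image(16, seed = 3)
  cs <- kmeans_split(img, K = 2)
  set.seed(99)
  for (rep in 1:5) {
    assign <- sample(1:2, length(img), replace = TRUE)
    if (length(unique(assign)) < 2) next
    sse_rand <- sum(tapply(as.vector(img), assign,
                           function(v) sum((v - mean(v))^2)))
    expect_lte(cs$sse, sse_rand)
  }
})

test_that("gradient magnitude matches the stencil oracle and flat/ramp cases", {
  expect_true(all(gradient_magnitude(matrix(0.4, 6, 6))$gradient == 0))
  # linear ramp: constant interior derivative equal to the slope
  m <- 9
  ramp <- matrix(rep(seq(0, 1, length.out = m), each = m), m, m, byrow = FALSE)
  g <- gradient_magnitude(t(ramp))$gradient
  expect_equal(g[2:(m - 1), 2:(m - 1)],
               matrix(1 / (m - 1), m - 2, m - 2), tolerance = 1e-12)
  img <- rand_image(8, seed = 7)
  expect_equal(gradient_magnitude(img)$gradient, naive_gradient(img),
               tolerance = 1e-12)
})

test_that("texture_mask thresholds the rescaled gradient", {
  em <- structure(list(gradient = matrix(c(0, 0.5, 0.6, 1.0), 2, 2),
                       mask = NULL, threshold = NA_real_),
                  class = "edge_map")
  tm <- texture_mask(em, threshold = 0.55)
  expect_identical(as.vector(tm$mask), c(FALSE, FALSE, TRUE, TRUE))
  # flat image: empty mask
  flat <- texture_mask(gradient_magnitude(matrix(0.3, 5, 5)))
  expect_false(any(flat$mask))
  # vertical stripes of period 2: one-sided borders see the full step,
  # interior central differences see zero horizontally; enumerating the
  # stencil puts the maximum on the left/right border columns
  stripes <- matrix(rep(c(0, 1), length.out = 6), 6, 6, byrow = TRUE)
  sm <- texture_mask(gradient_magnitude(stripes), threshold = 0.55)
  expect_true(all(sm$mask[, c(1, 6)]))
  expect_false(any(sm$mask[2:5, 3:4]))
  # polarity flip selects the complement
  tm_below <- texture_mask(em, threshold = 0.55, polarity = "below")
  expect_identical(tm_below$mask, !tm$mask)
})

test_that("he_equalize follows the closed-form CDF cases", {
  # texture pixels uniformly covering [alpha, beta]: transfer is the
  # linear stretch of [alpha, beta] up to the top grey level
  lv <- seq(64, 191) / 255
  img <- matrix(rep(lv, 2), nrow = 16)
  edge <- list(mask = matrix(TRUE, nrow(img), ncol(img)))
  out <- he_equalize(img, edge = edge)
  alpha <- 64
  expected <- (alpha + (255 - alpha) * (round(img * 255) - alpha + 1) / 128)
  expect_equal(out, pmin(expected / 255, 1), tolerance = 2e-3)
  # all texture mass at one level: everything at or above jumps to 1
  img2 <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2)
  edge2 <- list(mask = matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2))
  out2 <- he_equalize(img2, edge = edge2)
  expect_equal(out2[img2 >= 0.4], rep(1, 3))
  expect_equal(out2[1, 1], round(0.4 * 255) / 255)  # below alpha -> alpha
  # empty texture set: identity
  img3 <- rand_image(6, seed = 2)
  out3 <- he_equalize(img3, edge = list(mask = matrix(FALSE, 6, 6)))
  expect_identical(out3, img3)
})

test_that("equalization transfer is monotone on random inputs", {
  for (seed in 1:5) {
    img <- rand_image(12, seed = seed)
    edge <- texture_mask(gradient_magnitude(img), threshold = 0.3)
    out <- he_equalize(img, edge = edge)
    lev <- round(img * 255)
    ord <- order(lev)
    expect_true(all(diff(out[ord]) >= -1e-12))
  }
})

test_that("dct2/idct2 are orthonormal mutual inverses", {
  plan <- dct_plan(16)
  expect_equal(plan$basis %*% t(plan$basis), diag(16), tolerance = 1e-10)
  img <- rand_image(16, seed = 5)
  expect_lt(max(abs(idct2(dct2(img, plan), plan) - img)), 1e-8)
  # constant image: single DC coefficient c * M
  cimg <- matrix(0.3, 8, 8)
  co <- dct2(cimg, dct_plan(8))
  expect_equal(co[1, 1], 0.3 * 8, tolerance = 1e-12)
  expect_lt(max(abs(co[-1])), 1e-12)
  # non-square images round-trip through edge padding
  rect <- rand_image(6, 10, seed = 11)
  plan2 <- dct_plan(10)
  expect_lt(max(abs(idct2(dct2(rect, plan2), plan2) - rect)), 1e-8)
  # random sizes up to 64
  for (n in c(31, 64)) {
    p <- dct_plan(n)
    x <- rand_image(n, seed = n)
    expect_lt(max(abs(idct2(dct2(x, p), p) - x)), 1e-8)
  }
})

test_that("dct2 matches the independent naive DCT-II oracle", {
  img <- rand_image(8, seed = 9)
  expect_equal(dct2(img, dct_plan(8)), naive_dct2(img),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("dct_refine is an identity at r = 1 and boosts contrast below", {
  img <- rand_image(12, seed = 4)
  expect_lt(max(abs(dct_refine(img, dct_plan(12, alpha_root = 1)) - img)), 1e-8)
  cimg <- matrix(0.6, 10, 10)
  expect_lt(max(abs(dct_refine(cimg, dct_plan(10, alpha_root = 0.7)) - cimg)), 1e-8)
  step <- two_level_image(16, 0.3, 0.6)
  out <- dct_refine(step, dct_plan(16, alpha_root = 0.98))
  rms <- function(x) sqrt(mean((x - mean(x))^2))
  expect_gte(rms(out), rms(step))
})

test_that("enhance is deterministic, shape/range preserving, widens range", {
  # constant background with two blobs
  img <- matrix(0.45, 48, 48)
  img[10:18, 10:18] <- 0.55
  img[30:40, 28:38] <- 0.35
  set.seed(123)  # must not influence the result
  out1 <- enhance(img, seed = 7)
  out2 <- enhance(img, seed = 7)
  expect_identical(out1, out2)
  expect_identical(dim(out1), dim(img))
  expect_true(min(out1) >= 0 && max(out1) <= 1)
  expect_gte(diff(range(out1)), diff(range(img)))
  # enhancement is not idempotent by design
  expect_false(isTRUE(all.equal(enhance(out1, seed = 7), out1)))
})
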