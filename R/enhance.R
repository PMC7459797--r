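#' Hybrid linear contrast enhancement
#'
#' The enhancement stage improves the shallow contrast typical of T1 and
#' T1CE slices before feature extraction. It proceeds in three steps:
#' the slice is split into intensity clusters by 1-D K-means; each
#' cluster is histogram-equalized using only "texture" pixels (pixels
#' whose gradient magnitude exceeds a threshold) to build the transfer
#' function; the merged image is refined in the DCT domain by
#' alpha-rooting, which mildly amplifies the relative AC energy and
#' hence local contrast.
#'
#' @name enhance-module
NULL

#' Split an image into intensity clusters with 1-D K-means
#'
#' Lloyd's algorithm on scalar pixel intensities. Initial centroids are
#' placed deterministically at evenly spaced quantiles of the intensity
#' distribution (the 25th/75th percentiles for `K = 2`), so the split is
#' reproducible without random restarts.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param K number of clusters (default 2: the low/high intensity split).
#' @param seed optional integer; only used for random restarts when the
#'   deterministic quantile initialization fails to produce `K` distinct
#'   centers.
#' @return a list of class `cluster_split` with elements `assignment`
#'   (integer matrix of cluster ids `1..K`), `centroids` (ascending mean
#'   intensities), and `sse` (total within-cluster sum of squares).
#' @export
kmeans_split <- function(img, K = 2L, seed = 1L) {
  as_gray_image(img)
  if (K < 2) stop("K must be at least 2")
  v <- as.vector(img)
  if (length(unique(v)) < K)
    stop("degenerate input: fewer distinct intensities (",
         length(unique(v)), ") than K = ", K)
  probs <- (seq_len(K) - 0.5) / K          # K=2 -> 25th/75th percentiles
  centers <- unname(stats::quantile(v, probs))
  if (anyDuplicated(centers)) {
    # quantile init collapsed; fall back to seeded distinct values
    centers <- with_seed(seed, sort(sample(unique(v), K)))
  }
  km <- stats::kmeans(v, centers = matrix(centers, ncol = 1),
                      iter.max = 300L, algorithm = "Lloyd")
  ord <- order(km$centers[, 1])
  relabel <- match(seq_len(K), ord)
  assignment <- matrix(relabel[km$cluster], nrow(img), ncol(img))
  structure(list(assignment = assignment,
                 centroids = as.vector(km$centers[ord, 1]),
                 sse = km$tot.withinss),
            class = "cluster_split")
}

#' Gradient magnitude of an image
#'
#' Central differences in the interior, one-sided differences at the
#' borders, unit pixel spacing. The magnitude is
#' `sqrt(Gx^2 + Gy^2)`.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @return list of class `edge_map` with element `gradient` (matrix,
#'   same shape, non-negative).
#' @export
gradient_magnitude <- function(img) {
  as_gray_image(img)
  n <- nrow(img); m <- ncol(img)
  gx <- matrix(0, n, m); gy <- matrix(0, n, m)
  # column direction (x)
  if (m >= 3) gx[, 2:(m - 1)] <- (img[, 3:m] - img[, 1:(m - 2)]) / 2
  gx[, 1] <- img[, 2] - img[, 1]
  gx[, m] <- img[, m] - img[, m - 1]
  # row direction (y)
  if (n >= 3) gy[2:(n - 1), ] <- (img[3:n, ] - img[1:(n - 2), ]) / 2
  gy[1, ] <- img[2, ] - img[1, ]
  gy[n, ] <- img[n, ] - img[n - 1, ]
  structure(list(gradient = sqrt(gx^2 + gy^2), mask = NULL, threshold = NA_real_),
            class = "edge_map")
}

#' Threshold a gradient map into a texture mask
#'
#' The gradient is rescaled to `[0, 1]` by its own maximum before
#' thresholding, so the default `T = 0.55` is scale-free. Texture
#' pixels are those with rescaled gradient at or above the threshold;
#' `polarity = "below"` gives the complementary reading (gradient below
#' the threshold).
#'
#' @param edge an `edge_map` from [gradient_magnitude()].
#' @param threshold scalar in `[0, 1]`, default 0.55.
#' @param polarity `"above"` (default) or `"below"`.
#' @return the `edge_map` with `mask` (logical matrix) and `threshold`
#'   filled in. A flat image yields an empty mask.
#' @export
texture_mask <- function(edge, threshold = 0.55, polarity = c("above", "below")) {
  polarity <- match.arg(polarity)
  g <- edge$gradient
  mx <- max(g)
  if (mx > 0) g <- g / mx
  mask <- if (mx == 0) matrix(FALSE, nrow(g), ncol(g))
          else if (polarity == "above") g >= threshold
          else g < threshold
  edge$mask <- mask
  edge$threshold <- threshold
  edge
}

#' Histogram-equalize one cluster using texture pixels
#'
#' Builds a transfer function from the histogram of texture pixels
#' (mask intersected with the cluster) over 256 grey levels. Writing
#' `alpha`/`beta` for the minimum/maximum texture grey level, the
#' cumulative distribution over `[alpha, beta]` drives the transfer
#' `F(i) = alpha + (255 - alpha) * CDF(i)`, which stretches the texture
#' range up to the top grey level while anchoring its minimum. The
#' transfer is applied to every pixel of the cluster; levels below
#' `alpha` map to `alpha` and levels above `beta` to the top transfer
#' value. An empty texture set leaves the cluster unchanged.
#'
#' @param img numeric matrix in `[0, 1]` (the full image).
#' @param cluster_mask logical matrix selecting the cluster's pixels;
#'   `NULL` means the whole image.
#' @param edge an `edge_map` with a filled `mask` (see [texture_mask()]).
#' @return the image with the cluster's pixels replaced by their
#'   equalized values, still in `[0, 1]`.
#' @export
he_equalize <- function(img, cluster_mask = NULL, edge) {
  as_gray_image(img)
  if (is.null(cluster_mask)) cluster_mask <- matrix(TRUE, nrow(img), ncol(img))
  if (is.null(edge$mask)) stop("edge map has no mask; call texture_mask() first")
  L <- GREY_LEVELS
  lev <- matrix(as.integer(floor(img * (L - 1) + 0.5)), nrow(img))
  tex <- edge$mask & cluster_mask
  if (!any(tex)) return(img)
  tl <- lev[tex]
  alpha <- min(tl); beta <- max(tl)
  counts <- tabulate(tl - alpha + 1L, nbins = beta - alpha + 1L)
  cdf <- cumsum(counts) / sum(counts)
  transfer_band <- alpha + (L - 1 - alpha) * cdf       # levels alpha..beta
  transfer <- c(rep(alpha, alpha),                     # levels 0..alpha-1
                transfer_band,
                rep(transfer_band[length(transfer_band)], L - 1 - beta))
  out <- img
  out[cluster_mask] <- transfer[lev[cluster_mask] + 1L] / (L - 1)
  pmin(pmax(out, 0), 1)
}

#' Build an orthonormal DCT-II plan
#'
#' The basis is the real orthogonal matrix with first row `1/sqrt(M)`
#' and rows `sqrt(2/M) * cos(pi * (2y + 1) * x / (2M))` for
#' `x = 1..M-1`, so that `C %*% t(C)` is the identity.
#'
#' @param M side length of the (square) working tile.
#' @param alpha_root exponent in `(0, 1]` for coefficient-magnitude
#'   modification; `1` leaves coefficients untouched.
#' @return list of class `dct_plan` with `basis` and `alpha_root`.
#' @export
dct_plan <- function(M, alpha_root = 0.98) {
  if (M < 1) stop("M must be positive")
  if (alpha_root <= 0 || alpha_root > 1) stop("alpha_root must be in (0, 1]")
  x <- 0:(M - 1)
  C <- sqrt(2 / M) * cos(pi * outer(x, 2 * x + 1) / (2 * M))
  C[1, ] <- 1 / sqrt(M)
  structure(list(basis = C, alpha_root = alpha_root, M = M), class = "dct_plan")
}

#' Forward 2D DCT-II
#'
#' Computes `C %*% X %*% t(C)` with the plan's orthonormal basis.
#' Non-square images are padded to the larger dimension with edge
#' replication first; [idct2()] crops back.
#'
#' @param img numeric matrix.
#' @param plan a `dct_plan` whose size equals `max(dim(img))`.
#' @return coefficient matrix of the padded tile, with the original
#'   dimensions stored in attribute `orig_dim`.
#' @export
dct2 <- function(img, plan) {
  d <- dim(img)
  M <- plan$M
  if (max(d) != M) stop("plan size ", M, " does not match image ", d[1], "x", d[2])
  if (d[1] < M) img <- rbind(img, img[rep(d[1], M - d[1]), , drop = FALSE])
  if (d[2] < M) img <- cbind(img, img[, rep(d[2], M - d[2]), drop = FALSE])
  co <- plan$basis %*% img %*% t(plan$basis)
  attr(co, "orig_dim") <- d
  co
}

#' Inverse 2D DCT-II
#'
#' @param coeffs coefficient matrix from [dct2()].
#' @param plan the same `dct_plan`.
#' @return reconstructed image, cropped to the original dimensions.
#' @export
idct2 <- function(coeffs, plan) {
  d <- attr(coeffs, "orig_dim")
  img <- t(plan$basis) %*% coeffs %*% plan$basis
  if (!is.null(d)) img <- img[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  img
}

#' DCT-domain local contrast refinement by alpha-rooting
#'
#' Keeps the DC coefficient and replaces every AC coefficient `c` by
#' `c * (|c| / |DC|)^(r - 1)` with `r = plan$alpha_root` (the classic
#' DC-normalized alpha-rooting). Since `|c| <= |DC|` for non-negative
#' images, every AC coefficient is amplified when `r < 1`, raising
#' local contrast; `r = 1` is an exact identity (the forward/inverse
#' round trip). Output is clipped to `[0, 1]`.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param plan a `dct_plan` sized `max(dim(img))`.
#' @return refined image, same shape, in `[0, 1]`.
#' @export
dct_refine <- function(img, plan) {
  co <- dct2(img, plan)
  r <- plan$alpha_root
  dc <- abs(co[1, 1])
  if (r != 1 && dc > 0) {
    keep <- co[1, 1]
    co <- co * (pmax(abs(co), 1e-300) / dc)^(r - 1)
    co[1, 1] <- keep
  }
  out <- idct2(co, plan)
  pmin(pmax(out, 0), 1)
}

#' Full hybrid contrast enhancement
#'
#' Runs the three-step enhancement: K-means intensity split, per-cluster
#' texture histogram equalization with a shared edge mask, merge by
#' cluster assignment, and DCT alpha-rooting refinement. Deterministic
#' for a given seed. Not idempotent: applying it twice generally does
#' not reproduce the single-pass output.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param K number of K-means clusters (default 2).
#' @param edge_threshold texture-mask threshold on the rescaled
#'   gradient (default 0.55).
#' @param alpha_root DCT refinement exponent in `(0, 1]` (default 0.98).
#' @param edge_polarity `"above"` (texture = high gradient, default) or
#'   `"below"`.
#' @param seed integer seed for the K-means fallback initialization.
#' @return enhanced image, same shape, values in `[0, 1]`.
#' @export
enhance <- function(img, K = 2L, edge_threshold = 0.55, alpha_root = 0.98,
                    edge_polarity = "above", seed = 1L) {
  split <- kmeans_split(img, K = K, seed = seed)
  edge <- texture_mask(gradient_magnitude(img), threshold = edge_threshold,
                       polarity = edge_polarity)
  out <- img
  for (k in seq_len(K)) {
    cl <- split$assignment == k
    eq <- he_equalize(img, cluster_mask = cl, edge = edge)
    out[cl] <- eq[cl]
  }
  plan <- dct_plan(max(dim(img)), alpha_root = alpha_root)
  dct_refine(out, plan)
}
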