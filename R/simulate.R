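#' Synthetic data: brain phantoms and feature tables
#'
#' The simulators make every pipeline stage testable without external
#' data. Phantoms caricature the four MRI acquisition classes: the
#' tumor blob and the ventricles change appearance with the modality
#' while the surrounding "brain" tissue stays similar, so the 4-class
#' task is learnable but T2 and FLAIR deliberately overlap (both show a
#' hyper-intense tumor and differ mainly in ventricle/fluid signal).
#'
#' @name simulate-module
NULL

MODALITY_CLASSES <- c("T1", "T1CE", "T2", "FLAIR")

#' Specify a modality phantom
#'
#' @param class one of `"T1"`, `"T1CE"`, `"T2"`, `"FLAIR"`.
#' @param size image side length in pixels (default 256, minimum 64).
#' @param brain_center,brain_axes ellipse center and semi-axes as
#'   fractions of `size`.
#' @param tumor_center tumor center as fractions of `size`, or `NULL`
#'   to draw one (seeded) inside the brain.
#' @param tumor_radius tumor radius as a fraction of `size`.
#' @param noise_sd Gaussian pixel-noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(class, size = 256L,
                         brain_center = c(0.5, 0.5),
                         brain_axes = c(0.38, 0.32),
                         tumor_center = NULL, tumor_radius = 0.08,
                         noise_sd = 0.05, seed = 1L) {
  class <- match.arg(class, MODALITY_CLASSES)
  if (size < 64) stop("size must be at least 64")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(class = class, size = as.integer(size),
                 brain_center = brain_center, brain_axes = brain_axes,
                 tumor_center = tumor_center, tumor_radius = tumor_radius,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Per-class intensity profile of tumor and ventricles.
# T1: hypo-intense, low-contrast blob. T1CE: bright enhancing rim with
# dark core. T2: hyper-intense blob, bright fluid. FLAIR: hyper-intense
# blob with suppressed (dark) ventricles.
modality_profile <- function(class) {
  switch(class,
         T1    = list(tumor_core = 0.32, tumor_rim = 0.32, ventricle = 0.18),
         T1CE  = list(tumor_core = 0.25, tumor_rim = 0.90, ventricle = 0.18),
         T2    = list(tumor_core = 0.82, tumor_rim = 0.82, ventricle = 0.85),
         FLAIR = list(tumor_core = 0.78, tumor_rim = 0.78, ventricle = 0.08))
}

#' Generate one modality phantom
#'
#' Background 0; the brain ellipse sits at mid-grey with a smooth
#' low-frequency texture; two small ventricle ellipses near the center
#' and the tumor blob are rendered per the class profile (soft edges);
#' Gaussian noise is added and the result clipped to `[0, 1]`.
#' Deterministic given the spec (seed included). Errors if the tumor
#' is not inside the brain ellipse.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (size x size matrix in `[0, 1]`) and
#'   `label` (the class).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  s <- spec$size
  prof <- modality_profile(spec$class)
  yx <- seq_len(s) / s
  Yg <- matrix(yx, s, s)           # row coordinate
  Xg <- matrix(yx, s, s, byrow = TRUE)

  be <- ((Yg - spec$brain_center[1]) / spec$brain_axes[1])^2 +
        ((Xg - spec$brain_center[2]) / spec$brain_axes[2])^2
  brain <- softstep(1 - be, 0.02)

  tc <- spec$tumor_center
  if (is.null(tc)) {
    tc <- with_seed(spec$seed, {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0.05, 0.55)
      spec$brain_center + c(rad * spec$brain_axes[1] * sin(ang),
                            rad * spec$brain_axes[2] * cos(ang))
    })
  }
  # reject a tumor whose disc pokes outside the brain ellipse
  margin <- ((tc[1] - spec$brain_center[1]) / (spec$brain_axes[1] - spec$tumor_radius))^2 +
            ((tc[2] - spec$brain_center[2]) / (spec$brain_axes[2] - spec$tumor_radius))^2
  if (!is.finite(margin) || margin >= 1) stop("tumor lies outside the brain ellipse")

  img <- 0.45 * brain +
    0.04 * brain * (sin(14 * pi * Xg) * cos(10 * pi * Yg)) +
    0.03 * brain * cos(6 * pi * (Xg + Yg))

  for (off in c(-0.055, 0.055)) {
    ve <- ((Yg - spec$brain_center[1]) / 0.10)^2 +
          ((Xg - (spec$brain_center[2] + off)) / 0.035)^2
    vmask <- softstep(1 - ve, 0.05)
    img <- img * (1 - vmask) + prof$ventricle * vmask
  }

  td <- sqrt((Yg - tc[1])^2 + (Xg - tc[2])^2)
  core <- softstep(0.72 * spec$tumor_radius - td, 0.01)
  blob <- softstep(spec$tumor_radius - td, 0.01)
  rim <- pmax(blob - core, 0)
  img <- img * (1 - blob) + prof$tumor_core * core + prof$tumor_rim * rim

  if (spec$noise_sd > 0)
    img <- img + with_seed(sub_seed(spec$seed, 7L),
                           matrix(stats::rnorm(s * s, 0, spec$noise_sd), s, s))
  list(image = pmin(pmax(img, 0), 1), label = spec$class)
}

# Smooth unit step: 0 below -w, 1 above +w.
softstep <- function(x, w) pmin(pmax((x / w + 1) / 2, 0), 1)

#' Generate a balanced batch of phantoms
#'
#' Tumor position and radius vary per sample (seeded); each class gets
#' `n_per_class` phantoms.
#'
#' @param n_per_class phantoms per modality class (default 10).
#' @param size image side length (default 256).
#' @param noise_sd pixel-noise standard deviation (default 0.05).
#' @param seed integer seed.
#' @return list with `images` (list of matrices) and `labels`
#'   (character vector).
#' @export
generate_phantom_batch <- function(n_per_class = 10L, size = 256L,
                                   noise_sd = 0.05, seed = 1L) {
  images <- list(); labels <- character(0)
  k <- 0L
  for (cls in MODALITY_CLASSES) {
    for (j in seq_len(n_per_class)) {
      k <- k + 1L
      sd_k <- sub_seed(seed, k)
      geom <- with_seed(sd_k, list(
        r = stats::runif(1, 0.06, 0.10),
        ang = stats::runif(1, 0, 2 * pi),
        rad = stats::runif(1, 0.05, 0.5)))
      ctr <- c(0.5, 0.5) + c(geom$rad * (0.38 - geom$r) * sin(geom$ang),
                             geom$rad * (0.32 - geom$r) * cos(geom$ang))
      ph <- generate_phantom(phantom_spec(cls, size = size,
                                          tumor_center = ctr,
                                          tumor_radius = geom$r,
                                          noise_sd = noise_sd, seed = sd_k))
      images[[k]] <- ph$image
      labels[k] <- ph$label
    }
  }
  list(images = images, labels = labels)
}

#' Generate a feature table with known informative columns
#'
#' Informative columns carry class-dependent mean shifts of typical
#' magnitude `delta` on top of unit-scale Gaussian noise; nuisance
#' columns are pure noise. The ground-truth informative index set is
#' returned for parameter-recovery experiments.
#'
#' @param n_samples total samples (balanced over classes; must be a
#'   multiple of the class count and give at least 2 per class).
#' @param n_features total columns (default 1000).
#' @param n_informative number of informative columns.
#' @param delta class-mean shift scale (default 5).
#' @param noise_sd column noise standard deviation (default 1).
#' @param classes class labels (default the four modality classes).
#' @param seed integer seed.
#' @return list with `features` (a [feature_matrix()]) and
#'   `informative` (sorted integer indices).
#' @export
generate_feature_dataset <- function(n_samples = 200L, n_features = 1000L,
                                     n_informative = 10L, delta = 5,
                                     noise_sd = 1, classes = MODALITY_CLASSES,
                                     seed = 1L) {
  C <- length(classes)
  if (n_informative > n_features) stop("n_informative exceeds n_features")
  if (n_samples %% C != 0 || n_samples < 2 * C)
    stop("n_samples must be a multiple of ", C, " with >= 2 per class")
  labels <- factor(rep(classes, each = n_samples / C), levels = classes)
  with_seed(seed, {
    X <- matrix(stats::rnorm(n_samples * n_features, 0, noise_sd),
                n_samples, n_features)
    info <- sort(sample.int(n_features, n_informative))
    if (n_informative > 0) {
      shifts <- matrix(stats::rnorm(C * n_informative, 0, 1), C, n_informative)
      X[, info] <- X[, info] + delta * shifts[as.integer(labels), , drop = FALSE]
    }
    list(features = feature_matrix(X, labels = labels, source = "simulated",
                                   seed = seed),
         informative = info)
  })
}

#' Stratified train/test split
#'
#' Splits sample indices per class at the given training ratio (60:40
#' by default), seeded.
#'
#' @param labels per-sample labels.
#' @param ratio training fraction in `(0, 1)` (default 0.6).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(labels, ratio = 0.6, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  labels <- as.factor(labels)
  with_seed(seed, {
    train <- integer(0)
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      n_tr <- max(1L, round(ratio * length(idx)))
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Stratified cross-validation folds
#'
#' @param labels per-sample labels.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return list of `k` integer index vectors (the held-out fold
#'   members), jointly partitioning the samples.
#' @export
cv_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.factor(labels)
  if (k < 2 || k > length(labels)) stop("invalid fold count")
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in levels(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    lapply(seq_len(k), function(i) which(fold == i))
  })
}
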