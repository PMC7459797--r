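#' Feature matrix container
#'
#' A samples-by-features numeric matrix together with per-sample class
#' labels and the name of the backbone that produced it.
#'
#' @param values numeric matrix (samples x features).
#' @param labels per-sample labels (factor or character), or `NULL`.
#' @param source backbone or generator name.
#' @param seed seed used to produce the matrix, if any.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels = NULL, source = "unknown", seed = NA_integer_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (any(!is.finite(values))) stop("feature values must be finite")
  if (!is.null(labels)) {
    if (length(labels) != nrow(values))
      stop("labels length (", length(labels), ") != sample count (", nrow(values), ")")
    labels <- as.factor(labels)
  }
  structure(list(values = values, labels = labels,
                 feature_dim = ncol(values), source = source, seed = seed),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " samples x ", x$feature_dim,
      " features (source: ", x$source, ")\n", sep = "")
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  labels:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Describe a feature-extraction backbone
#'
#' Backbones take a 224x224x3 input tensor and emit a 1000-dimensional
#' feature vector (the dimensionality of a VGG-style final
#' fully-connected layer). The `toy` backbone is a deterministic seeded
#' random-projection bank usable without any downloaded weights; the
#' `vgg16`/`vgg19` names are reserved for adapters around published
#' pretrained weights and fail with an explicit message when those
#' weights are not available.
#'
#' @param name backbone name (`"toy"`, `"vgg16"`, `"vgg19"`).
#' @param output_dim feature dimension (default 1000).
#' @param seed integer seed fixing the toy projection bank.
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(name, output_dim = 1000L, seed = 1L) {
  if (output_dim <= 0) stop("output_dim must be positive")
  structure(list(name = name, input_size = c(224L, 224L, 3L),
                 output_dim = as.integer(output_dim), seed = as.integer(seed)),
            class = "backbone_spec")
}

#' Deterministic toy backbone
#'
#' A fixed, seeded projection bank applied to two summaries of the
#' prepared image -- the 32x32 block-mean downsampled pixel vector and
#' a 64-bin intensity histogram -- followed by half-wave rectification.
#' The bank is block-structured: identity units over the histogram bins
#' (emulating the pooled, position-tolerant abstractions a trained FC
#' layer provides), and sign-paired Gaussian projection units over the
#' pixel vector and the histogram. Sign pairing (`relu(Pz)` alongside
#' `relu(-Pz)`) keeps every linear functional of the inputs recoverable
#' after rectification, so downstream linear stages lose nothing to the
#' nonlinearity. Stands in for final-FC-layer CNN activations in tests
#' and download-free pipelines.
#'
#' @param seed integer seed for the projection bank.
#' @param output_dim number of features (default 1000).
#' @return a `backbone_spec` with `name = "toy"`.
#' @export
toy_backbone <- function(seed = 1L, output_dim = 1000L) {
  backbone_spec("toy", output_dim = output_dim, seed = seed)
}

#' Prepare an image for a backbone
#'
#' Bilinear resize to 224x224, replication of the single grey channel
#' to 3 channels. Values stay in `[0, 1]`; backbone-specific channel
#' normalization is left to the adapter.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @return a 224x224x3 array.
#' @export
prepare_input <- function(img) {
  as_gray_image(img)
  r <- bilinear_resize(img, 224L, 224L)
  array(rep(r, 3L), dim = c(224L, 224L, 3L))
}

# Block layout of the toy bank for a given output dimension:
# n_id identity histogram units, then sign-paired pixel and histogram
# projections (n_px and n_h rows per sign), plus at most one unpaired
# histogram row to hit output_dim exactly.
toy_layout <- function(output_dim) {
  n_id <- min(64L, output_dim)
  rest <- output_dim - n_id
  n_px <- rest %/% 4L
  n_h <- rest %/% 2L - n_px
  list(n_id = n_id, n_px = n_px, n_h = n_h,
       extra = rest - 2L * (n_px + n_h))
}

# Seeded Gaussian projection bank of the toy backbone.
toy_projection_bank <- function(backbone) {
  lay <- toy_layout(backbone$output_dim)
  with_seed(backbone$seed, list(
    px = matrix(stats::rnorm(lay$n_px * 1024L) / sqrt(1024),
                lay$n_px, 1024L),
    h = matrix(stats::rnorm((lay$n_h + lay$extra) * 64L) / sqrt(64),
               lay$n_h + lay$extra, 64L),
    layout = lay))
}

# 64-bin intensity histogram of a [0,1] image, as bin fractions
# scaled so its overall energy is comparable to the pixel vector.
intensity_histogram <- function(g) {
  tabulate(pmin(pmax(floor(as.vector(g) * 64) + 1L, 1L), 64L),
           nbins = 64L) / length(g) * 4
}

#' Extract features from a list of images
#'
#' Row order equals input order; the feature dimension equals
#' `backbone$output_dim`. The toy backbone is fully deterministic given
#' its seed. Pretrained adapters (`vgg16`, `vgg19`) require published
#' weights and fail with instructions to use the toy backbone when
#' these are absent.
#'
#' @param images list of grayscale image matrices.
#' @param backbone a `backbone_spec`.
#' @param labels optional per-image labels carried into the result.
#' @return a [feature_matrix()].
#' @export
extract_features <- function(images, backbone, labels = NULL) {
  if (!inherits(backbone, "backbone_spec")) stop("backbone must be a backbone_spec")
  if (length(images) == 0) stop("no images supplied")
  if (backbone$name %in% c("vgg16", "vgg19"))
    stop("pretrained weights for backbone '", backbone$name,
         "' are not available in this installation; use toy_backbone() instead")
  if (backbone$name != "toy") stop("unknown backbone: ", backbone$name)
  bank <- toy_projection_bank(backbone)
  lay <- bank$layout
  vals <- t(vapply(images, function(im) {
    x <- prepare_input(im)
    g <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
    px <- as.vector(block_mean(g, 7L))         # 224 -> 32x32 = 1024
    h <- intensity_histogram(g)
    zp <- as.vector(bank$px %*% px)
    zh <- as.vector(bank$h %*% h)              # last row may be unpaired
    zh_paired <- zh[seq_len(lay$n_h)]
    pmax(c(h[seq_len(lay$n_id)], zp, -zp, zh_paired, -zh_paired,
           zh[seq_len(lay$extra) + lay$n_h]), 0)  # half-wave rectification
  }, numeric(backbone$output_dim)))
  if (backbone$output_dim == 1L) vals <- matrix(vals, ncol = 1L)
  feature_matrix(vals, labels = labels, source = backbone$name,
                 seed = backbone$seed)
}
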