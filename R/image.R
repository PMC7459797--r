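#' Validate a grayscale image matrix
#'
#' Images are plain numeric matrices with intensities in `[0, 1]`.
#' Internally the enhancement code quantizes to 256 grey levels
#' (`0..255`); all public functions accept and return the `[0, 1]`
#' representation.
#'
#' @param img numeric matrix.
#' @param min_dim minimum number of rows and columns.
#' @return the validated matrix, invisibly unchanged.
#' @export
as_gray_image <- function(img, min_dim = 2L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix")
  if (nrow(img) < min_dim || ncol(img) < min_dim)
    stop("image must be at least ", min_dim, "x", min_dim)
  if (any(!is.finite(img)))
    stop("image contains non-finite values")
  if (min(img) < 0 || max(img) > 1)
    stop("image intensities must lie in [0, 1]")
  img
}

#' Number of grey levels used for quantized operations
#' @keywords internal
GREY_LEVELS <- 256L

#' Read a grayscale image slice
#'
#' Reads PNG or TIFF images (multi-channel images are averaged to one
#' channel), or one axial slice of a NIfTI volume. NIfTI volumes are
#' rescaled to `[0, 1]` by the volume maximum; PNG/TIFF loaders already
#' return `[0, 1]` (16-bit TIFFs are rescaled by their bit-depth
#' maximum by the reader).
#'
#' @param path file path (`.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @param slice axial slice index, required for NIfTI input.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path, slice = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    img <- tiff::readTIFF(path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is required to read NIfTI volumes")
    vol <- RNifti::asNifti(RNifti::readNifti(path))
    if (is.null(slice)) stop("a 'slice' index is required for NIfTI input")
    if (length(dim(vol)) < 3) stop("NIfTI input is not a 3D volume")
    if (slice < 1 || slice > dim(vol)[3])
      stop("slice index ", slice, " out of range 1..", dim(vol)[3])
    img <- vol[, , slice]
    mx <- max(vol)
    if (mx > 0) img <- img / mx
  } else {
    stop("unsupported image format: ", path)
  }
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  as_gray_image(pmin(pmax(img, 0), 1))
}

#' Write a grayscale image as PNG
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path ending in `.png`.
#' @export
write_gray_image <- function(img, path) {
  as_gray_image(img)
  png::writePNG(img, path)
  invisible(path)
}

# Bilinear resize of a matrix to a target size; used by the backbone
# input adapter. Edge pixels are clamped.
bilinear_resize <- function(img, out_rows, out_cols) {
  n <- nrow(img); m <- ncol(img)
  if (n == out_rows && m == out_cols) return(img)
  # map output pixel centers onto input pixel centers
  ry <- (seq_len(out_rows) - 0.5) * n / out_rows + 0.5
  rx <- (seq_len(out_cols) - 0.5) * m / out_cols + 0.5
  y0 <- pmin(pmax(floor(ry), 1), n); y1 <- pmin(y0 + 1, n)
  x0 <- pmin(pmax(floor(rx), 1), m); x1 <- pmin(x0 + 1, m)
  wy <- pmin(pmax(ry - y0, 0), 1); wx <- pmin(pmax(rx - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  top <- a * outer(rep(1, out_rows), 1 - wx) + b * outer(rep(1, out_rows), wx)
  bot <- c_ * outer(rep(1, out_rows), 1 - wx) + d * outer(rep(1, out_rows), wx)
  top * outer(1 - wy, rep(1, out_cols)) + bot * outer(wy, rep(1, out_cols))
}

# Block-mean downsample; out dims must divide the input dims.
block_mean <- function(img, fact) {
  n <- nrow(img); m <- ncol(img)
  stopifnot(n %% fact == 0, m %% fact == 0)
  nr <- n %/% fact; nc <- m %/% fact
  x <- matrix(0, nr, nc)
  for (i in seq_len(fact)) for (j in seq_len(fact)) {
    x <- x + img[seq(i, n, by = fact), seq(j, m, by = fact)]
  }
  x / fact^2
}
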