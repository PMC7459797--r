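#' Write a feature matrix as CSV plus JSON sidecar
#'
#' Values go to `<path>` as a plain CSV (one row per sample, named
#' feature columns); labels, source, and seed go to `<path>.json`.
#'
#' @param fm a [feature_matrix()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_features <- function(fm, path) {
  if (!inherits(fm, "feature_matrix")) stop("fm must be a feature_matrix")
  vals <- fm$values
  if (is.null(colnames(vals)))
    colnames(vals) <- sprintf("f%04d", seq_len(ncol(vals)))
  utils::write.csv(as.data.frame(vals), path, row.names = FALSE)
  meta <- list(labels = if (is.null(fm$labels)) NULL else as.character(fm$labels),
               source = fm$source, seed = fm$seed, feature_dim = fm$feature_dim)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' @param path CSV path; `<path>.json` must sit next to it.
#' @return a [feature_matrix()].
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("malformed feature CSV '", path,
                                          "': ", conditionMessage(e)))
  vals <- as.matrix(df)
  if (!is.numeric(vals)) stop("malformed feature CSV '", path,
                              "': non-numeric columns present")
  side <- paste0(path, ".json")
  labels <- NULL; source <- "file"; seed <- NA_integer_
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    labels <- meta$labels; source <- meta$source
    if (!is.null(meta$seed)) seed <- meta$seed
  }
  feature_matrix(vals, labels = labels, source = source, seed = seed)
}

#' Persist an ELM model as JSON
#'
#' All weight arrays are stored as JSON number arrays (full precision),
#' so the round trip reproduces predictions exactly.
#'
#' @param model an `elm_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_elm <- function(model, path) {
  if (!inherits(model, "elm_model")) stop("model must be an elm_model")
  obj <- list(type = "elm_model",
              u = model$u, B = model$B, beta = model$beta,
              activation = model$activation, c = model$c,
              L_nodes = model$L_nodes, classes = model$classes,
              center = model$center, scale = model$scale, seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read an ELM model written by [write_elm()]
#'
#' @param path JSON path.
#' @return an `elm_model`.
#' @export
read_elm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$type) || obj$type != "elm_model")
    stop("'", path, "' is not a stored elm_model")
  structure(list(u = matrix(obj$u, length(obj$center), obj$L_nodes, byrow = FALSE),
                 B = as.numeric(obj$B),
                 beta = matrix(obj$beta, obj$L_nodes, length(obj$classes)),
                 activation = obj$activation, c = obj$c,
                 L_nodes = as.integer(obj$L_nodes), classes = obj$classes,
                 center = as.numeric(obj$center), scale = as.numeric(obj$scale),
                 seed = as.integer(obj$seed)),
            class = "elm_model")
}
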