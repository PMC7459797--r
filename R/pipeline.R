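#' Pipeline configuration
#'
#' Validated container for all stage hyper-parameters of the end-to-end
#' pipeline: contrast enhancement, two-backbone feature extraction,
#' per-block feature selection, PLS fusion, ELM classification, and the
#' stratified train/test split. Unknown keys are rejected before any
#' computation.
#'
#' @param ... overrides of the default fields: `simulate` (list:
#'   `n_per_class`, `size`, `noise_sd`), `enhance_opts` (list: `enabled`,
#'   `K`, `edge_threshold`, `alpha_root`, `edge_polarity`), `backbones`
#'   (list of two [backbone_spec()] objects, or `NULL` to derive two
#'   toy backbones from the seed), `select_opts` (passed to
#'   [selection_config()]), `fuse_d` (direction pairs, capped by rank),
#'   `elm_opts` (list: `L_nodes`, `c`, `activation`), `split_ratio`,
#'   `seed`, `out_dir`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    simulate = list(n_per_class = 10L, size = 256L, noise_sd = 0.05),
    enhance_opts = list(enabled = TRUE, K = 2L, edge_threshold = 0.55,
                        alpha_root = 0.98, edge_polarity = "above"),
    backbones = NULL,
    select_opts = list(),
    fuse_d = 8L,
    elm_opts = list(L_nodes = 1000L, c = 1, activation = "sigmoid"),
    split_ratio = 0.6,
    seed = 1L,
    out_dir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown pipeline_config keys: ", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && is.list(over[[nm]]) && nm != "backbones") {
      badsub <- setdiff(names(over[[nm]]), names(defaults[[nm]]))
      if (nm != "select_opts" && length(badsub))
        stop("unknown keys in '", nm, "': ", paste(badsub, collapse = ", "))
      defaults[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      defaults[[nm]] <- over[[nm]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Run the full classification pipeline
#'
#' Simulates (or accepts) labeled slices, enhances them, extracts
#' features with two backbones, splits the samples 60:40 with
#' stratification, runs group-sparse selection per block on the
#' training split, fits the PLS fusion on the training split, trains
#' the ELM on the fused training scores, and evaluates on both splits.
#' Fully deterministic given the seed. When `out_dir` is set, the
#' resolved configuration, metrics report, and selection traces are
#' written there as JSON.
#'
#' @param config a [pipeline_config()].
#' @param images optional list of image matrices (with `labels`)
#'   bypassing simulation.
#' @param labels labels for `images`.
#' @return list with `metrics_train`, `metrics_test` (see
#'   [evaluate_predictions()]), `mcc_test`, `selection` (two
#'   `selection_result`s), `fusion`, `model` (the ELM), `split`, and
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), images = NULL, labels = NULL) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  seed <- config$seed

  if (is.null(images)) {
    sim <- generate_phantom_batch(n_per_class = config$simulate$n_per_class,
                                  size = config$simulate$size,
                                  noise_sd = config$simulate$noise_sd,
                                  seed = seed)
    images <- sim$images; labels <- sim$labels
  }
  if (is.null(labels) || length(labels) != length(images))
    stop("images must come with one label each")

  eo <- config$enhance_opts
  if (isTRUE(eo$enabled)) {
    images <- lapply(images, enhance, K = eo$K,
                     edge_threshold = eo$edge_threshold,
                     alpha_root = eo$alpha_root,
                     edge_polarity = eo$edge_polarity, seed = seed)
  }

  backbones <- config$backbones
  if (is.null(backbones))
    backbones <- list(toy_backbone(seed = sub_seed(seed, 101L)),
                      toy_backbone(seed = sub_seed(seed, 202L)))
  fmA <- extract_features(images, backbones[[1]], labels = labels)
  fmB <- extract_features(images, backbones[[2]], labels = labels)

  split <- train_test_split(labels, ratio = config$split_ratio,
                            seed = sub_seed(seed, 303L))
  tr <- split$train; te <- split$test

  sel_cfg <- do.call(selection_config,
                     c(config$select_opts,
                       list(seed = sub_seed(seed, 404L))[!("seed" %in% names(config$select_opts))]))
  selA <- run_selection(fmA$values[tr, , drop = FALSE], labels[tr], sel_cfg)
  selB <- run_selection(fmB$values[tr, , drop = FALSE], labels[tr], sel_cfg)
  A_tr <- fmA$values[tr, selA$selected, drop = FALSE]
  B_tr <- fmB$values[tr, selB$selected, drop = FALSE]
  A_te <- fmA$values[te, selA$selected, drop = FALSE]
  B_te <- fmB$values[te, selB$selected, drop = FALSE]

  d <- min(config$fuse_d, ncol(A_tr), ncol(B_tr), length(tr) - 1)
  fusion <- fit_fusion(A_tr, B_tr, d = d)
  fused_tr <- fuse_blocks(A_tr, B_tr, fusion, labels = labels[tr])
  fused_te <- fuse_blocks(A_te, B_te, fusion, labels = labels[te])

  el <- config$elm_opts
  model <- train_elm(fused_tr, L_nodes = el$L_nodes, c = el$c,
                     activation = el$activation, seed = sub_seed(seed, 505L))
  classes <- sort(unique(as.character(labels)))
  pred_tr <- predict(model, fused_tr)
  pred_te <- predict(model, fused_te)
  m_tr <- evaluate_predictions(labels[tr], pred_tr$labels, classes = classes)
  m_te <- evaluate_predictions(labels[te], pred_te$labels, classes = classes)

  out <- list(metrics_train = m_tr, metrics_test = m_te,
              mcc_test = mcc(m_te$confusion),
              selection = list(a = selA, b = selB), fusion = fusion,
              model = model, split = split, config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- list(
      accuracy_train = m_tr$accuracy, fnr_train = m_tr$fnr,
      accuracy_test = m_te$accuracy, fnr_test = m_te$fnr,
      mcc_test = out$mcc_test,
      confusion_test = m_te$confusion,
      n_selected = c(a = length(selA$selected), b = length(selB$selected)),
      seed = seed)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
    cfg <- config; class(cfg) <- NULL
    cfg$backbones <- lapply(backbones, unclass)
    jsonlite::write_json(cfg, file.path(config$out_dir, "config.json"),
                         digits = NA, auto_unbox = TRUE, null = "null",
                         force = TRUE)
    utils::write.csv(selA$trace, file.path(config$out_dir, "selection_trace_a.csv"),
                     row.names = FALSE)
    utils::write.csv(selB$trace, file.path(config$out_dir, "selection_trace_b.csv"),
                     row.names = FALSE)
    write_elm(model, file.path(config$out_dir, "elm_model.json"))
  }
  out
}
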