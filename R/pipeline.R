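MODEL_FORMAT_VERSION <- 1L

#' Save a trained pipeline model
#'
#' Serialises a fitted `fsvm_model` together with the full feature
#' extraction configuration (wavelet, level, q, estimator) to a versioned
#' JSON file, so that prediction always reuses exactly the training-time
#' extraction settings.
#'
#' @param model An `fsvm_model`.
#' @param path Output file (JSON).
#' @param extraction Named list of extraction settings (`q`, `wavelet`,
#'   `level`, `estimator`, `n_bins`, `normalize`).
#' @param extra Optional named list stored alongside (e.g. grid-search
#'   report).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, extraction, extra = list()) {
  stopifnot(inherits(model, "fsvm_model"))
  payload <- list(
    format = "wptefsvm-model",
    version = MODEL_FORMAT_VERSION,
    extraction = extraction,
    model = list(
      alpha = model$alpha,
      sv_x = model$sv_x,
      sv_y = model$sv_y,
      b = model$b,
      C = model$C,
      kernel = unclass(model$kernel),
      n_train = model$n_train
    ),
    extra = extra
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a pipeline model saved by [save_model()]
#'
#' @param path Model JSON file.
#' @return List with `model` (an `fsvm_model`) and `extraction`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "wptefsvm-model"))
    stop("not a wptefsvm model file: ", path, call. = FALSE)
  if (p$version > MODEL_FORMAT_VERSION)
    stop("model format version ", p$version, " is newer than supported (",
         MODEL_FORMAT_VERSION, ")", call. = FALSE)
  kern <- p$model$kernel
  kernel <- kernel_spec(kern$type,
                        gamma = if (is.null(kern$gamma)) NULL else kern$gamma,
                        degree = kern$degree, coef0 = kern$coef0)
  model <- structure(list(
    alpha = as.numeric(p$model$alpha),
    sv_x = matrix(as.numeric(p$model$sv_x), nrow = length(p$model$alpha)),
    sv_y = as.integer(p$model$sv_y),
    b = p$model$b, C = p$model$C, kernel = kernel,
    n_train = p$model$n_train
  ), class = "fsvm_model")
  list(model = model, extraction = p$extraction, extra = p$extra)
}

#' Offline training phase
#'
#' The full offline workflow: extract WPTE features from a manifest,
#' optionally grid-search the entropic index `q` and the penalty `C`, fit
#' the final classifier on all data, and write a serialized model whose
#' extraction settings are frozen for prediction.
#'
#' @param manifest Manifest data frame or CSV path (`path,label`, optional
#'   `train_label`).
#' @param model_path Output model JSON file.
#' @param q Fixed entropic index; `NULL` grid-searches `q_grid`.
#' @param q_grid,C_grid Candidate grids (used when `q`/`C` is `NULL`).
#' @param C Fixed penalty; `NULL` grid-searches `C_grid` (nested).
#' @param classifier,kernel,delta,scale Passed to [model_config()].
#' @param wavelet,level,estimator Extraction settings.
#' @param cv A [cv_config()] used by the grid searches.
#' @return List with `model_path`, `q_star`, `C_star` and the grid tables.
#' @export
cmd_train <- function(manifest, model_path, q = 0.8, q_grid = seq(0.1, 1, 0.1),
                      C = 1, C_grid = 2^(-2:6),
                      classifier = "fsvm", kernel = kernel_spec("rbf"),
                      delta = NULL, scale = FALSE,
                      wavelet = "haar", level = 2L, estimator = "energy",
                      cv = cv_config()) {
  if (is.character(manifest)) {
    if (!file.exists(manifest))
      stop("manifest not found: ", manifest, call. = FALSE)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  images <- if ("image" %in% names(manifest)) manifest$image
            else lapply(manifest$path, read_image)
  labels <- as.integer(manifest$label)
  train_labels <- if ("train_label" %in% names(manifest))
    as.integer(manifest$train_label) else labels
  cfg <- model_config(classifier, kernel, C = if (is.null(C)) 1 else C,
                      delta = delta, scale = scale)

  q_table <- NULL
  if (is.null(q)) {
    gs <- grid_search_q(images, labels, q_grid, cfg, cv,
                        wavelet = wavelet, level = level,
                        estimator = estimator)
    q <- gs$q_star
    q_table <- gs$table
  }
  feats <- t(vapply(images, function(im)
    as.numeric(extract_wpte(im, q = q, wavelet = wavelet, level = level,
                            estimator = estimator)), numeric(4L^level)))
  C_table <- NULL
  if (is.null(C)) {
    gc <- grid_search_C(feats, labels, C_grid, cfg, cv, mode = "nested")
    C <- gc$C_star
    C_table <- gc$table
  }
  cfg$C <- C
  fit <- fit_fold(feats, train_labels, cfg)
  extraction <- list(q = q, wavelet = wavelet, level = level,
                     estimator = estimator, normalize = TRUE,
                     scale_center = fit$center, scale_sd = fit$scale_sd)
  save_model(fit$model, model_path, extraction,
             extra = list(q_table = q_table, C_table = C_table,
                          classifier = classifier))
  list(model_path = model_path, q_star = q, C_star = C,
       q_table = q_table, C_table = C_table)
}

#' Online prediction phase
#'
#' Loads a serialized model and classifies query images. Extraction
#' parameters (wavelet, level, q, estimator) come from the model file only,
#' so online prediction cannot drift from the offline configuration.
#'
#' @param model_path Model JSON written by [cmd_train()] / [save_model()].
#' @param images Character vector of image paths, or list of matrices.
#' @return Data frame with `path`, `class` (`"pathological"`/`"healthy"`),
#'   `label` (+1/-1) and `decision`.
#' @export
cmd_predict <- function(model_path, images) {
  loaded <- load_model(model_path)
  ex <- loaded$extraction
  paths <- if (is.character(images)) images
           else sprintf("<matrix:%d>", seq_along(images))
  if (is.character(images)) images <- lapply(images, read_image)
  feats <- t(vapply(images, function(im)
    as.numeric(extract_wpte(im, q = ex$q, wavelet = ex$wavelet,
                            level = ex$level, estimator = ex$estimator)),
    numeric(4L^as.integer(ex$level))))
  if (!is.null(ex$scale_center))
    feats <- sweep(sweep(feats, 2, as.numeric(ex$scale_center)), 2,
                   as.numeric(ex$scale_sd), "/")
  pr <- predict(loaded$model, feats)
  data.frame(path = paths,
             class = ifelse(pr$label == 1L, "pathological", "healthy"),
             label = pr$label, decision = pr$decision,
             stringsAsFactors = FALSE)
}
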