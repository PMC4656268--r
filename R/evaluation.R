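# Run expr with a local, restored RNG state so evaluation is deterministic
# given its seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Stratified K-fold assignment
#'
#' Assigns samples to `K` folds so that per-class counts across folds differ
#' by at most one (exactly equal when the class size divides `K`), matching
#' the stratified cross-validation designs used for imbalanced
#' pathological/healthy image sets. Deterministic given `seed`.
#'
#' @param labels Class labels (any type with two or more values present).
#' @param K Number of folds, `>= 2`.
#' @param seed Integer seed controlling the shuffle.
#' @return Integer vector of fold ids in `1..K`, one per sample.
#' @examples
#' y <- rep(c(1, -1), c(48, 18))
#' table(y, stratified_kfold(y, K = 6, seed = 1))  # 8/3 per fold
#' @export
stratified_kfold <- function(labels, K, seed = 1L) {
  n <- length(labels)
  stopifnot(K >= 2, n >= K)
  fold <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < K)
        warning("class ", cl, " has fewer samples (", length(idx),
                ") than folds (", K, "); some folds will miss it")
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(K), length(idx))
    }
  })
  fold
}

#' Binary classification metrics
#'
#' Confusion counts and percentage metrics with the pathological class
#' (`+1`) as positive: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`, each times 100. A
#' zero-denominator metric is reported as `NA`, never 0.
#'
#' @param truth,pred Label vectors in `{+1, -1}`.
#' @return A `pbd_metrics` list with `TP`, `TN`, `FP`, `FN`, `sensitivity`,
#'   `specificity`, `accuracy`, `precision`.
#' @export
classification_metrics <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  TP <- sum(truth == 1L & pred == 1L)
  TN <- sum(truth == -1L & pred == -1L)
  FP <- sum(truth == -1L & pred == 1L)
  FN <- sum(truth == 1L & pred == -1L)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    TP = TP, TN = TN, FP = FP, FN = FN,
    sensitivity = pct(TP, TP + FN),
    specificity = pct(TN, TN + FP),
    accuracy = pct(TP + TN, TP + TN + FP + FN),
    precision = pct(TP, TP + FP)
  ), class = "pbd_metrics")
}

#' @export
print.pbd_metrics <- function(x, ...) {
  cat(sprintf(
    "TP %d TN %d FP %d FN %d | sens %.2f spec %.2f acc %.2f prec %.2f\n",
    x$TP, x$TN, x$FP, x$FN, x$sensitivity, x$specificity, x$accuracy,
    x$precision))
  invisible(x)
}

#' Cross-validation configuration
#'
#' @param K Folds (6 suits a 66-sample set with 18/48 split, 5 the larger
#'   sets).
#' @param runs Number of repeated shuffles `R` (default 10).
#' @param seed Base seed; run `r` uses `seed + r - 1`.
#' @return A `cv_config` list.
#' @export
cv_config <- function(K = 5L, runs = 10L, seed = 1L) {
  stopifnot(K >= 2, runs >= 1)
  structure(list(K = as.integer(K), runs = as.integer(runs),
                 seed = as.integer(seed)), class = "cv_config")
}

#' Classifier configuration for cross-validation
#'
#' @param classifier `"fsvm"` (membership-weighted) or `"svm"`.
#' @param kernel A [kernel_spec()].
#' @param C Error penalty.
#' @param delta Membership stabiliser (see [fit_membership()]); `NULL` for
#'   the relative default.
#' @param scale Z-score features using training-fold statistics only.
#' @return A `model_config` list.
#' @export
model_config <- function(classifier = c("fsvm", "svm"),
                         kernel = kernel_spec("rbf"), C = 1,
                         delta = NULL, scale = FALSE) {
  classifier <- match.arg(classifier)
  structure(list(classifier = classifier, kernel = kernel, C = C,
                 delta = delta, scale = scale), class = "model_config")
}

# Fit the configured classifier on one training partition. All data-driven
# pieces (scaling, membership geometry) are computed from the training rows
# only, so no test-fold information can leak into the model.
fit_fold <- function(X_tr, y_tr, config) {
  center <- NULL; scale_sd <- NULL
  if (config$scale) {
    center <- colMeans(X_tr)
    scale_sd <- apply(X_tr, 2, stats::sd)
    scale_sd[scale_sd == 0] <- 1
    X_tr <- sweep(sweep(X_tr, 2, center), 2, scale_sd, "/")
  }
  s <- if (config$classifier == "fsvm") {
    mm <- fit_membership(X_tr, y_tr, delta = config$delta)
    membership(mm, X_tr, y_tr)
  } else rep(1, length(y_tr))
  model <- train_fsvm(X_tr, y_tr, s = s, C = config$C,
                      kernel = config$kernel)
  list(model = model, center = center, scale_sd = scale_sd)
}

predict_fold <- function(fit, X_te) {
  if (!is.null(fit$center)) {
    X_te <- sweep(sweep(X_te, 2, fit$center), 2, fit$scale_sd, "/")
  }
  predict(fit$model, X_te)
}

#' Repeated stratified K-fold cross-validation
#'
#' Runs `R` independent stratified K-fold shuffles. Within each run, the
#' classifier (including fuzzy memberships and optional scaling) is fitted
#' on the K-1 training folds only and evaluated on the held-out fold; the
#' run's confusion counts are pooled across folds, and the final metrics
#' average the per-run percentages.
#'
#' @param features Feature matrix or the data frame from [extract_batch()]
#'   (its `label` column is used when `labels` is missing).
#' @param labels True labels in `{+1, -1}` used for scoring.
#' @param config A [model_config()].
#' @param cv A [cv_config()].
#' @param train_labels Labels used for *training* (defaults to `labels`);
#'   supplying a corrupted copy trains on noisy labels while still scoring
#'   against the truth, which is how classifier robustness to mislabeled
#'   samples is measured.
#' @return A `cv_report`: `runs` data frame (one row per run, pooled
#'   confusion + metrics), `folds` data frame (per run x fold), and
#'   `summary` — the across-run mean of each metric.
#' @export
run_cv <- function(features, labels = NULL, config = model_config(),
                   cv = cv_config(), train_labels = NULL) {
  if (is.data.frame(features)) {
    if (is.null(labels) && "label" %in% names(features))
      labels <- features$label
    features <- as.matrix(features[, grep("^f[0-9]+$", names(features)),
                                   drop = FALSE])
  }
  X <- as.matrix(features)
  y <- as.integer(labels)
  if (is.null(train_labels)) train_labels <- y
  train_labels <- as.integer(train_labels)
  stopifnot(nrow(X) == length(y), length(y) == length(train_labels))

  run_rows <- list(); fold_rows <- list()
  for (r in seq_len(cv$runs)) {
    fold <- stratified_kfold(y, cv$K, seed = cv$seed + r - 1L)
    pred <- integer(length(y))
    for (k in seq_len(cv$K)) {
      te <- fold == k
      if (length(unique(train_labels[!te])) < 2L)
        stop("degenerate training partition in run ", r, " fold ", k,
             call. = FALSE)
      fit <- fit_fold(X[!te, , drop = FALSE], train_labels[!te], config)
      pred[te] <- predict_fold(fit, X[te, , drop = FALSE])$label
      mk <- classification_metrics(y[te], pred[te])
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        run = r, fold = k, n_test = sum(te),
        degenerate = length(unique(y[te])) < 2L,
        sensitivity = mk$sensitivity, specificity = mk$specificity,
        accuracy = mk$accuracy, precision = mk$precision)
    }
    m <- classification_metrics(y, pred)
    run_rows[[r]] <- data.frame(
      run = r, TP = m$TP, TN = m$TN, FP = m$FP, FN = m$FN,
      sensitivity = m$sensitivity, specificity = m$specificity,
      accuracy = m$accuracy, precision = m$precision)
  }
  runs_df <- do.call(rbind, run_rows)
  metric_cols <- c("sensitivity", "specificity", "accuracy", "precision")
  structure(list(
    runs = runs_df,
    folds = do.call(rbind, fold_rows),
    summary = colMeans(runs_df[, metric_cols], na.rm = TRUE),
    config = config, cv = cv
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>", x$cv$runs, "runs of", x$cv$K, "-fold stratified CV |",
      x$config$classifier, x$config$kernel$type, "C =", x$config$C, "\n")
  cat(sprintf(
    "  mean sens %.2f | spec %.2f | acc %.2f | prec %.2f\n",
    x$summary["sensitivity"], x$summary["specificity"],
    x$summary["accuracy"], x$summary["precision"]))
  invisible(x)
}

#' Grid search over the entropic index q
#'
#' Re-extracts WPTE features for every candidate `q` and scores each with
#' [run_cv()], returning the mean accuracy per `q` and the winner `q*`
#' (ties resolved toward the smaller `q`). This is the offline-phase
#' parameter selection of the pipeline.
#'
#' @param images List of image matrices (or paths).
#' @param labels Labels in `{+1, -1}`.
#' @param q_grid Candidate entropic indices (default `seq(0.1, 1, 0.1)`).
#' @param config,cv As in [run_cv()].
#' @param wavelet,level,estimator Feature-extraction settings.
#' @return List with `table` (`q`, `accuracy`) and `q_star`.
#' @export
grid_search_q <- function(images, labels, q_grid = seq(0.1, 1, by = 0.1),
                          config = model_config(), cv = cv_config(),
                          wavelet = "haar", level = 2L,
                          estimator = "energy") {
  stopifnot(length(q_grid) >= 1)
  acc <- vapply(q_grid, function(q) {
    feats <- t(vapply(images, function(im)
      as.numeric(extract_wpte(im, q = q, wavelet = wavelet, level = level,
                              estimator = estimator)),
      numeric(4L^level)))
    run_cv(feats, labels, config, cv)$summary[["accuracy"]]
  }, numeric(1))
  best <- which(acc == max(acc))
  q_star <- min(q_grid[best])
  list(table = data.frame(q = q_grid, accuracy = acc), q_star = q_star)
}

#' Grid search over the error penalty C
#'
#' `mode = "nested"` (default) selects `C` by an inner cross-validation on
#' each outer training partition (no information from the held-out fold is
#' used), reports each partition's pick and returns the modal choice, ties
#' toward the smaller `C`. `mode = "outer"` simply scores each candidate
#' with [run_cv()] on the whole set and returns the argmax — optimistic, but
#' matching protocols that tune outside the evaluation loop.
#'
#' @param features Feature matrix or [extract_batch()] data frame.
#' @param labels Labels in `{+1, -1}`.
#' @param C_grid Candidate penalties.
#' @param config,cv As in [run_cv()].
#' @param mode `"nested"` or `"outer"`.
#' @return List with `table` (`C`, score or selection count) and `C_star`.
#' @export
grid_search_C <- function(features, labels = NULL,
                          C_grid = 2^(-2:6), config = model_config(),
                          cv = cv_config(), mode = c("nested", "outer")) {
  mode <- match.arg(mode)
  stopifnot(length(C_grid) >= 1)
  C_grid <- sort(C_grid)
  if (is.data.frame(features)) {
    if (is.null(labels) && "label" %in% names(features))
      labels <- features$label
    features <- as.matrix(features[, grep("^f[0-9]+$", names(features)),
                                   drop = FALSE])
  }
  X <- as.matrix(features); y <- as.integer(labels)
  score_C <- function(Xs, ys, C, cvc) {
    cfg <- config; cfg$C <- C
    run_cv(Xs, ys, cfg, cvc)$summary[["accuracy"]]
  }
  if (mode == "outer") {
    acc <- vapply(C_grid, function(C) score_C(X, y, C, cv), numeric(1))
    best <- which(acc == max(acc))
    return(list(table = data.frame(C = C_grid, accuracy = acc),
                C_star = min(C_grid[best]), mode = mode))
  }
  inner_cv <- cv_config(K = cv$K, runs = 1L, seed = cv$seed + 1000L)
  picks <- numeric(0)
  fold <- stratified_kfold(y, cv$K, seed = cv$seed)
  for (k in seq_len(cv$K)) {
    tr <- fold != k
    acc <- vapply(C_grid, function(C)
      score_C(X[tr, , drop = FALSE], y[tr], C, inner_cv), numeric(1))
    picks <- c(picks, min(C_grid[acc == max(acc)]))
  }
  tab <- table(factor(picks, levels = C_grid))
  C_star <- as.numeric(names(tab)[which.max(tab)])
  list(table = data.frame(C = C_grid, selections = as.integer(tab)),
       C_star = C_star, picks = picks, mode = mode)
}
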