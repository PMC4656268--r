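test_that("stratified folds reproduce the benchmark training/test splits", {
  # 66 = 18 healthy + 48 pathological, 6 folds -> 3 + 8 per fold
  y66 <- rep(c(-1, 1), c(18, 48))
  f <- stratified_kfold(y66, K = 6, seed = 1)
  expect_true(all(table(y66, f) == matrix(c(3, 8), 2, 6, byrow = FALSE)))
  for (k in 1:6) {
    expect_identical(sum(y66[f != k] == -1), 15L)  # training partition
    expect_identical(sum(y66[f != k] == 1), 40L)
  }
  # 160 = 20 + 140, 5 folds -> 4 + 28; training 16 + 112
  y160 <- rep(c(-1, 1), c(20, 140))
  f <- stratified_kfold(y160, K = 5, seed = 2)
  expect_true(all(table(y160, f)[1, ] == 4) && all(table(y160, f)[2, ] == 28))
  # 255 = 35 + 220, 5 folds -> 7 + 44; training 28 + 176
  y255 <- rep(c(-1, 1), c(35, 220))
  f <- stratified_kfold(y255, K = 5, seed = 3)
  expect_true(all(table(y255, f)[1, ] == 7) && all(table(y255, f)[2, ] == 44))
})

test_that("fold assignment is seed-deterministic and near-balanced otherwise", {
  y <- rep(c(-1, 1), c(7, 12))
  expect_identical(stratified_kfold(y, 4, seed = 9),
                   stratified_kfold(y, 4, seed = 9))
  f <- stratified_kfold(y, 4, seed = 9)
  counts <- table(y, f)
  expect_lte(max(counts[1, ]) - min(counts[1, ]), 1)
  expect_lte(max(counts[2, ]) - min(counts[2, ]), 1)
  expect_warning(stratified_kfold(rep(c(-1, 1), c(2, 20)), 5, seed = 1),
                 "fewer samples")
})

test_that("metrics match their confusion-count definitions", {
  truth <- rep(c(1, -1), c(10, 8))
  pred <- truth
  pred[c(1, 2, 11)] <- -pred[c(1, 2, 11)]  # 2 FN, 1 FP
  m <- classification_metrics(truth, pred)
  expect_identical(c(m$TP, m$TN, m$FP, m$FN), c(8L, 7L, 1L, 2L))
  expect_equal(m$sensitivity, 100 * 8 / 10)
  expect_equal(m$specificity, 100 * 7 / 8)
  expect_equal(m$accuracy, 100 * 15 / 18)
  expect_equal(m$precision, 100 * 8 / 9)
  # zero denominator reported as missing, not zero
  m2 <- classification_metrics(rep(-1, 5), rep(-1, 5))
  expect_true(is.na(m2$sensitivity) && is.na(m2$precision))
  expect_equal(m2$specificity, 100)
})

test_that("cross-validation is perfect on separable features, repeatable", {
  set.seed(12)
  n <- 40
  y <- rep(c(-1, 1), each = n / 2)
  X <- matrix(rnorm(n * 4), n) + outer(y, c(6, 0, 0, 0))
  rep1 <- run_cv(X, y, model_config("fsvm", C = 10),
                 cv_config(K = 5, runs = 3, seed = 4))
  expect_equal(unname(rep1$summary["accuracy"]), 100)
  rep2 <- run_cv(X, y, model_config("fsvm", C = 10),
                 cv_config(K = 5, runs = 3, seed = 4))
  expect_identical(rep1$runs, rep2$runs)
  expect_identical(nrow(rep1$runs), 3L)
  expect_identical(nrow(rep1$folds), 15L)
})

test_that("metric identities hold in every report row", {
  set.seed(13)
  n <- 30
  y <- rep(c(-1, 1), c(10, 20))
  X <- matrix(rnorm(n * 3), n) + outer(y, c(1, 0, 0))
  r <- run_cv(X, y, model_config("svm", C = 1), cv_config(K = 5, runs = 2))
  with(r$runs, {
    expect_equal(accuracy, 100 * (TP + TN) / (TP + TN + FP + FN))
    expect_equal(sensitivity, 100 * TP / (TP + FN))
    expect_equal(specificity, 100 * TN / (TN + FP))
  })
})

test_that("shuffled labels score at the majority rate, not above", {
  set.seed(14)
  n <- 60
  y <- rep(c(-1, 1), c(20, 40))
  X <- matrix(rnorm(n * 4), n)  # features carry no class signal
  r <- run_cv(X, y, model_config("svm", C = 1), cv_config(K = 5, runs = 4))
  maj <- 100 * 40 / 60
  half_width <- 100 * 1.96 * sqrt((2 / 3) * (1 / 3) / n)
  expect_lt(abs(r$summary[["accuracy"]] - maj), half_width + 1e-9)
})

test_that("test-fold labels cannot leak into training", {
  set.seed(15)
  n <- 24
  y <- rep(c(-1, 1), each = n / 2)
  X <- matrix(rnorm(n * 3), n) + outer(y, c(3, 0, 0))
  cv <- cv_config(K = 2, runs = 1, seed = 6)
  fold <- stratified_kfold(y, 2, seed = cv$seed)
  # corrupt the training-label copy only inside fold 1 (the test fold for
  # models trained on fold 2): fold-1 predictions must not move
  y_bad <- y
  y_bad[fold == 1] <- -y_bad[fold == 1]
  r_ref <- run_cv(X, y, model_config("fsvm", C = 5), cv)
  r_bad <- run_cv(X, y, model_config("fsvm", C = 5), cv, train_labels = y_bad)
  # fold 2 was trained on untouched labels in both runs
  ref_fold2 <- r_ref$folds[r_ref$folds$fold == 1, ]
  bad_fold2 <- r_bad$folds[r_bad$folds$fold == 1, ]
  expect_identical(ref_fold2$accuracy, bad_fold2$accuracy)
})

test_that("q grid search reports one row per candidate and the argmax q", {
  set.seed(16)
  # classes differ in the tail-heaviness of their coefficient
  # distributions: Gaussian texture vs sparse heavy-tailed texture
  images <- c(lapply(1:8, function(i) matrix(rnorm(32^2), 32)),
              lapply(1:8, function(i) matrix(rnorm(32^2)^3, 32)))
  labels <- rep(c(-1, 1), each = 8)
  gs <- grid_search_q(images, labels, q_grid = c(0.5, 0.8, 1),
                      model_config("svm", C = 10),
                      cv_config(K = 4, runs = 2, seed = 7))
  expect_identical(nrow(gs$table), 3L)
  expect_true(gs$q_star %in% c(0.5, 0.8, 1))
  # separable by noise level: the winner classifies perfectly
  expect_equal(max(gs$table$accuracy), 100)
  # a single-point grid at q = 1 equals the WPSE pipeline
  feats_wpse <- t(sapply(images, function(im)
    as.numeric(extract_wpse(im))))
  acc_wpse <- run_cv(feats_wpse, labels, model_config("svm", C = 10),
                     cv_config(K = 4, runs = 2, seed = 7))$summary["accuracy"]
  gs1 <- grid_search_q(images, labels, q_grid = 1,
                       model_config("svm", C = 10),
                       cv_config(K = 4, runs = 2, seed = 7))
  expect_equal(gs1$table$accuracy, unname(acc_wpse))
  expect_identical(gs1$q_star, 1)
})

test_that("C grid search honours ties, modes and planted noise", {
  set.seed(17)
  n <- 24
  y <- rep(c(-1, 1), each = n / 2)
  X <- matrix(rnorm(n * 2), n) + outer(y, c(4, 0))
  cv <- cv_config(K = 3, runs = 1, seed = 8)
  # single candidate comes straight back
  one <- grid_search_C(X, y, C_grid = 2, model_config("svm"), cv)
  expect_equal(one$C_star, 2)
  # separable data: all large C tie, smallest wins (outer mode)
  sep <- grid_search_C(X, y, C_grid = c(1, 10, 100),
                       model_config("svm"), cv, mode = "outer")
  expect_equal(sep$C_star, 1)
  # label noise: the best penalty is finite, not the top of the grid
  y_noisy <- y
  flip <- sample(n, 4)
  y_noisy[flip] <- -y_noisy[flip]
  noisy <- grid_search_C(X, y_noisy, C_grid = c(0.25, 1, 4, 16, 64, 256),
                         model_config("svm"), cv, mode = "outer")
  expect_lt(noisy$C_star, 256)
})
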