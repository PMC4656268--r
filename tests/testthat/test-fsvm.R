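test_that("membership model recovers class centers and radii", {
  X <- rbind(c(0, 0), c(2, 0), c(5, 5), c(5, 5))
  y <- c(1, 1, -1, -1)
  mm <- fit_membership(X, y, delta = 0.1)
  expect_equal(mm$center_pos, c(1, 0))
  expect_equal(mm$radius_pos, 1)
  # duplicate-only class: radius 0, memberships 1
  expect_equal(mm$radius_neg, 0)
  expect_equal(membership(mm, X[3:4, ], y[3:4]), c(1, 1))
  # singleton class
  mm2 <- fit_membership(rbind(c(0, 0), c(1, 1), c(9, 9)), c(1, 1, -1))
  expect_equal(mm2$radius_neg, 0)
  expect_equal(membership(mm2, c(9, 9), -1), 1)
  expect_error(fit_membership(X, rep(1, 4)), "both classes")
})

test_that("membership is 1 at the class mean and delta/(r+delta) at the rim", {
  X <- rbind(c(0, 0), c(2, 0), c(1, 5), c(1, -5))
  y <- c(1, 1, -1, -1)
  mm <- fit_membership(X, y, delta = 0.5)
  expect_equal(membership(mm, c(1, 0), 1), 1)       # at the +1 mean
  expect_equal(membership(mm, c(0, 0), 1), 0.5 / 1.5)  # at radius 1
  # prediction-time points beyond the radius stay strictly positive
  expect_gt(membership(mm, c(100, 0), 1), 0)
})

test_that("two-point max-margin problem matches the closed form", {
  m <- train_svm(rbind(c(0, 0), c(2, 0)), c(-1, 1), C = 100,
                 kernel_spec("linear"))
  expect_equal(sort(m$alpha), c(0.5, 0.5), tolerance = 1e-6)
  # boundary x1 = 1: decision is x1 - 1
  expect_equal(predict(m, rbind(c(1, 0)))$decision, 0, tolerance = 1e-6)
  expect_equal(predict(m, rbind(c(3, 5)))$decision, 2, tolerance = 1e-6)
})

test_that("a separable set is fit with zero training error", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(4, 4), c(5, 4), c(4, 5))
  y <- c(-1, -1, -1, 1, 1, 1)
  for (k in list(kernel_spec("linear"), kernel_spec("rbf", gamma = 0.5))) {
    m <- train_svm(X, y, C = 10, k)
    expect_identical(predict(m, X)$label, as.integer(y))
  }
})

test_that("dual objective matches a brute-force QP solver on small problems", {
  set.seed(7)
  for (i in 1:12) {
    n <- sample(4:8, 1)
    p <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n)
    y <- c(-1, 1, sample(c(-1, 1), n - 2, replace = TRUE))
    C <- runif(1, 0.5, 10)
    kern <- kernel_spec(sample(c("linear", "rbf", "polynomial"), 1),
                        gamma = 0.5, degree = 2)
    # plain SVM
    m <- train_svm(X, y, C, kern)
    expect_equal(m$dual_objective, qp_dual_objective(X, y, rep(1, n), C, kern),
                 tolerance = 1e-6)
    # fuzzy SVM with random memberships
    s <- runif(n, 0.05, 1)
    mf <- train_fsvm(X, y, s, C, kern)
    expect_equal(mf$dual_objective, qp_dual_objective(X, y, s, C, kern),
                 tolerance = 1e-6)
  }
})

test_that("dual feasibility holds after every fit", {
  set.seed(8)
  for (i in 1:5) {
    n <- 20
    X <- matrix(rnorm(n * 3), n)
    y <- rep(c(-1, 1), each = n / 2)
    s <- runif(n, 0.1, 1)
    C <- 5
    m <- train_fsvm(X, y, s, C, kernel_spec("rbf"))
    expect_true(all(m$alpha_full >= -1e-12))
    expect_true(all(m$alpha_full <= s * C + 1e-8))
    expect_lt(abs(sum(m$alpha_full * y)), 1e-8)
  }
})

test_that("unit memberships reproduce the plain SVM exactly", {
  set.seed(9)
  X <- matrix(rnorm(60), 20)
  y <- rep(c(-1, 1), 10)
  m1 <- train_svm(X, y, C = 2, kernel_spec("rbf"))
  m2 <- train_fsvm(X, y, rep(1, 20), C = 2, kernel_spec("rbf"))
  expect_equal(m1$alpha_full, m2$alpha_full, tolerance = 1e-6)
  expect_equal(m1$b, m2$b, tolerance = 1e-6)
  Xt <- matrix(rnorm(15), 5)
  expect_equal(predict(m1, Xt)$decision, predict(m2, Xt)$decision,
               tolerance = 1e-6)
})

test_that("a down-weighted mislabeled outlier cannot bend the boundary", {
  # two tight clusters plus one point deep in the -1 cluster labeled +1;
  # at large C the plain RBF-SVM carves a positive island around it
  X <- rbind(c(0, 0), c(0, 1), c(1, 0.5),
             c(5, 0), c(5, 1), c(6, 0.5),
             c(5.5, 0.5))
  y <- c(1, 1, 1, -1, -1, -1, 1)
  C <- 100
  kern <- kernel_spec("rbf", gamma = 0.5)
  clean <- train_svm(X[1:6, ], y[1:6], C, kern)
  s <- c(rep(1, 6), 0.01)
  fuzzy <- train_fsvm(X, y, s, C, kern)
  # the outlier's multiplier is capped at s * C
  expect_lte(fuzzy$alpha_full[7], 0.01 * C + 1e-8)
  # boundary matches the outlier-free SVM near and between the clusters
  grid <- rbind(cbind(seq(0, 6, length.out = 13), 0.5), c(5.5, 0.5))
  expect_equal(predict(fuzzy, grid)$decision, predict(clean, grid)$decision,
               tolerance = 0.15)
  # whereas the plain SVM is pulled over by the outlier
  plain <- train_svm(X, y, C, kern)
  expect_gt(max(abs(predict(plain, grid)$decision -
                    predict(clean, grid)$decision)), 0.5)
})

test_that("the boundary converges to the clean one as membership shrinks", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0.5),
             c(5, 0), c(5, 1), c(6, 0.5),
             c(5.5, 0.5))
  y <- c(1, 1, 1, -1, -1, -1, 1)
  kern <- kernel_spec("rbf", gamma = 0.5)
  clean <- train_svm(X[1:6, ], y[1:6], C = 100, kern)
  grid <- rbind(cbind(seq(0, 6, length.out = 13), 0.5), c(5.5, 0.5))
  f_clean <- predict(clean, grid)$decision
  dist <- vapply(c(1, 0.5, 0.1, 0.01), function(s_out) {
    m <- train_fsvm(X, y, c(rep(1, 6), s_out), C = 100, kern)
    max(abs(predict(m, grid)$decision - f_clean))
  }, numeric(1))
  expect_true(all(diff(dist) <= 1e-8))
  expect_lt(dist[4], 0.15)
})

test_that("Gram matrices are symmetric and positive semi-definite", {
  set.seed(10)
  X <- matrix(rnorm(40), 10)
  for (kern in list(kernel_spec("linear"), kernel_spec("rbf", gamma = 0.7),
                    kernel_spec("polynomial", degree = 2))) {
    K <- wptefsvm:::kernel_matrix(kern, X)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("prediction resolves ties to +1 and is order-invariant", {
  X <- rbind(c(0, 0), c(2, 0))
  m <- train_svm(X, c(-1, 1), C = 100, kernel_spec("linear"))
  expect_identical(predict(m, rbind(c(1, 0)))$label, 1L)  # f = 0 tie
  set.seed(11)
  Xt <- matrix(rnorm(20), 10)
  f <- predict(m, Xt)$decision
  ord <- sample(10)
  expect_equal(predict(m, Xt[ord, ])$decision, f[ord])
  expect_error(predict(m, matrix(1, 2, 5)), "dimension mismatch")
})
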