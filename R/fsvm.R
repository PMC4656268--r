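#' Kernel specification
#'
#' @param type `"linear"`, `"rbf"` or `"polynomial"`.
#' @param gamma RBF width; `NULL` (default) uses the `1 / (p * var(X))`
#'   heuristic computed at training time.
#' @param degree,coef0 Polynomial kernel parameters
#'   `(x'y + coef0)^degree`.
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(type = c("rbf", "linear", "polynomial"),
                        gamma = NULL, degree = 3, coef0 = 1) {
  type <- match.arg(type)
  structure(list(type = type, gamma = gamma, degree = degree, coef0 = coef0),
            class = "kernel_spec")
}

# Gram matrix between rows of A and rows of B.
kernel_matrix <- function(kernel, A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  switch(kernel$type,
    linear = A %*% t(B),
    polynomial = (A %*% t(B) + kernel$coef0)^kernel$degree,
    rbf = {
      g <- kernel$gamma
      if (is.null(g)) stop("rbf gamma not resolved", call. = FALSE)
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      exp(-g * pmax(d2, 0))
    }
  )
}

resolve_kernel <- function(kernel, X) {
  if (kernel$type == "rbf" && is.null(kernel$gamma)) {
    v <- stats::var(as.vector(X))
    kernel$gamma <- if (v > 0) 1 / (ncol(X) * v) else 1
  }
  kernel
}

#' Radius/center fuzzy membership model
#'
#' Fits the class geometry used by the fuzzy membership function: each
#' class's mean vector and its radius — the maximum Euclidean distance from
#' the mean to any member. A sample's membership is
#' \eqn{s = 1 - |x - x_c| / (r_c + \delta)} where `c` is its own class, so
#' training memberships lie in `(0, 1]`, with outliers far from their class
#' center down-weighted.
#'
#' @param X Numeric feature matrix (rows = samples).
#' @param y Labels in `{+1, -1}`; both classes must be present.
#' @param delta Positive stabiliser added to the radius; `NULL` (default)
#'   uses `1e-3 * max(r+, r-)`, floored at `1e-8`, so `s > 0` always.
#' @return A `membership_model` with class centers, radii and `delta`.
#' @export
fit_membership <- function(X, y, delta = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1/-1", call. = FALSE)
  if (!any(y == 1L) || !any(y == -1L))
    stop("both classes must be present to fit memberships", call. = FALSE)
  ctr_pos <- colMeans(X[y == 1L, , drop = FALSE])
  ctr_neg <- colMeans(X[y == -1L, , drop = FALSE])
  dist_to <- function(M, ctr) sqrt(rowSums(sweep(M, 2, ctr)^2))
  r_pos <- max(dist_to(X[y == 1L, , drop = FALSE], ctr_pos))
  r_neg <- max(dist_to(X[y == -1L, , drop = FALSE], ctr_neg))
  if (is.null(delta)) delta <- max(1e-3 * max(r_pos, r_neg), 1e-8)
  stopifnot(delta > 0)
  structure(list(center_pos = ctr_pos, center_neg = ctr_neg,
                 radius_pos = r_pos, radius_neg = r_neg, delta = delta),
            class = "membership_model")
}

#' Fuzzy membership values
#'
#' Evaluates the radius/center membership function of a fitted
#' [fit_membership()] model. Points beyond the training radius (possible
#' only for unseen data) are clamped to a small positive floor.
#'
#' @param model A `membership_model`.
#' @param X Feature matrix (or vector for a single sample).
#' @param y Labels in `{+1, -1}` selecting each sample's own class.
#' @param floor Lower clamp for out-of-radius points (default `1e-6`).
#' @return Memberships in `(0, 1]`.
#' @export
membership <- function(model, X, y, floor = 1e-6) {
  stopifnot(inherits(model, "membership_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  y <- as.integer(y)
  s <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    c_i <- if (y[i] == 1L) model$center_pos else model$center_neg
    r_i <- if (y[i] == 1L) model$radius_pos else model$radius_neg
    d <- sqrt(sum((X[i, ] - c_i)^2))
    s[i] <- 1 - d / (r_i + model$delta)
  }
  pmin(pmax(s, floor), 1)
}

# SMO working-set solver for the dual
#   max_a  sum(a) - 0.5 a' Q a,  Q = (y y') * K
#   s.t.   0 <= a_n <= u_n,  sum(a_n y_n) = 0
# with per-sample upper bounds u_n = s_n * C (u_n = C recovers the plain
# soft-margin SVM). Maximal-violating-pair selection; converged when the
# KKT gap m(a) - M(a) drops below tol.
solve_dual_smo <- function(K, y, upper, tol = 1e-8, max_iter = 1e5) {
  n <- length(y)
  alpha <- numeric(n)
  grad <- rep(-1, n)              # gradient of 0.5 a'Qa - sum(a)
  Q <- K * tcrossprod(y)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    yg <- -y * grad
    up <- (y > 0 & alpha < upper - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < upper - 1e-12)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]
    gap <- yg[i] - yg[j]
    if (gap < tol) break
    if (iter > max_iter)
      stop("SMO did not converge in ", max_iter,
           " iterations (KKT gap ", format(gap), ")", call. = FALSE)
    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    t_step <- gap / max(quad, 1e-12)
    # feasible step range from both boxes
    t_max <- if (y[i] > 0) upper[i] - alpha[i] else alpha[i]
    t_max <- min(t_max, if (y[j] > 0) alpha[j] else upper[j] - alpha[j])
    t_step <- min(t_step, t_max)
    if (t_step <= 0) break
    alpha[i] <- alpha[i] + y[i] * t_step
    alpha[j] <- alpha[j] - y[j] * t_step
    grad <- grad + t_step * (Q[, i] * y[i] - Q[, j] * y[j])
  }
  list(alpha = alpha, grad = grad, iterations = iter,
       objective = sum(alpha) - 0.5 * drop(crossprod(alpha, Q %*% alpha)))
}

# Bias from KKT conditions: average of y_n - f0(x_n) over free support
# vectors, or the midpoint of the feasible interval when none are free.
compute_bias <- function(alpha, grad, y, upper) {
  yg <- -y * grad
  eps <- 1e-8 * max(upper)
  free <- alpha > eps & alpha < upper - eps
  if (any(free)) return(mean(yg[free]))
  lower_set <- (y > 0 & alpha <= eps) | (y < 0 & alpha >= upper - eps)
  upper_set <- (y > 0 & alpha >= upper - eps) | (y < 0 & alpha <= eps)
  b_lo <- if (any(upper_set)) max(yg[upper_set]) else -Inf
  b_hi <- if (any(lower_set)) min(yg[lower_set]) else Inf
  if (is.finite(b_lo) && is.finite(b_hi)) (b_lo + b_hi) / 2
  else if (is.finite(b_lo)) b_lo
  else if (is.finite(b_hi)) b_hi
  else 0
}

fit_dual <- function(X, y, s, C, kernel, tol, max_iter) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1/-1", call. = FALSE)
  if (!any(y == 1L) || !any(y == -1L))
    stop("both classes must be present", call. = FALSE)
  stopifnot(C > 0, all(s > 0), all(s <= 1), length(s) == length(y))
  kernel <- resolve_kernel(kernel, X)
  K <- kernel_matrix(kernel, X)
  upper <- s * C
  sol <- solve_dual_smo(K, y, upper, tol, max_iter)
  b <- compute_bias(sol$alpha, sol$grad, y, upper)
  sv <- sol$alpha > 1e-10 * C
  structure(
    list(alpha = sol$alpha[sv], sv_x = X[sv, , drop = FALSE],
         sv_y = y[sv], b = b, C = C, kernel = kernel, memberships = s,
         sv_index = which(sv), n_train = length(y),
         dual_objective = sol$objective, iterations = sol$iterations,
         alpha_full = sol$alpha),
    class = "fsvm_model"
  )
}

#' Train a soft-margin SVM
#'
#' Maximises the standard dual
#' \eqn{\sum_n \alpha_n - \frac12 \sum_{n,m} \alpha_n \alpha_m y_n y_m
#' K(x_n, x_m)} subject to \eqn{0 \le \alpha_n \le C} and
#' \eqn{\sum_n \alpha_n y_n = 0}, using an SMO-style maximal-violating-pair
#' working-set solver. The bias is the mean over free support vectors of
#' \eqn{y_n - \sum_m \alpha_m y_m K(x_m, x_n)} (midpoint of the feasible
#' KKT interval when no support vector is free).
#'
#' @param X Feature matrix (rows = samples).
#' @param y Labels in `{+1, -1}`, both classes present.
#' @param C Error penalty, `> 0`.
#' @param kernel A [kernel_spec()].
#' @param tol KKT gap tolerance for the solver.
#' @param max_iter Iteration cap (error with diagnostics on overrun).
#' @return An `fsvm_model` with `alpha` (support-vector coefficients),
#'   `sv_x`, `sv_y`, `b`, the resolved kernel, `C`, memberships, and the
#'   attained `dual_objective`.
#' @seealso [train_fsvm()], [predict.fsvm_model()]
#' @export
train_svm <- function(X, y, C = 1, kernel = kernel_spec("rbf"),
                      tol = 1e-8, max_iter = 1e5) {
  fit_dual(X, y, s = rep(1, length(y)), C = C, kernel = kernel,
           tol = tol, max_iter = max_iter)
}

#' Train a fuzzy SVM
#'
#' Identical to [train_svm()] except each sample `n` carries a fuzzy
#' membership \eqn{s_n \in (0, 1]} that scales its slack penalty, which in
#' the dual becomes the per-sample box constraint
#' \eqn{0 \le \alpha_n \le s_n C}. Down-weighting suspect samples
#' (outliers, label noise) caps how much they can bend the decision
#' boundary; with all `s = 1` the fit coincides with the plain SVM.
#'
#' @inheritParams train_svm
#' @param s Memberships in `(0, 1]`, typically from [membership()].
#' @return An `fsvm_model`; see [train_svm()].
#' @export
train_fsvm <- function(X, y, s, C = 1, kernel = kernel_spec("rbf"),
                       tol = 1e-8, max_iter = 1e5) {
  fit_dual(X, y, s = s, C = C, kernel = kernel,
           tol = tol, max_iter = max_iter)
}

#' @export
print.fsvm_model <- function(x, ...) {
  cat("<fsvm_model>", length(x$alpha), "support vectors /", x$n_train,
      "samples | kernel", x$kernel$type, "| C =", x$C, "\n")
  invisible(x)
}

#' Predict with a (fuzzy) SVM model
#'
#' Decision values \eqn{f(x) = \sum_n \alpha_n y_n K(x_n, x) + b}; labels
#' are `sign(f)` with the tie `f = 0` resolved to `+1` (pathological).
#'
#' @param object An `fsvm_model`.
#' @param newdata Feature matrix (or single feature vector).
#' @param ... Unused.
#' @return List with `label` (+1/-1) and `decision` (numeric).
#' @export
predict.fsvm_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$sv_x))
    stop("feature dimension mismatch: model has ", ncol(object$sv_x),
         ", data has ", ncol(newdata), call. = FALSE)
  f <- drop(kernel_matrix(object$kernel, newdata, object$sv_x) %*%
              (object$alpha * object$sv_y)) + object$b
  list(label = ifelse(f >= 0, 1L, -1L), decision = f)
}
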