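# Independent oracles used across the suite. These deliberately take a
# different computational route from the package code they check.

# Dense analysis matrix of the one-level 1D periodic filter bank: lowpass
# rows stacked over highpass rows, each filter placed at stride-2 circular
# shifts.
analysis_matrix <- function(n, h, g) {
  W <- matrix(0, n, n)
  for (k in seq_len(n %/% 2)) {
    for (j in seq_along(h)) {
      col <- ((2 * (k - 1) + j - 1) %% n) + 1
      W[k, col] <- W[k, col] + h[j]
      W[n %/% 2 + k, col] <- W[n %/% 2 + k, col] + g[j]
    }
  }
  W
}

# Full 2D packet tree via explicit matrix products LL = L X L', LH = L X H',
# HL = H X L', HH = H X H', recursively; natural (Paley) child order.
wpt_oracle <- function(x, wavelet_name, level) {
  w <- wavelet_spec(wavelet_name)
  blocks <- list(x)
  for (d in seq_len(level)) {
    n <- nrow(blocks[[1]])
    W <- analysis_matrix(n, w$lowpass, w$highpass)
    L <- W[seq_len(n %/% 2), , drop = FALSE]
    H <- W[(n %/% 2 + 1):n, , drop = FALSE]
    blocks <- unlist(lapply(blocks, function(b) list(
      L %*% b %*% t(L), L %*% b %*% t(H),
      H %*% b %*% t(L), H %*% b %*% t(H))), recursive = FALSE)
  }
  blocks
}

# Brute-force generic QP oracle for the (fuzzy) SVM dual via kernlab::ipop;
# returns the attained dual objective.
qp_dual_objective <- function(X, y, s, C, kernel) {
  K <- wptefsvm:::kernel_matrix(wptefsvm:::resolve_kernel(kernel, X), X)
  Q <- K * tcrossprod(y)
  sol <- kernlab::ipop(c = matrix(-1, length(y)), H = Q + diag(1e-10, length(y)),
                       A = matrix(as.numeric(y), 1), b = 0, r = 0,
                       l = matrix(0, length(y)), u = matrix(s * C, length(y)),
                       sigf = 9, maxiter = 200)
  a <- kernlab::primal(sol)
  sum(a) - 0.5 * drop(crossprod(a, Q %*% a))
}

# WPTE feature matrix for a list of images.
feature_matrix <- function(images, q = 0.8, ...) {
  t(vapply(images, function(im) as.numeric(extract_wpte(im, q = q, ...)),
           numeric(16)))
}

random_dist <- function(z) {
  p <- stats::runif(z)
  p / sum(p)
}
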