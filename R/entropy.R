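#' @title Shannon and Tsallis entropy of discrete distributions
#' @name entropy
#' @description
#' Entropy primitives used to turn wavelet subband coefficient distributions
#' into texture descriptors. Tsallis entropy
#' \eqn{E_q = (\sum_k p_k^q - 1)/(1 - q)} generalises Shannon entropy with a
#' single nonextensivity index `q`; as `q -> 1` it converges to the Shannon
#' entropy in natural-log units. `q < 1` is the subextensive regime,
#' `q > 1` superextensive.
NULL

check_dist <- function(p, tol = 1e-12) {
  if (!is.numeric(p) || length(p) < 1L)
    stop("p must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0))
    stop("probabilities must be finite and nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > max(tol, 1e-8))
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  invisible(p)
}

#' Shannon entropy (bits)
#'
#' \eqn{E = -\sum_k p_k \log_2 p_k}, with \eqn{0 \log 0 = 0}.
#'
#' @param p Probability vector (nonnegative, sums to 1).
#' @param base Logarithm base; 2 (bits) by default, `exp(1)` for nats.
#' @return Entropy in `[0, log(length(p), base)]`.
#' @examples
#' shannon_entropy(rep(1/16, 16))  # 4 bits
#' @export
shannon_entropy <- function(p, base = 2) {
  check_dist(p)
  pos <- p[p > 0]
  -sum(pos * log(pos, base = base))
}

#' Tsallis entropy
#'
#' Nonextensive entropy \eqn{E_q = (\sum_k p_k^q - 1)/(1 - q)} for
#' \eqn{q \ne 1}; at `q = 1` the analytic limit — Shannon entropy in
#' natural-log units — is returned, so the function is continuous in `q`.
#'
#' @inheritParams shannon_entropy
#' @param q Entropic (nonextensivity) index, any real number.
#' @return Nonnegative entropy for `q > 0`.
#' @examples
#' tsallis_entropy(c(0.5, 0.5), q = 0.8)
#' tsallis_entropy(c(0.5, 0.5), q = 1)  # log(2)
#' @export
tsallis_entropy <- function(p, q) {
  check_dist(p)
  stopifnot(is.numeric(q), length(q) == 1L, is.finite(q))
  if (q == 1) return(shannon_entropy(p, base = exp(1)))
  pos <- p[p > 0]
  (sum(pos^q) - 1) / (1 - q)
}

#' Pseudo-additivity residual of Tsallis entropy
#'
#' For independent systems X and Y (joint distribution = outer product),
#' Tsallis entropy satisfies
#' \eqn{E_q(X,Y) = E_q(X) + E_q(Y) + (1-q) E_q(X) E_q(Y)}. Returns the
#' residual of that identity; at `q = 1` it reduces to the additivity of
#' Shannon entropy. Exported as a documentation/verification utility.
#'
#' @param px,py Probability vectors of the two independent subsystems.
#' @param q Entropic index.
#' @return The residual (should be ~0 up to rounding).
#' @export
pseudo_additivity_check <- function(px, py, q) {
  check_dist(px); check_dist(py)
  joint <- as.vector(outer(px, py))
  ej <- tsallis_entropy(joint, q)
  ex <- tsallis_entropy(px, q)
  ey <- tsallis_entropy(py, q)
  ej - (ex + ey + (1 - q) * ex * ey)
}

#' Subband coefficients to a probability distribution
#'
#' Converts a block of wavelet coefficients into the discrete distribution
#' whose entropy is the subband's texture descriptor. The default `"energy"`
#' estimator uses the normalised energy distribution
#' \eqn{p_k = c_k^2 / \sum_j c_j^2} (the standard wavelet-entropy
#' convention); `"histogram"` bins coefficient values into `n_bins`
#' equal-width bins over the block's range. A zero-energy (all-zero) block
#' maps to the degenerate distribution so its entropy is 0.
#'
#' @param coeffs Numeric vector or matrix of coefficients.
#' @param estimator `"energy"` or `"histogram"`.
#' @param n_bins Number of histogram bins (histogram estimator only).
#' @return Probability vector summing to 1.
#' @examples
#' coeffs_to_distribution(c(3, 4))  # c(0.36, 0.64)
#' @export
coeffs_to_distribution <- function(coeffs, estimator = c("energy", "histogram"),
                                   n_bins = 256L) {
  estimator <- match.arg(estimator)
  c_vec <- as.vector(coeffs)
  if (length(c_vec) == 0L) stop("empty subband", call. = FALSE)
  if (any(!is.finite(c_vec)))
    stop("subband contains non-finite coefficients", call. = FALSE)
  if (estimator == "energy") {
    e <- c_vec^2
    tot <- sum(e)
    if (tot == 0) {
      p <- c(1, rep(0, length(c_vec) - 1L))
    } else {
      p <- e / tot
    }
  } else {
    rng <- range(c_vec)
    if (diff(rng) == 0) {
      p <- c(1, rep(0, n_bins - 1L))
    } else {
      breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
      cnt <- tabulate(findInterval(c_vec, breaks, rightmost.closed = TRUE,
                                   all.inside = TRUE), nbins = n_bins)
      p <- cnt / sum(cnt)
    }
  }
  p
}
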