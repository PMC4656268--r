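#' Wavelet filter specification
#'
#' Builds the quadrature-mirror analysis filter pair used by
#' [wpt_decompose()] and [dwt_decompose()]. The high-pass filter is derived
#' from the low-pass taps by the conjugate quadrature rule
#' \eqn{g_j = (-1)^j h_{L-1-j}}, so orthonormal low-pass taps yield an
#' orthonormal two-channel bank.
#'
#' @param name Wavelet family: `"haar"` or `"db2"` (Daubechies, 4 taps).
#' @param boundary Signal extension mode: `"periodic"` (default; gives exact
#'   Parseval energy conservation and perfect reconstruction on dyadic
#'   sizes) or `"symmetric"` (decomposition only).
#' @return An object of class `wavelet_spec` with elements `name`,
#'   `lowpass`, `highpass`, `boundary`.
#' @examples
#' w <- wavelet_spec("haar")
#' sum(w$lowpass^2)  # orthonormal taps: 1
#' @export
wavelet_spec <- function(name = "haar", boundary = c("periodic", "symmetric")) {
  boundary <- match.arg(boundary)
  name <- tolower(name)
  h <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db1  = c(1, 1) / sqrt(2),
    db2  = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    stop("unknown wavelet name: '", name, "' (supported: haar, db2)",
         call. = FALSE)
  )
  if (name == "db1") name <- "haar"
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  stopifnot(abs(sum(h^2) - 1) < 1e-10, abs(sum(g^2) - 1) < 1e-10)
  structure(list(name = name, lowpass = h, highpass = g, boundary = boundary),
            class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat("<wavelet_spec>", x$name, "| taps:", length(x$lowpass),
      "| boundary:", x$boundary, "\n")
  invisible(x)
}

as_wavelet <- function(wavelet, boundary = "periodic") {
  if (inherits(wavelet, "wavelet_spec")) wavelet
  else wavelet_spec(wavelet, boundary)
}

# One analysis step along the rows of X (output has nrow(X)/2 rows):
# y[k, ] = sum_j f[j+1] * X[(2(k-1)+j) mod n + 1, ].  Periodic indexing, or
# whole-point symmetric reflection for "symmetric".
filter_down_rows <- function(X, f, boundary) {
  n <- nrow(X)
  if (n %% 2L != 0L) stop("block length must be even", call. = FALSE)
  n2 <- n %/% 2L
  Y <- matrix(0, n2, ncol(X))
  base <- 2L * (seq_len(n2) - 1L)
  for (j in seq_along(f)) {
    idx <- base + (j - 1L)
    if (boundary == "periodic") {
      idx <- idx %% n
    } else {
      # reflect indices (0-based whole-point symmetric extension)
      per <- 2L * n - 2L
      idx <- idx %% per
      idx <- ifelse(idx >= n, per - idx, idx)
    }
    Y <- Y + f[j] * X[idx + 1L, , drop = FALSE]
  }
  Y
}

# Adjoint of filter_down_rows (periodic only): scatter-add coefficients back.
filter_up_rows <- function(Y, f, n) {
  X <- matrix(0, n, ncol(Y))
  base <- 2L * (seq_len(nrow(Y)) - 1L)
  for (j in seq_along(f)) {
    idx <- (base + (j - 1L)) %% n + 1L
    X[idx, ] <- X[idx, , drop = FALSE] + f[j] * Y
  }
  X
}

# Split one 2D block into its 4 children, ordered LL, LH, HL, HH where the
# first letter is the filter applied along columns (vertical direction) and
# the second along rows (horizontal).
split4 <- function(X, w) {
  lo_v <- filter_down_rows(X, w$lowpass, w$boundary)
  hi_v <- filter_down_rows(X, w$highpass, w$boundary)
  lo_v_t <- t(lo_v); hi_v_t <- t(hi_v)
  list(
    LL = t(filter_down_rows(lo_v_t, w$lowpass,  w$boundary)),
    LH = t(filter_down_rows(lo_v_t, w$highpass, w$boundary)),
    HL = t(filter_down_rows(hi_v_t, w$lowpass,  w$boundary)),
    HH = t(filter_down_rows(hi_v_t, w$highpass, w$boundary))
  )
}

# Inverse of split4 (periodic extension).
merge4 <- function(children, w) {
  n_half <- nrow(children$LL)
  m_half <- ncol(children$LL)
  lo_v <- t(filter_up_rows(t(children$LL), w$lowpass, 2L * m_half)) +
          t(filter_up_rows(t(children$LH), w$highpass, 2L * m_half))
  hi_v <- t(filter_up_rows(t(children$HL), w$lowpass, 2L * m_half)) +
          t(filter_up_rows(t(children$HH), w$highpass, 2L * m_half))
  filter_up_rows(lo_v, w$lowpass, 2L * n_half) +
    filter_up_rows(hi_v, w$highpass, 2L * n_half)
}

pad_to_dyadic <- function(image, level, boundary) {
  mult <- as.integer(2^level)
  nr <- nrow(image); nc <- ncol(image)
  pr <- (mult - nr %% mult) %% mult
  pc <- (mult - nc %% mult) %% mult
  if (pr == 0L && pc == 0L) {
    return(list(image = image, pad = c(0L, 0L)))
  }
  # extend by wrapping (periodic) or reflecting (symmetric)
  ext <- function(n, p, per) {
    extra <- if (per) ((n + seq_len(p) - 1L) %% n) + 1L
             else pmax(1L, n - seq_len(p) + 1L)
    c(seq_len(n), extra)
  }
  per <- boundary == "periodic"
  image <- image[ext(nr, pr, per), ext(nc, pc, per), drop = FALSE]
  list(image = image, pad = c(pr, pc))
}

check_image <- function(image, level) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(image)))
    stop("image contains non-finite intensities", call. = FALSE)
  if (nrow(image) < 2^level || ncol(image) < 2^level)
    stop("image too small for a level-", level, " decomposition ",
         "(need at least ", 2^level, " rows and columns)", call. = FALSE)
}

#' 2D wavelet packet decomposition
#'
#' Separable 2D wavelet packet transform: every block (approximation and
#' detail alike) is re-filtered at each level, so depth `d` yields the full
#' tree of `4^d` terminal subbands, each downsampled by `2^d` per axis.
#' Children follow natural (Paley) order — recursively LL, LH, HL, HH — so
#' channel `m` of a subband at depth `d` is stable across runs and images.
#'
#' Non-dyadic inputs are extended to the next multiple of `2^level` using the
#' wavelet's boundary mode; the padding is recorded in the returned tree.
#'
#' @param image Numeric matrix of finite intensities.
#' @param wavelet A [wavelet_spec()] or a wavelet name.
#' @param level Decomposition depth `d >= 1`.
#' @return A `wpt_tree`: list with `level`, `wavelet`, `source_shape`, `pad`
#'   and `subbands`, an ordered list of `4^level` coefficient matrices named
#'   `m00, m01, ...` by channel index.
#' @seealso [wpt_reconstruct()], [dwt_decompose()]
#' @examples
#' tr <- wpt_decompose(matrix(rnorm(64^2), 64), "haar", 2)
#' length(tr$subbands)  # 16
#' @export
wpt_decompose <- function(image, wavelet = "haar", level = 2L) {
  w <- as_wavelet(wavelet)
  level <- as.integer(level)
  stopifnot(level >= 1L)
  check_image(image, level)
  padded <- pad_to_dyadic(image, level, w$boundary)
  blocks <- list(padded$image)
  for (d in seq_len(level)) {
    blocks <- unlist(lapply(blocks, split4, w = w), recursive = FALSE)
  }
  names(blocks) <- sprintf("m%02d", seq_along(blocks) - 1L)
  structure(
    list(level = level, wavelet = w, source_shape = dim(image),
         pad = padded$pad, subbands = blocks),
    class = "wpt_tree"
  )
}

#' @export
print.wpt_tree <- function(x, ...) {
  cat("<wpt_tree> level", x$level, "|", length(x$subbands), "subbands of",
      paste(dim(x$subbands[[1]]), collapse = "x"), "| wavelet",
      x$wavelet$name, "\n")
  invisible(x)
}

#' Inverse wavelet packet transform
#'
#' Reconstructs the source image from a full packet tree. Exact (to rounding)
#' for orthonormal filters with periodic extension; symmetric-extension trees
#' are refused because the same-length orthogonal bank is not invertible
#' under reflection.
#'
#' @param tree A `wpt_tree` from [wpt_decompose()].
#' @param wavelet Optional wavelet; must match the tree's (a mismatch in the
#'   declared name is a configuration error).
#' @return Numeric matrix with the tree's `source_shape`.
#' @export
wpt_reconstruct <- function(tree, wavelet = NULL) {
  stopifnot(inherits(tree, "wpt_tree"))
  w <- if (is.null(wavelet)) tree$wavelet else as_wavelet(wavelet)
  if (w$name != tree$wavelet$name)
    stop("wavelet '", w$name, "' does not match the tree's '",
         tree$wavelet$name, "'", call. = FALSE)
  if (tree$wavelet$boundary != "periodic")
    stop("reconstruction supported for periodic extension only",
         call. = FALSE)
  blocks <- tree$subbands
  for (d in seq_len(tree$level)) {
    blocks <- lapply(seq_len(length(blocks) %/% 4L), function(i) {
      ch <- blocks[(4L * (i - 1L) + 1L):(4L * i)]
      names(ch) <- c("LL", "LH", "HL", "HH")
      merge4(ch, w)
    })
  }
  out <- blocks[[1]]
  out[seq_len(tree$source_shape[1]), seq_len(tree$source_shape[2]),
      drop = FALSE]
}

#' 2D discrete wavelet transform (Mallat pyramid)
#'
#' Standard DWT: only the approximation block is re-split at each level,
#' giving `3*level + 1` subbands. At depth 1 this coincides with
#' [wpt_decompose()]. Provided for DWT-vs-WPT comparisons and baseline
#' features.
#'
#' @inheritParams wpt_decompose
#' @return A `dwt_pyramid`: list with `level`, `wavelet`, `source_shape` and
#'   `subbands` — the final approximation `a<level>` followed by detail
#'   triplets `h/v/d` per level (coarsest first).
#' @export
dwt_decompose <- function(image, wavelet = "haar", level = 2L) {
  w <- as_wavelet(wavelet)
  level <- as.integer(level)
  stopifnot(level >= 1L)
  check_image(image, level)
  padded <- pad_to_dyadic(image, level, w$boundary)
  approx <- padded$image
  details <- list()
  for (d in seq_len(level)) {
    ch <- split4(approx, w)
    approx <- ch$LL
    details <- c(stats::setNames(
      list(ch$LH, ch$HL, ch$HH),
      paste0(c("h", "v", "d"), d)), details)
  }
  subbands <- c(stats::setNames(list(approx), paste0("a", level)), details)
  structure(
    list(level = level, wavelet = w, source_shape = dim(image),
         pad = padded$pad, subbands = subbands),
    class = "dwt_pyramid"
  )
}

#' @export
print.dwt_pyramid <- function(x, ...) {
  cat("<dwt_pyramid> level", x$level, "|", length(x$subbands),
      "subbands | wavelet", x$wavelet$name, "\n")
  invisible(x)
}

#' Export subbands as PNG images
#'
#' Writes each subband of a packet tree or DWT pyramid to `dir` as an
#' individually min-max scaled grayscale PNG, for visual inspection of the
#' decomposition.
#'
#' @param x A `wpt_tree` or `dwt_pyramid`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
export_subbands <- function(x, dir) {
  stopifnot(inherits(x, c("wpt_tree", "dwt_pyramid")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(x$subbands), function(nm) {
    b <- x$subbands[[nm]]
    rng <- range(b)
    img <- if (diff(rng) > 0) (b - rng[1]) / diff(rng) else b * 0
    p <- file.path(dir, paste0(nm, ".png"))
    png::writePNG(img, p)
    p
  }, character(1))
  invisible(paths)
}
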