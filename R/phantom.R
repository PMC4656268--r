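#' Phantom generator configuration
#'
#' Parameters of the synthetic two-class brain phantom. Defaults mirror the
#' structure of a small imbalanced pathological-brain benchmark: 66 images
#' (18 healthy, 48 pathological), 256x256 grayscale, lesions expressed as
#' irregular blobs that shift local intensity and raise local texture
#' variance.
#'
#' @param n_healthy,n_pathological Class sizes.
#' @param size Image side in pixels.
#' @param lesion_intensity Mean intensity shift of a lesion relative to the
#'   surrounding tissue (0 disables the intensity cue).
#' @param lesion_texture_sd Extra Gaussian noise s.d. inside lesions (0
#'   disables the texture cue).
#' @param lesion_count_range Integer range of lesions per pathological
#'   image.
#' @param texture_noise_sd Background tissue noise s.d.
#' @param label_flip_fraction Fraction of samples whose *training* label is
#'   flipped (planted outliers; true labels are kept alongside).
#' @param seed RNG seed for the whole dataset.
#' @return A `phantom_config` list.
#' @seealso [phantom_preset()], [generate_dataset()]
#' @export
phantom_config <- function(n_healthy = 18L, n_pathological = 48L,
                           size = 256L, lesion_intensity = 0.30,
                           lesion_texture_sd = 0.10,
                           lesion_count_range = c(1L, 3L),
                           texture_noise_sd = 0.02,
                           label_flip_fraction = 0, seed = 1L) {
  stopifnot(n_healthy >= 0, n_pathological >= 0, size >= 4,
            lesion_intensity >= 0, lesion_texture_sd >= 0,
            texture_noise_sd >= 0,
            label_flip_fraction >= 0, label_flip_fraction < 1)
  structure(list(
    n_healthy = as.integer(n_healthy),
    n_pathological = as.integer(n_pathological),
    size = as.integer(size),
    lesion_intensity = lesion_intensity,
    lesion_texture_sd = lesion_texture_sd,
    lesion_count_range = as.integer(lesion_count_range),
    texture_noise_sd = texture_noise_sd,
    label_flip_fraction = label_flip_fraction,
    seed = as.integer(seed)), class = "phantom_config")
}

#' Named phantom presets
#'
#' * `"easy"` — the defaults: clear lesion intensity and texture contrast;
#'   the feature classes separate well and both SVM and FSVM should score
#'   highly.
#' * `"null"` — lesion cues switched off entirely, so the two class
#'   generators are statistically identical and any classifier can only
#'   perform at the majority-class rate.
#' * `"outlier"` — the easy conditions plus 10% of training labels flipped,
#'   the scenario where membership-weighted training is expected to beat
#'   the plain SVM.
#'
#' @param name `"easy"`, `"null"` or `"outlier"`.
#' @param ... Overrides passed to [phantom_config()].
#' @return A `phantom_config`.
#' @export
phantom_preset <- function(name = c("easy", "null", "outlier"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    easy = list(),
    null = list(lesion_intensity = 0, lesion_texture_sd = 0),
    outlier = list(label_flip_fraction = 0.10)
  )
  do.call(phantom_config, utils::modifyList(args, list(...)))
}

# Soft-edged ellipse indicator on the pixel grid: 1 inside, cosine rolloff
# over `edge` pixels.
soft_ellipse <- function(rows, cols, cy, cx, ry, rx, edge = 2) {
  d <- sqrt(outer((rows - cy)^2 / ry^2, (cols - cx)^2 / rx^2, "+"))
  w <- (1 - (d - 1) * ry / edge)
  pmin(pmax(w, 0), 1)
}

# Irregular blob mask: ellipse whose radius is modulated by low-order
# angular harmonics (perturbed-ellipse boundary).
blob_mask <- function(rows, cols, cy, cx, r0, aspect, harm_amp, harm_ph) {
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  theta <- atan2(dy, dx)
  rr <- r0 * (1 + Reduce(`+`, lapply(seq_along(harm_amp), function(h)
    harm_amp[h] * cos((h + 1) * theta + harm_ph[h]))))
  d <- sqrt((dy / aspect)^2 + (dx * aspect)^2)
  d <= rr
}

#' Generate one brain phantom image
#'
#' Healthy phantoms are an elliptical brain mask with a smooth radial
#' intensity gradient, two ventricle-like dark ellipses, and Gaussian
#' texture noise. Pathological phantoms add 1..k hyper- or hypo-intense
#' lesion blobs with perturbed-ellipse boundaries and locally raised
#' texture variance. Deterministic given `seed`; pixel values in `[0, 1]`.
#'
#' @param class `"healthy"` or `"pathological"`.
#' @param config A [phantom_config()].
#' @param seed Seed for this image.
#' @return Numeric matrix in `[0, 1]` of side `config$size`.
#' @export
generate_phantom <- function(class = c("healthy", "pathological"),
                             config = phantom_config(), seed = 1L) {
  class <- match.arg(class)
  s <- config$size
  rows <- seq_len(s); cols <- seq_len(s)
  with_seed(seed, {
    cy <- s / 2 + stats::rnorm(1, 0, s / 64)
    cx <- s / 2 + stats::rnorm(1, 0, s / 64)
    ry <- s * stats::runif(1, 0.38, 0.42)
    rx <- s * stats::runif(1, 0.32, 0.36)
    brain <- soft_ellipse(rows, cols, cy, cx, ry, rx, edge = s / 64)
    # radial gradient: tissue brighter mid-radius, darker at the rim
    d <- sqrt(outer((rows - cy)^2 / ry^2, (cols - cx)^2 / rx^2, "+"))
    img <- brain * (0.55 + 0.20 * (1 - d^2))
    # ventricles: paired dark ellipses flanking the midline
    for (side in c(-1, 1)) {
      v <- soft_ellipse(rows, cols, cy - 0.05 * s,
                        cx + side * 0.07 * s,
                        0.12 * s * stats::runif(1, 0.9, 1.1),
                        0.035 * s * stats::runif(1, 0.9, 1.1),
                        edge = s / 128)
      img <- img - 0.25 * v
    }
    noise_sd <- matrix(config$texture_noise_sd, s, s)
    if (class == "pathological") {
      k <- sample(seq(config$lesion_count_range[1],
                      config$lesion_count_range[2]), 1L)
      for (i in seq_len(k)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0.15, 0.65)
        lcy <- cy + rad * ry * sin(ang)
        lcx <- cx + rad * rx * cos(ang)
        r0 <- s * stats::runif(1, 0.05, 0.10)
        m <- blob_mask(rows, cols, lcy, lcx, r0,
                       aspect = stats::runif(1, 0.8, 1.25),
                       harm_amp = stats::runif(4, 0, 0.15),
                       harm_ph = stats::runif(4, 0, 2 * pi))
        sign_i <- sample(c(-1, 1), 1L)
        img[m] <- img[m] + sign_i * config$lesion_intensity
        noise_sd[m] <- noise_sd[m] + config$lesion_texture_sd
      }
    }
    img <- img + matrix(stats::rnorm(s * s, 0, 1), s, s) * noise_sd * brain
    pmin(pmax(img, 0), 1)
  })
}

#' Generate a labelled phantom dataset
#'
#' Produces `n_healthy + n_pathological` phantom images with labels (+1 =
#' pathological, -1 = healthy) in a shuffled order, optionally writing them
#' to disk as PNGs with a `manifest.csv` (`path,label`). When
#' `label_flip_fraction > 0`, a `train_label` column carries the corrupted
#' copy (planted outliers); `label` always holds the truth.
#'
#' @param config A [phantom_config()] or [phantom_preset()].
#' @param dir Optional output directory for PNGs + manifest.
#' @return List with `images` (list of matrices), `manifest` (data frame
#'   with `label`, `train_label`, and `path` if written), and `config`.
#' @export
generate_dataset <- function(config = phantom_config(), dir = NULL) {
  n <- config$n_healthy + config$n_pathological
  labels <- rep(c(-1L, 1L), c(config$n_healthy, config$n_pathological))
  ord <- with_seed(config$seed, sample.int(n))
  labels <- labels[ord]
  images <- lapply(seq_len(n), function(i) {
    generate_phantom(if (labels[i] == 1L) "pathological" else "healthy",
                     config, seed = config$seed * 10000L + i)
  })
  train_label <- labels
  if (config$label_flip_fraction > 0 && n > 0) {
    n_flip <- max(1L, round(config$label_flip_fraction * n))
    flip <- with_seed(config$seed + 7L, sample.int(n, n_flip))
    train_label[flip] <- -train_label[flip]
  }
  manifest <- data.frame(label = labels, train_label = train_label)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    manifest$path <- file.path(dir, sprintf("phantom_%03d.png", seq_len(n)))
    for (i in seq_len(n)) png::writePNG(images[[i]], manifest$path[i])
    utils::write.csv(manifest[, c("path", "label", "train_label")],
                     file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(images = images, manifest = manifest, config = config)
}
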