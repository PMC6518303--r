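# Seeded synthetic multi-class image data. Each class owns a parametric
# prototype (ellipse phantoms + oriented sinusoid + smoothed random texture);
# images perturb the prototype with affine jitter, illumination changes and
# pixel noise, emulating the intra-class variance / inter-class similarity
# structure of heterogeneous medical image collections.

gaussian_blur_matrix <- function(side, sigma) {
  i <- seq_len(side)
  G <- exp(-outer(i, i, "-")^2 / (2 * sigma^2))
  sweep(G, 1, rowSums(G), "/")
}

class_prototype <- function(side, rng_seed) {
  with_seed(rng_seed, {
    y <- matrix(seq_len(side), side, side)
    x <- matrix(seq_len(side), side, side, byrow = TRUE)
    img <- matrix(0, side, side)
    for (b in seq_len(sample(2:4, 1))) {
      cy <- stats::runif(1, 0.25, 0.75) * side
      cx <- stats::runif(1, 0.25, 0.75) * side
      ay <- stats::runif(1, 0.08, 0.35) * side
      ax <- stats::runif(1, 0.08, 0.35) * side
      th <- stats::runif(1, 0, pi)
      dy <- (y - cy)
      dx <- (x - cx)
      u <- cos(th) * dx + sin(th) * dy
      v <- -sin(th) * dx + cos(th) * dy
      img <- img + stats::runif(1, 0.4, 1) *
        exp(-((u / ax)^2 + (v / ay)^2))
    }
    ang <- stats::runif(1, 0, pi)
    freq <- stats::runif(1, 1.5, 4) * 2 * pi / side
    img <- img + 0.25 * sin(freq * (cos(ang) * x + sin(ang) * y))
    G <- gaussian_blur_matrix(side, side / 16)
    img <- img + 0.35 * (G %*% matrix(stats::rnorm(side^2), side) %*% t(G)) *
      side / 8
    rng <- range(img)
    0.1 + 0.8 * (img - rng[1]) / (rng[2] - rng[1])
  })
}

#' Synthetic dataset specification
#'
#' @param K number of classes (>= 2).
#' @param n_per_class images per class.
#' @param image_side image side in pixels.
#' @param channels per-class channel counts (1 = grayscale modality such as
#'   CT/MRI/X-ray, 3 = color modality such as endoscopy/retina); a single
#'   value recycles, the default alternates.
#' @param noise_sd pixel noise standard deviation (intensity units).
#' @param illumination half-range of the multiplicative illumination jitter.
#' @param affine_magnitude scale of the geometric jitter in \[0, 1\]
#'   (1 corresponds to rotations up to 20 degrees and shifts up to 10% of the
#'   side).
#' @param similarity_pairs list of `c(a, b, s)` triples forcing class b's
#'   prototype to share a fraction `s` in \[0, 1\] of class a's prototype.
#' @param seed master seed; everything generated is a pure function of the
#'   spec.
#' @return a `cbmir_synthetic_spec`.
#' @export
synthetic_spec <- function(K, n_per_class, image_side = 64L,
                           channels = NULL, noise_sd = 0.02,
                           illumination = 0.1, affine_magnitude = 0.25,
                           similarity_pairs = list(), seed = 1L) {
  K <- as.integer(K)
  n_per_class <- as.integer(n_per_class)
  if (K < 2L) stop("K must be >= 2")
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  if (is.null(channels)) channels <- rep(c(1L, 3L), length.out = K)
  channels <- rep(as.integer(channels), length.out = K)
  if (!all(channels %in% c(1L, 3L))) stop("channels must be 1 or 3")
  for (p in similarity_pairs) {
    if (length(p) != 3L || p[1] < 1 || p[2] < 1 || p[1] > K || p[2] > K ||
          p[3] < 0 || p[3] > 1) {
      stop("similarity pairs must be (class a, class b, similarity in [0,1])")
    }
  }
  structure(list(K = K, n_per_class = n_per_class,
                 image_side = as.integer(image_side), channels = channels,
                 noise_sd = noise_sd, illumination = illumination,
                 affine_magnitude = affine_magnitude,
                 similarity_pairs = similarity_pairs,
                 seed = as.integer(seed)),
            class = "cbmir_synthetic_spec")
}

synth_image <- function(proto, channels, spec, rng_seed) {
  with_seed(rng_seed, {
    side <- spec$image_side
    a <- spec$affine_magnitude
    img <- proto
    if (a > 0) {
      img <- affine_image(img,
                          angle = stats::runif(1, -20 * a, 20 * a),
                          tx = stats::runif(1, -0.1 * a, 0.1 * a) * side,
                          ty = stats::runif(1, -0.1 * a, 0.1 * a) * side)
    }
    gain <- 1 + stats::runif(1, -spec$illumination, spec$illumination)
    img <- img * gain
    if (channels == 3L) {
      w <- attr(proto, "colw")  # class-level tint, fixed across the class
      img <- array(rep(img, 3) * rep(w, each = side^2), c(side, side, 3L))
    }
    if (spec$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    }
    round(pmin(pmax(img, 0), 1) * 255) / 255
  })
}

#' Generate a synthetic labeled image dataset
#'
#' Writes `K * n_per_class` PNG images (BMP on request) under
#' `out_dir/class_<k>/` plus `manifest.csv`, fully determined by the spec's
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir writable output directory (created if needed).
#' @param format "png" (default) or "bmp"; both are lossless.
#' @return the manifest data.frame (`path`, `class_id`, `channels`,
#'   `digest`), invisibly written to `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(spec, out_dir, format = c("png", "bmp")) {
  stopifnot(inherits(spec, "cbmir_synthetic_spec"))
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  protos <- synthetic_prototypes(spec)
  rows <- list()
  for (k in seq_len(spec$K)) {
    cls_dir <- file.path(out_dir, sprintf("class_%02d", k))
    dir.create(cls_dir, showWarnings = FALSE)
    for (i in seq_len(spec$n_per_class)) {
      img <- synth_image(protos[[k]], spec$channels[k], spec,
                         rng_seed = spec$seed + 100003L * k + 17L * i)
      rel <- file.path(sprintf("class_%02d", k),
                       sprintf("img_%04d.%s", i, format))
      save_image(img, file.path(out_dir, rel))
      rows[[length(rows) + 1L]] <-
        data.frame(path = rel, class_id = k, channels = spec$channels[k],
                   digest = unname(tools::md5sum(file.path(out_dir, rel))))
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "base_dir") <- normalizePath(out_dir)
  manifest
}

# class prototypes after applying similarity sharing
synthetic_prototypes <- function(spec) {
  protos <- lapply(seq_len(spec$K), function(k) {
    p <- class_prototype(spec$image_side, spec$seed + 7907L * k)
    attr(p, "colw") <- with_seed(spec$seed + 7907L * k + 1L,
                                 stats::runif(3, 0.6, 1))
    p
  })
  for (p in spec$similarity_pairs) {
    a <- as.integer(p[1])
    b <- as.integer(p[2])
    s <- p[3]
    cw <- attr(protos[[b]], "colw")
    protos[[b]] <- s * protos[[a]] + (1 - s) * protos[[b]]
    attr(protos[[b]], "colw") <- cw
  }
  protos
}

#' Gaussian feature-space fixture
#'
#' Draws K isotropic Gaussian clusters in feature space whose centroids are
#' mutually `separation * sd` apart (vertices of a scaled simplex), giving a
#' direct handle on classification difficulty without touching images.
#'
#' @param K number of classes.
#' @param n vectors per class.
#' @param dim feature dimensionality (>= K for exact equidistance).
#' @param separation centroid separation in units of the noise sd.
#' @param sd isotropic noise standard deviation.
#' @param seed RNG seed.
#' @return a [feature_store()] with `true_centroids` attached as an
#'   attribute.
#' @export
make_feature_fixture <- function(K, n, dim, separation, sd = 1, seed = 1L) {
  if (dim < 1L) stop("dim must be >= 1")
  if (separation < 0) stop("separation must be >= 0")
  if (dim < K) stop("dim must be >= K so centroids can be equidistant")
  centroids <- diag(separation * sd / sqrt(2), K, dim)
  with_seed(seed, {
    feats <- matrix(stats::rnorm(K * n * dim, 0, sd), K * n, dim)
    labels <- rep(seq_len(K), each = n)
    feats <- feats + centroids[labels, , drop = FALSE]
    st <- feature_store(feats, labels)
    attr(st, "true_centroids") <- centroids
    st
  })
}
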