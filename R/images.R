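#' Image ensembles with controlled statistical structure
#'
#' An `image_set` is an ordered collection of grayscale images (matrices with
#' values in \[0,1\], all of the same height H and width W), optionally
#' labeled, optionally with a known intrinsic (embedding) dimension d. Images
#' are consumed by the reservoir as multivariate time series: rows are the
#' H = L1 input features, columns are the W = L2 time steps.
#'
#' @name image_set
NULL

new_image_set <- function(images, labels = NULL, intrinsic_dim = NULL,
                          seed = NULL, generator = "manual",
                          prerescale = NULL, templates = NULL) {
  stopifnot(is.list(images), length(images) >= 1L)
  h <- nrow(images[[1L]]); w <- ncol(images[[1L]])
  for (im in images) {
    if (!is.matrix(im) || nrow(im) != h || ncol(im) != w)
      stop("all images must be matrices of identical dimensions")
    if (anyNA(im) || min(im) < 0 || max(im) > 1)
      stop("pixel values must lie in [0,1]")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != length(images)) stop("one label per image required")
    f <- max(labels) + 1L
    if (min(labels) < 0L) stop("labels must be integers in [0, F)")
    if (!all((seq_len(f) - 1L) %in% labels))
      stop("every class in [0, F) must occur at least once")
  }
  structure(
    list(images = images, labels = labels, intrinsic_dim = intrinsic_dim,
         seed = seed, generator = generator, prerescale = prerescale,
         templates = templates),
    class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  h <- nrow(x$images[[1L]]); w <- ncol(x$images[[1L]])
  cat(sprintf("<image_set> %d images of %dx%d (generator: %s)\n",
              length(x$images), h, w, x$generator))
  if (!is.null(x$labels))
    cat("  classes:", paste(names(table(x$labels)), collapse = " "), "\n")
  if (!is.null(x$intrinsic_dim))
    cat("  intrinsic dimension d =", x$intrinsic_dim, "\n")
  invisible(x)
}

#' @export
length.image_set <- function(x) length(x$images)

# dimensions of the images in a set, c(H, W)
image_dim <- function(x) c(nrow(x$images[[1L]]), ncol(x$images[[1L]]))

# Spatially smooth Gaussian random field (periodic), via low-pass filtered
# white noise in Fourier space. `smoothness` is the correlation length as a
# fraction of the larger image side.
gaussian_random_field <- function(height, width, smoothness) {
  fy <- c(seq(0, floor(height / 2)), seq(-(ceiling(height / 2) - 1), -1)) / height
  fx <- c(seq(0, floor(width / 2)),  seq(-(ceiling(width / 2) - 1), -1)) / width
  f2 <- outer(fy^2, fx^2, `+`)                    # (cycles/pixel)^2
  len_pix <- max(smoothness * max(height, width), 1e-8)
  fc <- 1 / len_pix                               # cutoff frequency
  filt <- exp(-f2 / (2 * fc^2))
  noise <- matrix(stats::rnorm(height * width), height, width)
  Re(stats::fft(stats::fft(noise) * filt, inverse = TRUE)) / (height * width)
}

#' Generate images confined to a d-dimensional linear subspace
#'
#' Each image is a linear combination of `d` fixed, spatially smooth,
#' mutually orthonormal basis patterns with i.i.d. standard-normal latent
#' coordinates, then affinely rescaled into \[0,1\] using the global ensemble
#' minimum and maximum. Because the rescaling is affine (no clipping), the
#' mean-centered ensemble has rank exactly `d` both before and after it; the
#' pre-rescale flattened ensemble is kept in the returned object for exact
#' rank checks.
#'
#' @param n_images Number of images M (must exceed `d`).
#' @param height,width Image dimensions in pixels.
#' @param d Intrinsic dimension of the ensemble (>= 1, <= height*width).
#' @param smoothness Correlation length of the basis patterns as a fraction
#'   of the larger image side.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An [image_set] with `intrinsic_dim = d` and a `prerescale`
#'   component (M x H*W matrix of pre-rescale flattened images).
#' @export
generate_lowrank_images <- function(n_images, height, width, d,
                                    smoothness = 0.2, seed = 1L) {
  if (height < 1 || width < 1) stop("invalid dimension: height/width must be positive")
  if (d < 1) stop("invalid dimension: d must be >= 1")
  if (d > height * width) stop("invalid dimension: d exceeds the number of pixels")
  if (n_images <= d) stop("insufficient samples: n_images must exceed d")
  p <- height * width
  with_seed(seed, {
    raw <- vapply(seq_len(d),
                  function(j) as.vector(gaussian_random_field(height, width, smoothness)),
                  numeric(p))
    basis <- qr.Q(qr(matrix(raw, p, d)))          # p x d orthonormal patterns
    latents <- matrix(stats::rnorm(n_images * d), n_images, d)
    flat <- latents %*% t(basis)                  # M x p, rank d a.s.
  })
  flat01 <- rescale01(flat)
  images <- lapply(seq_len(n_images),
                   function(i) matrix(flat01[i, ], height, width))
  new_image_set(images, intrinsic_dim = d, seed = seed,
                generator = "lowrank", prerescale = flat)
}

#' Generate naturalistic images with a power-law spatial spectrum
#'
#' Random-phase images whose isotropic spatial power spectrum decays as
#' (spatial frequency)^(-beta), emulating the 1/f^beta statistics of natural
#' scenes. beta = 0 gives white noise. Each image is synthesized by filtering
#' white Gaussian noise in Fourier space with amplitude f^(-beta/2) (DC term
#' zeroed), then min-max rescaled into \[0,1\], per image by default.
#'
#' @param n_images Number of images.
#' @param height,width Image dimensions in pixels.
#' @param spectral_slope Power-spectrum decay exponent beta >= 0.
#' @param seed Integer seed.
#' @param normalize `"image"` (each image spans \[0,1\]) or `"ensemble"`
#'   (one global affine rescale).
#' @return An [image_set].
#' @export
generate_naturalistic_images <- function(n_images, height, width,
                                         spectral_slope = 2, seed = 1L,
                                         normalize = c("image", "ensemble")) {
  if (n_images < 1) stop("invalid dimension: n_images must be >= 1")
  if (height < 1 || width < 1) stop("invalid dimension: height/width must be positive")
  if (spectral_slope < 0) stop("spectral_slope must be >= 0")
  normalize <- match.arg(normalize)
  fy <- c(seq(0, floor(height / 2)), seq(-(ceiling(height / 2) - 1), -1)) / height
  fx <- c(seq(0, floor(width / 2)),  seq(-(ceiling(width / 2) - 1), -1)) / width
  f <- sqrt(outer(fy^2, fx^2, `+`))
  amp <- f
  amp[1, 1] <- 1
  amp <- amp^(-spectral_slope / 2)
  amp[1, 1] <- 0                                   # zero-mean fields
  raw <- with_seed(seed, lapply(seq_len(n_images), function(i) {
    noise <- matrix(stats::rnorm(height * width), height, width)
    Re(stats::fft(stats::fft(noise) * amp, inverse = TRUE)) / (height * width)
  }))
  images <- if (normalize == "image") {
    lapply(raw, rescale01)
  } else {
    r <- range(unlist(raw))
    lapply(raw, function(im) (im - r[1]) / (r[2] - r[1]))
  }
  new_image_set(images, seed = seed, generator = "naturalistic")
}

#' Generate a labeled multi-class image ensemble
#'
#' Each of the F classes is defined by a distinct smooth template (a Gaussian
#' luminance blob at a class-specific position); images are the template plus
#' pixelwise zero-mean Gaussian noise of scale `noise_sd`, clipped to \[0,1\].
#' Classes are well separated by construction, so a nearest-template pixel
#' classifier is essentially perfect at small noise.
#'
#' @param n_per_class Images per class.
#' @param n_classes Number of classes F (>= 2).
#' @param height,width Image dimensions in pixels.
#' @param noise_sd Pixel noise standard deviation.
#' @param seed Integer seed.
#' @return An [image_set] with integer labels in \[0, F) (`n_per_class` of
#'   each, class-major order) and the class templates in `$templates`.
#' @export
generate_labeled_images <- function(n_per_class, n_classes, height, width,
                                    noise_sd = 0.05, seed = 1L) {
  if (n_classes < 2) stop("invalid class count: n_classes must be >= 2")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  cy <- height / 2 + 0.5; cx <- width / 2 + 0.5
  rad <- 0.30 * min(height, width)
  sig <- 0.16 * min(height, width)
  templates <- lapply(seq_len(n_classes) - 1L, function(k) {
    ang <- 2 * pi * k / n_classes
    my <- cy + rad * sin(ang); mx <- cx + rad * cos(ang)
    g <- outer(seq_len(height), seq_len(width),
               function(y, x) exp(-((y - my)^2 + (x - mx)^2) / (2 * sig^2)))
    0.1 + 0.8 * g / max(g)
  })
  labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  images <- with_seed(seed, lapply(labels, function(k) {
    im <- templates[[k + 1L]]
    if (noise_sd > 0)
      im <- im + matrix(stats::rnorm(height * width, sd = noise_sd), height, width)
    pmin(pmax(im, 0), 1)
  }))
  new_image_set(images, labels = labels, seed = seed,
                generator = "labeled", templates = templates)
}

#' Convert an image into a multivariate input time series
#'
#' The image's vertical dimension becomes the feature vector (L1 = H
#' elements) and the horizontal dimension becomes time: step t is column t,
#' left to right, with T = L2 = W steps. No value transformation is applied.
#'
#' @param image An H x W matrix with values in \[0,1\].
#' @param source_image_index Optional index of the image in its ensemble.
#' @return An `input_sequence`: the L1 x T matrix of input columns, carrying
#'   `source_image_index` as an attribute.
#' @export
image_to_sequence <- function(image, source_image_index = NA_integer_) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (anyNA(image) || min(image) < 0 || max(image) > 1)
    stop("normalization error: pixel values must lie in [0,1]")
  structure(image, class = "input_sequence",
            source_image_index = as.integer(source_image_index))
}

# stack the columns of all images in order into one L1 x (T*M) drive matrix
image_set_drive <- function(image_set) {
  do.call(cbind, image_set$images)
}

#' Radially averaged spatial power spectrum of an ensemble
#'
#' Averages |FFT|^2 over images (after removing each image's mean), then bins
#' by integer radial frequency. Used to verify the spectral slope of
#' generated ensembles.
#'
#' @param image_set An [image_set].
#' @return A data.frame with columns `freq` (cycles per image, >= 1) and
#'   `power` (mean spectral power in the radial bin).
#' @export
radial_power_spectrum <- function(image_set) {
  h <- nrow(image_set$images[[1L]]); w <- ncol(image_set$images[[1L]])
  acc <- matrix(0, h, w)
  for (im in image_set$images) {
    im <- im - mean(im)
    acc <- acc + Mod(stats::fft(im))^2
  }
  acc <- acc / length(image_set$images)
  ky <- c(seq(0, floor(h / 2)), seq(-(ceiling(h / 2) - 1), -1))
  kx <- c(seq(0, floor(w / 2)), seq(-(ceiling(w / 2) - 1), -1))
  r <- sqrt(outer((ky / h)^2, (kx / w)^2, `+`)) * max(h, w)
  rint <- round(r)
  keep <- rint >= 1 & rint <= floor(min(h, w) / 2)
  pw <- tapply(acc[keep], rint[keep], mean)
  fbar <- tapply(r[keep], rint[keep], mean)   # mean radius, not bin label:
  # within a shell the power varies as f^-beta, so labeling the bin by its
  # integer index would bias the log-log slope
  data.frame(freq = as.numeric(fbar), power = as.numeric(pw))
}
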