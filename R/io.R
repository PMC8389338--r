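#' Image and ensemble I/O
#'
#' Individual images round-trip through 8-bit grayscale PNG (value v maps
#' to round(255 v)). Whole ensembles use a plain-text bundle — a directory
#' holding `meta.json` (dimensions, seed, generator, intrinsic dimension,
#' labels) and `images.csv` (one row per image, flattened column-major) —
#' which preserves full double precision and is the canonical interchange
#' format.
#'
#' @name image_io
NULL

#' Write a grayscale image as 8-bit PNG
#'
#' @param image H x W matrix in \[0,1\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  if (anyNA(image) || min(image) < 0 || max(image) > 1)
    stop("normalization error: pixel values must lie in [0,1]")
  png::writePNG(image, target = path)
  invisible(path)
}

#' Read a grayscale PNG image
#'
#' Color PNGs are converted to grayscale by channel averaging.
#'
#' @param path PNG file path.
#' @return H x W matrix in \[0,1\].
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE],
                                       c(1, 2), mean)
  a
}

#' Write an image ensemble as a plain-text bundle
#'
#' @param image_set An [image_set].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_image_set <- function(image_set, dir) {
  stopifnot(inherits(image_set, "image_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hw <- image_dim(image_set)
  meta <- list(height = hw[1], width = hw[2],
               n_images = length(image_set$images),
               seed = image_set$seed, generator = image_set$generator,
               intrinsic_dim = image_set$intrinsic_dim,
               labels = image_set$labels)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  flat <- t(vapply(image_set$images, as.vector, numeric(prod(hw))))
  utils::write.table(flat, file.path(dir, "images.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read an image ensemble written by [write_image_set()]
#'
#' @param dir Bundle directory.
#' @return An [image_set].
#' @export
read_image_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(dir, "images.csv"), sep = ","))
  images <- lapply(seq_len(nrow(flat)),
                   function(i) matrix(flat[i, ], meta$height, meta$width))
  new_image_set(images,
                labels = if (length(meta$labels)) meta$labels else NULL,
                intrinsic_dim = meta$intrinsic_dim,
                seed = meta$seed, generator = meta$generator %||% "manual")
}

#' Read MNIST-style IDX image and label files
#'
#' Standard big-endian IDX format (magic 2051 for images, 2049 for labels),
#' as distributed for MNIST. Pixel values are rescaled from 0-255 to
#' \[0,1\].
#'
#' @param image_path,label_path Paths to the IDX files (uncompressed).
#' @param limit Optional cap on the number of items read.
#' @return `read_idx_images`: an [image_set] (labels attached when
#'   `label_path` is given); `read_idx_labels`: integer vector.
#' @export
read_idx_images <- function(image_path, label_path = NULL, limit = NULL) {
  con <- file(image_path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic != 2051L) stop("not an IDX image file (magic != 2051)")
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  h <- readBin(con, "integer", 1, size = 4, endian = "big")
  w <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!is.null(limit)) n <- min(n, limit)
  raw <- readBin(con, "integer", n * h * w, size = 1, signed = FALSE)
  images <- lapply(seq_len(n), function(i) {
    block <- raw[((i - 1) * h * w + 1):(i * h * w)]
    matrix(block, h, w, byrow = TRUE) / 255
  })
  labels <- if (!is.null(label_path)) read_idx_labels(label_path, limit = n)
  new_image_set(images, labels = labels, generator = "idx")
}

#' @rdname read_idx_images
#' @export
read_idx_labels <- function(label_path, limit = NULL) {
  con <- file(label_path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic != 2049L) stop("not an IDX label file (magic != 2049)")
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!is.null(limit)) n <- min(n, limit)
  readBin(con, "integer", n, size = 1, signed = FALSE)
}
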