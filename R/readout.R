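#' Reservoir-model-space encoding and ridge readout
#'
#' Each image's reservoir dynamics is summarized by ridge-fitting the linear
#' one-step model `x(t+1) = W_x x(t) + w_x` to the image's trajectory; the
#' parameter vector `theta = (vec(W_x); w_x)` of length N(N+1) is the
#' image's feature ("reservoir model space"). A linear output layer
#' `y = W_out theta + w_out`, trained by ridge regression against one-hot
#' class targets, performs the classification.
#'
#' @name readout
NULL

#' Encode a trajectory in the reservoir model space
#'
#' Solves the multi-output ridge problem
#' `argmin sum_t ||x(t+1) - W_x x(t) - w_x||^2 + lambda ||W_x||_F^2`
#' over the trajectory's T-1 transitions (bias unpenalized), and returns
#' `theta = c(vec(W_x), w_x)` (column-major vec), of length N(N+1).
#'
#' @param trajectory N x T `state_trajectory` (or plain matrix), T >= 3.
#' @param ridge_penalty Ridge penalty lambda_r > 0.
#' @return A `model_space_encoding` list: `theta`, `n_units`,
#'   `ridge_penalty`, `source_image_index`.
#' @export
encode_reservoir_model <- function(trajectory, ridge_penalty = 1) {
  if (ridge_penalty <= 0) stop("invalid penalty: ridge_penalty must be > 0")
  x <- unclass(trajectory)
  if (!is.matrix(x)) stop("trajectory must be a matrix")
  n <- nrow(x); tt <- ncol(x)
  if (tt < 3) stop("insufficient transitions: need T >= 3")
  xp <- x[, -tt, drop = FALSE]               # x(t)
  xn <- x[, -1L, drop = FALSE]               # x(t+1)
  z <- rbind(xp, 1)                          # (N+1) x (T-1)
  a <- tcrossprod(z)
  diag(a) <- diag(a) + c(rep(ridge_penalty, n), 0)
  cf <- solve(a, z %*% t(xn))                # (N+1) x N: [W_x'; w_x']
  w_x <- t(cf[seq_len(n), , drop = FALSE])
  w_bias <- cf[n + 1L, ]
  structure(list(theta = c(as.vector(w_x), w_bias),
                 n_units = n, ridge_penalty = ridge_penalty,
                 source_image_index = attr(trajectory, "source_image_index")),
            class = "model_space_encoding")
}

#' Encode every image of an ensemble in the reservoir model space
#'
#' Runs the reservoir over each image (reset-per-image recommended) and
#' encodes each trajectory with [encode_reservoir_model()].
#'
#' @param weights A `reservoir_weights` object.
#' @param image_set An [image_set].
#' @param config A [reservoir_config()].
#' @param ridge_penalty Model-space ridge penalty lambda_r.
#' @param rng_stream Noise-stream seed if the dynamics is noisy.
#' @return M x N(N+1) matrix of encodings (one row per image).
#' @export
encode_images <- function(weights, image_set, config, ridge_penalty = 1,
                          rng_stream = NULL) {
  m <- length(image_set$images)
  n <- nrow(weights$W_res)
  out <- matrix(0, m, n * (n + 1L))
  for (i in seq_len(m)) {
    stream_i <- if (is.null(rng_stream)) NULL else derive_seed(rng_stream, i)
    traj <- run_sequence(weights, image_to_sequence(image_set$images[[i]], i),
                         config, rng_stream = stream_i)
    out[i, ] <- encode_reservoir_model(traj, ridge_penalty)$theta
  }
  out
}

#' One-hot encode integer class labels
#'
#' @param labels Integer labels in \[0, F).
#' @param n_classes Number of classes F >= 2.
#' @return length(labels) x F matrix of exact one-hot rows.
#' @export
one_hot <- function(labels, n_classes) {
  if (n_classes < 2) stop("invalid class count: n_classes must be >= 2")
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= n_classes)) stop("invalid label: outside [0, F)")
  y <- matrix(0, length(labels), n_classes)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}

#' Train the linear output layer by ridge regression
#'
#' Fits `y = W_out theta + w_out` against one-hot targets by ridge
#' regression with an unpenalized bias. Features are optionally standardized
#' (per-dimension z-score over the training set; the parameters are frozen
#' and reapplied at prediction time). When the feature dimension exceeds the
#' sample count the dual (kernel) form of the ridge solution is used; the
#' two forms agree exactly.
#'
#' @param encodings M x P feature matrix (rows = images), or a list of
#'   `model_space_encoding` objects.
#' @param labels Integer labels in \[0, F).
#' @param ridge_penalty Output ridge penalty lambda_o > 0.
#' @param n_classes Number of classes (default: max(labels)+1).
#' @param standardize Z-score features before the regression (default TRUE).
#' @return A `readout_model` with `coef` (P x F), `intercept` (length F),
#'   feature `center`/`scale`, `n_classes`, `ridge_penalty`.
#' @export
train_readout <- function(encodings, labels, ridge_penalty = 1,
                          n_classes = NULL, standardize = TRUE) {
  if (ridge_penalty <= 0) stop("invalid penalty: ridge_penalty must be > 0")
  x <- encodings_matrix(encodings)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) stop("shape error: one label per encoding required")
  if (length(unique(labels)) < 2) stop("degenerate training: need >= 2 classes present")
  f <- n_classes %||% (max(labels) + 1L)
  y <- one_hot(labels, f)
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0] <- 1
  } else {
    center <- colMeans(x)      # centering alone keeps the bias unpenalized
    scale <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, center), 2, scale, `/`)
  ybar <- colMeans(y)
  yc <- sweep(y, 2, ybar)
  p <- ncol(xs); m <- nrow(xs)
  if (p <= m) {
    g <- crossprod(xs)
    diag(g) <- diag(g) + ridge_penalty
    coef <- solve(g, crossprod(xs, yc))
  } else {
    k <- tcrossprod(xs)
    diag(k) <- diag(k) + ridge_penalty
    coef <- crossprod(xs, solve(k, yc))
  }
  structure(list(coef = coef, intercept = ybar, center = center,
                 scale = scale, n_classes = f, ridge_penalty = ridge_penalty,
                 standardize = standardize),
            class = "readout_model")
}

encodings_matrix <- function(encodings) {
  if (is.matrix(encodings)) return(encodings)
  if (is.list(encodings) && all(vapply(encodings, inherits, logical(1), "model_space_encoding")))
    return(do.call(rbind, lapply(encodings, `[[`, "theta")))
  stop("encodings must be a matrix or a list of model_space_encoding objects")
}

#' Predict class labels from encodings
#'
#' @param object A `readout_model`.
#' @param encodings M x P matrix or list of encodings.
#' @param ... Unused.
#' @return Integer predicted labels in \[0, F); ties at the argmax are
#'   broken toward the lowest class index.
#' @export
predict.readout_model <- function(object, encodings, ...) {
  x <- encodings_matrix(encodings)
  if (ncol(x) != length(object$center)) stop("shape error: feature dimension mismatch")
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, `/`)
  scores <- xs %*% object$coef
  scores <- sweep(scores, 2, object$intercept, `+`)
  max.col(scores, ties.method = "first") - 1L
}

#' Evaluate a readout on labeled encodings
#'
#' @param model A `readout_model`.
#' @param encodings M x P matrix or list of encodings.
#' @param labels True integer labels in \[0, F).
#' @return A `classification_report`: `error_rate`, `confusion` (F x F,
#'   true class x predicted class), `n_evaluated`.
#' @export
evaluate_readout <- function(model, encodings, labels) {
  labels <- as.integer(labels)
  pred <- predict(model, encodings)
  if (length(labels) != length(pred)) stop("shape error: one label per encoding required")
  f <- model$n_classes
  confusion <- table(factor(labels, levels = 0:(f - 1L)),
                     factor(pred, levels = 0:(f - 1L)))
  confusion <- matrix(as.integer(confusion), f, f,
                      dimnames = list(true = 0:(f - 1L), pred = 0:(f - 1L)))
  structure(list(error_rate = mean(pred != labels),
                 confusion = confusion,
                 n_evaluated = length(labels)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> error rate %.4f over %d instances\n",
              x$error_rate, x$n_evaluated))
  invisible(x)
}
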