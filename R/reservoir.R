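#' Reservoir configuration
#'
#' Parameters of an echo state network reservoir: size, sparsity, spectral
#' radius rho, input scaling epsilon, dynamical noise amplitude xi, and the
#' simulation policy (state reset between images, washout).
#'
#' The reservoir dynamics is
#' \deqn{x(t) = \tanh(\epsilon W_{in} u(t) + W_{res} x(t-1) + \xi \eta(t))}
#' with eta i.i.d. standard-normal per unit and step when xi > 0.
#'
#' @param n_units Number of reservoir units N.
#' @param spectral_radius Target spectral radius rho >= 0 of the reservoir
#'   weight matrix (primary order/chaos control knob).
#' @param input_scaling Input gain epsilon >= 0.
#' @param density Fraction of nonzero reservoir weights (default 0.10).
#' @param noise_amplitude White-noise amplitude xi >= 0 inside the
#'   activation function (default 0, deterministic dynamics).
#' @param seed Integer seed for weight generation.
#' @param state_reset_policy `"reset-per-image"` (each image starts from the
#'   zero state; images are independent classification instances) or
#'   `"carry-over"`.
#' @param washout Non-negative number of initial states discarded per
#'   sequence.
#' @return A `reservoir_config` list.
#' @export
reservoir_config <- function(n_units, spectral_radius, input_scaling = 1,
                             density = 0.1, noise_amplitude = 0, seed = 1L,
                             state_reset_policy = c("reset-per-image", "carry-over"),
                             washout = 0L) {
  state_reset_policy <- match.arg(state_reset_policy)
  if (n_units < 1) stop("invalid parameter: n_units must be >= 1")
  if (density <= 0 || density > 1) stop("invalid parameter: density must be in (0,1]")
  if (spectral_radius < 0) stop("invalid parameter: spectral_radius must be >= 0")
  if (input_scaling < 0) stop("invalid parameter: input_scaling must be >= 0")
  if (noise_amplitude < 0) stop("invalid parameter: noise_amplitude must be >= 0")
  if (washout < 0) stop("invalid parameter: washout must be >= 0")
  structure(list(n_units = as.integer(n_units),
                 spectral_radius = spectral_radius,
                 input_scaling = input_scaling,
                 density = density,
                 noise_amplitude = noise_amplitude,
                 seed = as.integer(seed),
                 state_reset_policy = state_reset_policy,
                 washout = as.integer(washout)),
            class = "reservoir_config")
}

#' Build random reservoir and input weights
#'
#' Samples a sparse N x N reservoir matrix (nonzero entries uniform on
#' \[-1,1\] at the configured density) and rescales it so its largest
#' eigenvalue magnitude equals the target spectral radius; samples a dense
#' N x L1 input matrix uniform on \[-1,1\] (input gain epsilon is applied at
#' run time, not baked into the weights).
#'
#' @param config A [reservoir_config()].
#' @param n_inputs Input dimension L1 (image height).
#' @return A `reservoir_weights` list: `W_res` (sparse), `W_in` (dense),
#'   `achieved_spectral_radius`, `raw_spectral_radius`, `n_inputs`, `seed`.
#' @export
build_reservoir <- function(config, n_inputs) {
  stopifnot(inherits(config, "reservoir_config"))
  if (n_inputs < 1) stop("invalid parameter: n_inputs must be >= 1")
  n <- config$n_units
  rho <- config$spectral_radius
  out <- with_seed(config$seed, {
    w <- Matrix::rsparsematrix(n, n, nnz = max(1L, round(config$density * n * n)),
                               rand.x = function(k) stats::runif(k, -1, 1))
    w_in <- matrix(stats::runif(n * n_inputs, -1, 1), n, n_inputs)
    list(w = w, w_in = w_in)
  })
  raw_sr <- spectral_radius(out$w)
  if (rho > 0 && raw_sr == 0)
    stop("degenerate matrix: sampled reservoir has zero spectral radius; use a different seed")
  w_res <- if (rho == 0) out$w * 0 else out$w * (rho / raw_sr)
  structure(list(W_res = w_res, W_in = out$w_in,
                 achieved_spectral_radius = rho,
                 raw_spectral_radius = raw_sr,
                 n_inputs = as.integer(n_inputs),
                 seed = config$seed),
            class = "reservoir_weights")
}

#' @export
print.reservoir_weights <- function(x, ...) {
  cat(sprintf("<reservoir_weights> N=%d, L1=%d, rho=%.4g, nnz=%d\n",
              nrow(x$W_res), x$n_inputs, x$achieved_spectral_radius,
              Matrix::nnzero(x$W_res)))
  invisible(x)
}

#' Advance the reservoir by one step
#'
#' Computes `tanh(eps * W_in %*% u + W_res %*% x + xi * eta)`. When the
#' noise amplitude is zero the noise draw is ignored.
#'
#' @param weights A `reservoir_weights` object.
#' @param state Length-N state vector x(t-1).
#' @param input Length-L1 input vector u(t), values in \[0,1\].
#' @param config The [reservoir_config()].
#' @param noise_draw Optional length-N standard-normal vector eta(t);
#'   required when `noise_amplitude > 0`.
#' @return The length-N next state.
#' @export
reservoir_step <- function(weights, state, input, config, noise_draw = NULL) {
  n <- nrow(weights$W_res)
  if (length(state) != n) stop("shape error: state must have length N")
  if (length(input) != weights$n_inputs) stop("shape error: input must have length L1")
  pre <- config$input_scaling * as.numeric(weights$W_in %*% input) +
    as.numeric(weights$W_res %*% state)
  if (config$noise_amplitude > 0) {
    if (is.null(noise_draw)) stop("noise_draw required when noise_amplitude > 0")
    if (length(noise_draw) != n) stop("shape error: noise_draw must have length N")
    pre <- pre + config$noise_amplitude * noise_draw
  }
  tanh(pre)
}

# draw an N x T standard-normal noise block from a dedicated stream seed,
# leaving the caller's RNG untouched
noise_block <- function(n, t, rng_stream) {
  with_seed(rng_stream, matrix(stats::rnorm(n * t), n, t))
}

#' Run the reservoir over one input sequence
#'
#' Iterates the reservoir map over the columns of the input sequence,
#' discarding the first `washout` states. With noise enabled, all noise
#' draws come from the dedicated `rng_stream` seed, so two runs with the
#' same weights and input but different streams share the signal and differ
#' only in noise (the setting cross-validated PCA requires).
#'
#' @param weights A `reservoir_weights` object.
#' @param sequence An `input_sequence` (or plain L1 x T matrix in \[0,1\]).
#' @param config The [reservoir_config()].
#' @param initial_state Length-N start state (default: zero vector).
#' @param rng_stream Integer seed for the noise stream (required if
#'   `noise_amplitude > 0`).
#' @return A `state_trajectory`: N x (T - washout) matrix of activations.
#' @export
run_sequence <- function(weights, sequence, config, initial_state = NULL,
                         rng_stream = NULL) {
  u <- unclass(sequence)
  if (!is.matrix(u) || ncol(u) == 0) stop("empty input: sequence has no steps")
  if (nrow(u) != weights$n_inputs) stop("shape error: sequence rows must equal L1")
  n <- nrow(weights$W_res)
  tt <- ncol(u)
  if (config$washout >= tt) stop("washout leaves no states")
  x <- if (is.null(initial_state)) numeric(n) else {
    if (length(initial_state) != n) stop("shape error: initial_state must have length N")
    as.numeric(initial_state)
  }
  xi <- config$noise_amplitude
  eta <- NULL
  if (xi > 0) {
    if (is.null(rng_stream)) stop("rng_stream required when noise_amplitude > 0")
    eta <- noise_block(n, tt, rng_stream)
  }
  win_u <- config$input_scaling * (weights$W_in %*% u)   # N x T, precomputed
  w <- weights$W_res
  states <- matrix(0, n, tt)
  for (t in seq_len(tt)) {
    pre <- win_u[, t] + as.numeric(w %*% x)
    if (xi > 0) pre <- pre + xi * eta[, t]
    x <- tanh(pre)
    states[, t] <- x
  }
  if (config$washout > 0) states <- states[, -seq_len(config$washout), drop = FALSE]
  structure(states, class = "state_trajectory",
            source_image_index = attr(sequence, "source_image_index"),
            washout = config$washout)
}

#' Run the reservoir over a whole image ensemble
#'
#' Concatenates per-image trajectories in image order (image-major,
#' time-minor) into the N x (T' * M) activity matrix, where T' = T - washout.
#' State handling between images follows `config$state_reset_policy`.
#'
#' @param weights A `reservoir_weights` object.
#' @param image_set An [image_set] (all images the same shape).
#' @param config The [reservoir_config()].
#' @param rng_stream Integer noise-stream seed (required if noisy); each
#'   image gets an independent sub-stream derived from it.
#' @return N x (T' * M) activity matrix with attribute `block_width` = T'.
#' @export
run_ensemble <- function(weights, image_set, config, rng_stream = NULL) {
  stopifnot(inherits(image_set, "image_set"))
  m <- length(image_set$images)
  tt <- ncol(image_set$images[[1L]]) - config$washout
  if (tt < 1) stop("washout leaves no states")
  n <- nrow(weights$W_res)
  if (config$noise_amplitude > 0 && is.null(rng_stream))
    stop("rng_stream required when noise_amplitude > 0")
  out <- matrix(0, n, tt * m)
  state <- numeric(n)
  for (i in seq_len(m)) {
    seq_i <- image_to_sequence(image_set$images[[i]], i)
    stream_i <- if (is.null(rng_stream)) NULL else derive_seed(rng_stream, i)
    init <- if (config$state_reset_policy == "reset-per-image") NULL else state
    traj <- run_sequence(weights, seq_i, config, initial_state = init,
                         rng_stream = stream_i)
    out[, ((i - 1L) * tt + 1L):(i * tt)] <- traj
    state <- traj[, ncol(traj)]
  }
  structure(out, block_width = tt, n_images = m,
            state_reset_policy = config$state_reset_policy)
}
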