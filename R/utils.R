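# Internal helpers: reproducible RNG scoping, seed derivation, spectral radius.

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-unit-of-work seed from a master seed
#'
#' Counter-based derivation so that grid points, trials and noise streams get
#' reproducible, mutually distinct seeds regardless of execution order. The
#' result always fits in a 32-bit signed integer.
#'
#' @param master Integer master seed.
#' @param index Non-negative integer counter (grid-point index, repeat id...).
#' @return A positive integer seed.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  # affine congruential mix; doubles hold the intermediate exactly (< 2^53)
  v <- (abs(as.double(master)) %% 2147483629) * 48271 + 7919 * (as.double(index) + 1)
  as.integer(v %% 2147483629) + 1L
}

#' Spectral radius of a square matrix
#'
#' Largest eigenvalue magnitude, computed by dense eigendecomposition.
#'
#' @param m A square matrix (base or \pkg{Matrix}).
#' @return Non-negative scalar.
#' @export
spectral_radius <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("spectral_radius() needs a square matrix")
  if (all(m == 0)) return(0)
  max(Mod(eigen(m, only.values = TRUE)$values))
}

# min-max rescale of a numeric array onto [0,1]; degenerate range maps to 0.5
rescale01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(array(0.5, dim = dim(x) %||% length(x)))
  (x - r[1]) / (r[2] - r[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
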