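# Shared small fixtures, built in code at test time.

tiny_images <- function(m = 6, h = 12, w = 12, seed = 42) {
  generate_naturalistic_images(m, h, w, spectral_slope = 2, seed = seed)
}

small_reservoir <- function(n = 50, rho = 0.9, eps = 0.5, seed = 8,
                            n_inputs = 12, ...) {
  config <- reservoir_config(n, spectral_radius = rho, input_scaling = eps,
                             seed = seed, ...)
  list(config = config, weights = build_reservoir(config, n_inputs))
}

# naive two-trajectory MLE oracle: log-separation slope before saturation,
# no renormalization
naive_mle_oracle <- function(weights, horizon = 80, gamma0 = 1e-10) {
  n <- nrow(weights$W_res)
  xa <- numeric(n); xb <- xa; xb[1] <- gamma0
  seps <- numeric(horizon)
  for (t in seq_len(horizon)) {
    xa <- tanh(as.numeric(weights$W_res %*% xa))
    xb <- tanh(as.numeric(weights$W_res %*% xb))
    seps[t] <- sqrt(sum((xa - xb)^2))
  }
  k <- which(seps > 1e-300 & seps < 1e-3)
  unname(stats::coef(stats::lm(log(seps[k]) ~ k))[2])
}

# brute-force ridge oracle via the penalized normal equations, bias
# unpenalized; returns [W'; w'] coefficients for targets Y' ~ [X; 1]'
ridge_oracle <- function(x_pred, y_resp, lambda) {
  z <- rbind(x_pred, 1)
  p <- nrow(x_pred)
  a <- z %*% t(z) + diag(c(rep(lambda, p), 0))
  solve(a, z %*% t(y_resp))
}

# drop class/attributes, keep dim: for value-level matrix comparisons
unattr <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}
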