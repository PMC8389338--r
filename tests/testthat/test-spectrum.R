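test_that("eigenspectrum recovers exact diagonal covariances and is rotation invariant", {
  # rows mutually orthogonal, zero mean, population variances 3, 2, 1
  a <- rbind(c(1, -1, 1, -1) * sqrt(3),
             c(1, 1, -1, -1) * sqrt(2),
             c(1, -1, -1, 1))
  es <- compute_eigenspectrum(a)
  expect_equal(es$variances, c(3, 2, 1), tolerance = 1e-12)

  set.seed(2)
  x <- matrix(stats::rnorm(40 * 300), 40)
  r <- qr.Q(qr(matrix(stats::rnorm(1600), 40)))
  e1 <- compute_eigenspectrum(x)$variances
  e2 <- compute_eigenspectrum(r %*% x)$variances
  expect_equal(e2, e1, tolerance = 1e-10)

  expect_error(compute_eigenspectrum(matrix(1, 3, 1)), "insufficient samples")
})

test_that("variance is conserved and spectra are non-negative and sorted", {
  set.seed(7)
  for (i in 1:5) {
    x <- matrix(stats::rnorm(30 * 100, sd = stats::runif(1, 0.5, 3)), 30)
    es <- compute_eigenspectrum(x)
    expect_equal(sum(es$variances), es$total_variance,
                 tolerance = 1e-10 * es$total_variance)
    expect_true(all(diff(es$variances) <= 1e-12))
    expect_true(all(es$variances >= 0))
  }
})

test_that("linear-regime activity rank equals the linear-map oracle rank", {
  # tiny input scaling and rho = 0: the reservoir is an affine map of the
  # drive, so its spectrum has exactly rank(eps * W_in %*% U_centered)
  # numerically nonzero eigenvalues
  imgs <- generate_lowrank_images(40, 10, 6, d = 3, seed = 5)
  cfg <- reservoir_config(80, spectral_radius = 0, input_scaling = 1e-4, seed = 2)
  w <- build_reservoir(cfg, 10)
  act <- run_ensemble(w, imgs, cfg)
  es <- compute_eigenspectrum(act)
  u <- do.call(cbind, imgs$images)
  oracle <- 1e-4 * (w$W_in %*% u)
  oracle_rank <- sum(svd(oracle - rowMeans(oracle))$d^2 > 1e-12 * max(svd(oracle - rowMeans(oracle))$d)^2)
  n_nonzero <- sum(es$variances > 1e-12 * es$variances[1])
  expect_identical(n_nonzero, oracle_rank)
})

test_that("power-law fits recover exact and sampled exponents", {
  for (a0 in c(1.0, 1.5)) {
    f <- fit_powerlaw((1:1000)^(-a0), rank_range = c(1, 1000))
    expect_equal(f$alpha, a0, tolerance = 1e-6)
  }
  # default rank range starts at 11
  fd <- fit_powerlaw(compute_eigenspectrum(matrix(stats::rnorm(3000), 30)))
  expect_identical(fd$rank_range, c(11L, 30L))

  # Clauset ML on samples from a known continuous power law
  set.seed(12)
  x <- (1 - stats::runif(3000))^(-1 / 1.5)    # alpha = 2.5, xmin = 1
  pm <- powerlaw_ml(x)
  expect_equal(pm$alpha, 2.5, tolerance = 0.1)
  expect_gte(pm$xmin, 1)

  expect_error(fit_powerlaw((1:5)^-1, rank_range = c(1, 5)), "fit error")
})

test_that("regression and Clauset-ML routes agree on jittered power laws", {
  set.seed(4)
  for (a0 in c(0.8, 1.0, 1.5)) {
    v <- sort((1:1000)^(-a0) * exp(stats::rnorm(1000, sd = 0.1)),
              decreasing = TRUE)
    fr <- fit_powerlaw(v, "loglog-regression", c(11, 500))
    fc <- fit_powerlaw(v, "clauset-ml", c(11, 500))
    expect_lt(abs(fr$alpha - fc$alpha), 0.15)
  }
})

test_that("cvPCA reduces to plain PCA for identical repeats", {
  set.seed(3)
  x <- matrix(stats::rnorm(50 * 400), 50)
  cv <- cvpca(x, x)
  es <- compute_eigenspectrum(x)
  expect_equal(cv$signal_variances, es$variances,
               tolerance = 1e-12 * es$variances[1])
  expect_error(cvpca(x, x[, 1:10]), "shape error")
})

test_that("cvPCA is unbiased: null is zero and a known signal is recovered", {
  # independent pure-noise repeats: mean signal variance is 0 up to MC error
  means <- vapply(1:20, function(i) {
    set.seed(i)
    a <- matrix(stats::rnorm(60 * 1000), 60)
    b <- matrix(stats::rnorm(60 * 1000), 60)
    mean(cvpca(a, b)$signal_variances)
  }, numeric(1))
  expect_lt(abs(mean(means)), 3 * stats::sd(means) / sqrt(length(means)) + 1e-3)

  # signal + independent noise: top signal variances recovered
  set.seed(5)
  n <- 60; s <- 2000
  s_true <- 5 * (1:n)^-1
  a_mix <- qr.Q(qr(matrix(stats::rnorm(n * n), n))) %*% diag(sqrt(s_true))
  signal <- a_mix %*% matrix(stats::rnorm(n * s), n, s)
  x1 <- signal + 0.25 * matrix(stats::rnorm(n * s), n, s)
  x2 <- signal + 0.25 * matrix(stats::rnorm(n * s), n, s)
  cv <- cvpca(x1, x2)
  rel <- abs(cv$signal_variances[1:10] - s_true[1:10]) / s_true[1:10]
  expect_lt(mean(rel), 0.1)
})

test_that("the continuity bound and manifold classification follow the spectral rule", {
  expect_identical(cplusd_threshold(4), 1.5)
  expect_identical(cplusd_threshold(8), 1.25)
  expect_identical(cplusd_threshold(Inf), 1)
  expect_error(cplusd_threshold(0.5), "invalid dimension")

  expect_identical(as.character(classify_manifold(0.8, 4)), "neither")
  expect_identical(as.character(classify_manifold(1.3, 4)),
                   "continuous-not-differentiable")
  expect_identical(as.character(classify_manifold(1.3, 8)), "C+D")
  expect_identical(as.character(classify_manifold(1.3, Inf)), "C+D")
  # boundary values take the weaker class and are flagged
  b1 <- classify_manifold(1, 4)
  expect_identical(as.character(b1), "neither")
  expect_true(attr(b1, "boundary"))
  b2 <- classify_manifold(1.5, 4)
  expect_identical(as.character(b2), "continuous-not-differentiable")
  expect_true(attr(b2, "boundary"))
})
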