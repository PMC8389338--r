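test_that("spectral radius contract holds across sizes and seeds", {
  set.seed(1)
  sizes <- sample(c(50L, 200L, 1000L), 50, replace = TRUE,
                  prob = c(0.45, 0.45, 0.10))
  for (i in seq_along(sizes)) {
    rho <- stats::runif(1, 0.1, 2.5)
    cfg <- reservoir_config(sizes[i], spectral_radius = rho, seed = 1000L + i)
    w <- build_reservoir(cfg, 10)
    expect_lt(abs(spectral_radius(w$W_res) - rho) / rho, 1e-6)
  }
})

test_that("reservoir sampling honors density, range and the zero-radius case", {
  cfg <- reservoir_config(500, spectral_radius = 1.2, density = 0.1, seed = 3)
  w <- build_reservoir(cfg, 20)
  nnz <- Matrix::nnzero(w$W_res)
  # 99% binomial band around density * N^2
  expected <- 0.1 * 500^2
  band <- 2.576 * sqrt(500^2 * 0.1 * 0.9)
  expect_gt(nnz, expected - band)
  expect_lt(nnz, expected + band)
  # pre-scaling entries are uniform [-1,1]: undo the scaling and check range
  raw <- as.numeric(w$W_res@x) * (w$raw_spectral_radius / 1.2)
  expect_gt(min(raw), -1)
  expect_lt(max(raw), 1)
  expect_gt(min(w$W_in), -1)
  expect_lt(max(w$W_in), 1)

  cfg0 <- reservoir_config(50, spectral_radius = 0, seed = 3)
  w0 <- build_reservoir(cfg0, 5)
  expect_identical(Matrix::nnzero(w0$W_res), 0L)

  expect_error(reservoir_config(50, spectral_radius = -1), "invalid parameter")
})

test_that("single steps follow the activation map and stay bounded", {
  r <- small_reservoir(n = 40, rho = 0.8, eps = 0.5, n_inputs = 6)
  z <- numeric(40)
  expect_identical(reservoir_step(r$weights, z, numeric(6), r$config), z)

  x <- stats::runif(40, -0.9, 0.9)
  u <- stats::runif(6)
  out <- reservoir_step(r$weights, x, u, r$config)
  expect_true(all(abs(out) < 1))

  # small-signal regime: tanh is linear to cubic order
  xs <- x * 1e-5; us <- u * 1e-5
  lin <- r$config$input_scaling * as.numeric(r$weights$W_in %*% us) +
    as.numeric(r$weights$W_res %*% xs)
  expect_lt(max(abs(reservoir_step(r$weights, xs, us, r$config) - lin)), 1e-12)

  expect_error(reservoir_step(r$weights, z[1:10], u, r$config), "shape error")
})

test_that("sequence runs are deterministic and respect the no-recurrence case", {
  r <- small_reservoir(n = 30, rho = 0, eps = 0.7, n_inputs = 8)
  u <- matrix(0.3, 8, 20)
  traj <- run_sequence(r$weights, u, r$config)
  expected <- tanh(0.7 * as.numeric(r$weights$W_in %*% rep(0.3, 8)))
  for (t in 1:20) expect_equal(unclass(traj)[, t], expected, tolerance = 1e-15)

  r2 <- small_reservoir(n = 30, rho = 0.9, eps = 0.5, n_inputs = 8)
  t1 <- run_sequence(r2$weights, u, r2$config)
  t2 <- run_sequence(r2$weights, u, r2$config)
  expect_identical(t1, t2)

  expect_error(run_sequence(r$weights, matrix(0.1, 8, 0), r$config), "empty input")
})

test_that("noise streams share signal but differ in noise", {
  cfg <- reservoir_config(50, 0.9, 0.6, noise_amplitude = 0.4, seed = 21)
  w <- build_reservoir(cfg, 12)
  img <- generate_naturalistic_images(1, 12, 40, 2, seed = 3)
  sq <- image_to_sequence(img$images[[1]])
  t1 <- run_sequence(w, sq, cfg, rng_stream = 101)
  t2 <- run_sequence(w, sq, cfg, rng_stream = 202)
  expect_false(identical(t1, t2))
  # per-unit time averages correlate strongly: the signal is shared
  expect_gt(stats::cor(rowMeans(t1), rowMeans(t2)), 0.9)
  # same stream reproduces bitwise
  expect_identical(t1, run_sequence(w, sq, cfg, rng_stream = 101))
  expect_error(run_sequence(w, sq, cfg), "rng_stream")
})

test_that("ensemble runs concatenate image blocks correctly", {
  imgs <- tiny_images(m = 3, h = 12, w = 28)
  r <- small_reservoir(n = 50, rho = 0.9, eps = 0.5, n_inputs = 12)
  act <- run_ensemble(r$weights, imgs, r$config)
  expect_identical(dim(act), c(50L, 84L))
  for (i in 1:3) {
    solo <- run_sequence(r$weights, image_to_sequence(imgs$images[[i]]), r$config)
    expect_identical(act[, ((i - 1) * 28 + 1):(i * 28)], unattr(solo))
  }
  # M = 1 equals a single sequence run
  one <- imgs; one$images <- imgs$images[1]
  expect_identical(unattr(run_ensemble(r$weights, one, r$config))[, 1:28],
                   unattr(run_sequence(r$weights,
                                       image_to_sequence(imgs$images[[1]]),
                                       r$config)))
})

test_that("carry-over and reset policies differ from the second image on", {
  imgs <- tiny_images(m = 3, h = 12, w = 28)
  r_reset <- small_reservoir(n = 50, rho = 0.9, eps = 0.5, n_inputs = 12)
  cfg_carry <- reservoir_config(50, 0.9, 0.5, seed = 8,
                                state_reset_policy = "carry-over")
  act_reset <- run_ensemble(r_reset$weights, imgs, r_reset$config)
  act_carry <- run_ensemble(r_reset$weights, imgs, cfg_carry)
  expect_identical(act_reset[, 1:28], act_carry[, 1:28])
  expect_false(identical(act_reset[, 29:84], act_carry[, 29:84]))

  # with rho = 0 the state does not propagate, so the policies agree
  r0 <- small_reservoir(n = 50, rho = 0, eps = 0.5, n_inputs = 12)
  cfg0_carry <- reservoir_config(50, 0, 0.5, seed = 8,
                                 state_reset_policy = "carry-over")
  expect_identical(unattr(run_ensemble(r0$weights, imgs, r0$config)),
                   unattr(run_ensemble(r0$weights, imgs, cfg0_carry)))
})

test_that("contracting reservoirs forget their initial conditions", {
  r <- small_reservoir(n = 60, rho = 0.5, eps = 0.1, n_inputs = 12)
  imgs <- tiny_images(m = 4)
  u <- do.call(cbind, imgs$images)
  u <- u[, ((0:199) %% ncol(u)) + 1]
  set.seed(9)
  xa <- stats::runif(60, -1, 1); xb <- stats::runif(60, -1, 1)
  ta <- run_sequence(r$weights, u, r$config, initial_state = xa)
  tb <- run_sequence(r$weights, u, r$config, initial_state = xb)
  expect_lt(sqrt(sum((ta[, 200] - tb[, 200])^2)), 1e-10)
  # trajectories stay strictly inside (-1, 1) in this regime
  expect_true(all(abs(ta) < 1))
})
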