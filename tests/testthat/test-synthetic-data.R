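test_that("low-rank ensembles have exactly d nonzero covariance eigenvalues", {
  # d = 1: every centered pre-rescale image is a multiple of one pattern
  s1 <- generate_lowrank_images(30, 10, 10, d = 1, seed = 3)
  sv1 <- svd(scale(s1$prerescale, scale = FALSE))$d
  expect_lt(sv1[2] / sv1[1], 1e-12)

  for (d in c(4, 8)) {
    s <- generate_lowrank_images(500, 15, 15, d = d, seed = 11 + d)
    centered <- scale(s$prerescale, scale = FALSE)
    ev <- eigen(crossprod(centered) / nrow(centered), symmetric = TRUE,
                only.values = TRUE)$values
    expect_lt(abs(ev[d + 1]) / ev[1], 1e-10)
    # all pre-rescale variance concentrated in the top d components
    expect_equal(sum(ev[seq_len(d)]) / sum(pmax(ev, 0)), 1.0, tolerance = 1e-10)
    # affine per-ensemble rescale preserves the rank of the centered ensemble
    flat <- t(vapply(s$images, as.vector, numeric(225)))
    sv <- svd(scale(flat, scale = FALSE))$d
    expect_lt(sv[d + 1] / sv[1], 1e-10)
  }

  expect_error(generate_lowrank_images(10, 3, 3, d = 10), "invalid dimension")
  expect_error(generate_lowrank_images(4, 10, 10, d = 4), "insufficient samples")
})

test_that("generators are deterministic given the seed", {
  expect_identical(generate_lowrank_images(20, 8, 8, 3, seed = 5),
                   generate_lowrank_images(20, 8, 8, 3, seed = 5))
  expect_identical(generate_naturalistic_images(5, 8, 8, 2, seed = 5),
                   generate_naturalistic_images(5, 8, 8, 2, seed = 5))
  expect_identical(generate_labeled_images(3, 2, 8, 8, 0.1, seed = 5),
                   generate_labeled_images(3, 2, 8, 8, 0.1, seed = 5))
  # different seeds differ
  expect_false(identical(generate_naturalistic_images(5, 8, 8, 2, seed = 5),
                         generate_naturalistic_images(5, 8, 8, 2, seed = 6)))
})

test_that("naturalistic images have the requested spectral slope and range", {
  nat <- generate_naturalistic_images(60, 32, 32, spectral_slope = 2, seed = 5)
  ps <- radial_power_spectrum(nat)
  slope <- unname(stats::coef(stats::lm(log(power) ~ log(freq), ps))[2])
  expect_equal(slope, -2, tolerance = 0.1)

  # rescaling contract: ensemble min is 0 and max is 1
  px <- unlist(nat$images)
  expect_identical(min(px), 0)
  expect_identical(max(px), 1)

  # white noise (beta = 0): flat bulk eigenspectrum; max/min bulk ratio at
  # n = 1000 stays under the frozen reference (Marchenko-Pastur-scale spread)
  wn <- generate_naturalistic_images(1000, 20, 20, spectral_slope = 0, seed = 11)
  pixels <- t(vapply(wn$images, as.vector, numeric(400)))
  ev <- compute_eigenspectrum(t(pixels))$variances
  expect_lt(ev[2] / ev[length(ev) - 1], 25)

  expect_error(generate_naturalistic_images(5, 0, 8, 2, seed = 1), "invalid dimension")
})

test_that("labeled ensembles have separable class structure", {
  # zero noise: images equal their class template
  clean <- generate_labeled_images(3, 4, 16, 16, noise_sd = 0, seed = 2)
  expect_identical(clean$images[[1]], clean$templates[[1]])
  expect_identical(clean$images[[10]], clean$templates[[4]])

  # label histogram exact by construction
  s <- generate_labeled_images(50, 3, 16, 16, noise_sd = 0.05, seed = 7)
  expect_identical(unname(table(s$labels)), table(rep(0:2, each = 50)) |> unname())

  # nearest-template pixel oracle is perfect at this noise level
  pred <- vapply(s$images, function(im) {
    which.min(vapply(s$templates, function(tp) sum((im - tp)^2), numeric(1))) - 1L
  }, integer(1))
  expect_identical(pred, s$labels)

  expect_error(generate_labeled_images(5, 1, 8, 8), "invalid class count")
})

test_that("image-to-sequence conversion is the identity on columns", {
  img28 <- generate_labeled_images(1, 2, 28, 28, 0, seed = 1)$images[[1]]
  sq <- image_to_sequence(img28)
  expect_identical(dim(unclass(sq)), c(28L, 28L))          # T = 28 steps

  img90 <- generate_naturalistic_images(1, 30, 90, 2, seed = 1)$images[[1]]
  expect_identical(ncol(unclass(image_to_sequence(img90))), 90L)  # T = 90

  const <- matrix(0.4, 5, 7)
  sq_c <- image_to_sequence(const)
  expect_true(all(unclass(sq_c) == 0.4))

  # round trip: column-stacking the steps reconstructs the image exactly
  expect_identical(matrix(unclass(sq), 28, 28), img28)

  expect_error(image_to_sequence(matrix(1.5, 3, 3)), "normalization error")
})

test_that("PNG and bundle I/O round-trip images", {
  img <- generate_naturalistic_images(1, 16, 16, 2, seed = 9)$images[[1]]
  f <- tempfile(fileext = ".png")
  write_image_png(img, f)
  back <- read_image_png(f)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)   # 8-bit quantization bound

  s <- generate_labeled_images(3, 2, 8, 8, 0.05, seed = 4)
  d <- tempfile("bundle")
  write_image_set(s, d)
  back_set <- read_image_set(d)
  expect_equal(back_set$images, s$images, tolerance = 1e-12)
  expect_identical(back_set$labels, s$labels)
})
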