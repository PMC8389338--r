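#' Experiment drivers: phase diagram, dimensionality spectra, classification
#'
#' Reproducible orchestration of the three studies: the (rho, eps) phase
#' diagram of the decay exponent alpha and the maximum Lyapunov exponent;
#' eigenspectra versus input dimensionality with and without dynamical
#' noise (plain PCA and cvPCA); and classification performance across the
#' order-chaos transition. Every grid point derives its own seed from the
#' master seed and its index, so serial and parallel execution agree and a
#' point's result is independent of the rest of the grid.
#'
#' Desk-scale defaults (N = 200 units, M = 200 images of 30 x 30 for
#' sweeps; N = 100 for classification) keep runs on a laptop scale; the
#' full-scale settings (N = 2000, M = 2800, and N = 500 over 20,000 MNIST
#' images) are available via [experiment_profile()].
#'
#' @name experiments
NULL

#' Named experiment profiles
#'
#' @param name `"desk"` (default scale used in tests and analyses) or
#'   `"full"` (the full-scale settings; hours of compute).
#' @return List of profile parameters.
#' @export
experiment_profile <- function(name = c("desk", "full")) {
  name <- match.arg(name)
  if (name == "desk") {
    list(n_units = 200L, n_images = 200L, height = 30L, width = 30L,
         n_units_classification = 100L, n_seeds = 1L)
  } else {
    list(n_units = 2000L, n_images = 2800L, height = 90L, width = 90L,
         n_units_classification = 500L, n_seeds = 10L)
  }
}

# one phase-diagram grid point; returns a one-row data.frame
phase_point <- function(image_set, rho, eps, n_units, density, point_seed,
                        mle_steps, mle_trials, mle_washout, fit_range,
                        fit_method) {
  config <- reservoir_config(n_units, spectral_radius = rho,
                             input_scaling = eps, density = density,
                             seed = point_seed)
  weights <- build_reservoir(config, n_inputs = image_dim(image_set)[1])
  act <- run_ensemble(weights, image_set, config)
  fit <- fit_powerlaw(compute_eigenspectrum(act), method = fit_method,
                      rank_range = fit_range)
  mle <- estimate_mle(weights, config, drive = image_set,
                      washout = mle_washout, n_steps = mle_steps,
                      n_trials = mle_trials, seed = point_seed)
  d <- image_set$intrinsic_dim %||% Inf
  data.frame(rho = rho, eps = eps, seed = point_seed,
             mle = mle$mle, mle_se = mle$std_error,
             alpha = fit$alpha, fit_goodness = fit$goodness,
             manifold_class = as.character(classify_manifold(fit$alpha, d)),
             failed = FALSE, stringsAsFactors = FALSE)
}

#' Sweep the (rho, eps) plane: decay exponent and Lyapunov exponent
#'
#' For every grid point: build a reservoir, drive it with the image
#' ensemble, compute the activity eigenspectrum and its power-law exponent
#' alpha, and estimate the maximum Lyapunov exponent. Per-point failures are
#' recorded (`failed = TRUE`) and the sweep continues.
#'
#' @param image_set Driving [image_set].
#' @param rho_values,eps_values Grid values of the spectral radius and the
#'   input scaling.
#' @param n_units Reservoir size N.
#' @param density Reservoir weight density.
#' @param seed Master seed; each grid point uses [derive_seed()].
#' @param mle_steps,mle_trials,mle_washout Lyapunov estimator settings
#'   (reduced trial count by default: grid points are averaged over a
#'   surface, not reported individually).
#' @param fit_range Power-law fit rank range (default ranks 11-500).
#' @param fit_method Power-law fit method.
#' @return data.frame with one row per (rho, eps): `mle`, `alpha`,
#'   `manifold_class`, metadata.
#' @export
run_phase_diagram <- function(image_set, rho_values, eps_values,
                              n_units = 200L, density = 0.1, seed = 1L,
                              mle_steps = 400L, mle_trials = 3L,
                              mle_washout = 100L, fit_range = NULL,
                              fit_method = "loglog-regression") {
  grid <- expand.grid(rho = rho_values, eps = eps_values,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) stop("empty grid")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ps <- derive_seed(seed, i)
    tryCatch(
      phase_point(image_set, grid$rho[i], grid$eps[i], n_units, density, ps,
                  mle_steps, mle_trials, mle_washout, fit_range, fit_method),
      error = function(e) data.frame(rho = grid$rho[i], eps = grid$eps[i],
                                     seed = ps, mle = NA_real_, mle_se = NA_real_,
                                     alpha = NA_real_, fit_goodness = NA_real_,
                                     manifold_class = NA_character_,
                                     failed = TRUE, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Tune a parameter so the reservoir sits at the edge of chaos
#'
#' Bisection on the spectral radius (or the input scaling) until the
#' maximum Lyapunov exponent falls inside `target_mle_window` (default
#' \[-0.02, 0): just below the onset of chaos). The same weight seed is used
#' at every evaluation so only the searched parameter changes.
#'
#' @param image_set Driving [image_set].
#' @param bracket Length-2 search interval for the parameter.
#' @param search_variable `"rho"` or `"eps"`.
#' @param target_mle_window Interval for the MLE; upper bound must be <= 0.
#' @param n_units,density,rho,eps Reservoir settings (`rho`/`eps` give the
#'   fixed value of the variable not searched over).
#' @param seed Weight seed (fixed across evaluations).
#' @param mle_steps,mle_trials,mle_washout Lyapunov estimator settings.
#' @param max_iter Bisection iteration cap.
#' @return List with `value` (tuned parameter), `mle` (achieved), and
#'   `trace` (data.frame of all evaluations).
#' @export
calibrate_edge <- function(image_set, bracket, search_variable = c("rho", "eps"),
                           target_mle_window = c(-0.02, 0), n_units = 200L,
                           density = 0.1, rho = NULL, eps = 0.6, seed = 1L,
                           mle_steps = 400L, mle_trials = 2L,
                           mle_washout = 100L, max_iter = 30L) {
  search_variable <- match.arg(search_variable)
  if (target_mle_window[2] > 0) stop("target window upper bound must be <= 0")
  evals <- list()
  mle_at <- function(v) {
    r <- if (search_variable == "rho") v else rho
    e <- if (search_variable == "eps") v else eps
    config <- reservoir_config(n_units, spectral_radius = r, input_scaling = e,
                               density = density, seed = seed)
    weights <- build_reservoir(config, n_inputs = image_dim(image_set)[1])
    m <- estimate_mle(weights, config, drive = image_set,
                      washout = mle_washout, n_steps = mle_steps,
                      n_trials = mle_trials, seed = seed)$mle
    evals[[length(evals) + 1L]] <<- data.frame(value = v, mle = m)
    m
  }
  res <- bisect_to_window(mle_at, bracket, target_mle_window, max_iter)
  if (is.null(res))
    stop(paste0("calibration failure: MLE window unreachable in bracket; scanned curve:\n",
                paste(utils::capture.output(print(do.call(rbind, evals))), collapse = "\n")))
  list(value = res$x, mle = res$y, trace = do.call(rbind, evals))
}

# Bisection until f(x) lands inside [window[1], window[2]); assumes f is
# monotone over the bracket (either direction). Returns list(x, y) or NULL.
bisect_to_window <- function(f, bracket, window, max_iter = 30L) {
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo)
  if (flo >= window[1] && flo < window[2]) return(list(x = lo, y = flo))
  fhi <- f(hi)
  if (fhi >= window[1] && fhi < window[2]) return(list(x = hi, y = fhi))
  if (flo > fhi) { tmp <- lo; lo <- hi; hi <- tmp; tmp <- flo; flo <- fhi; fhi <- tmp }
  if (flo >= window[2] || fhi < window[1]) return(NULL)   # window not straddled
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm >= window[1] && fm < window[2]) return(list(x = mid, y = fm))
    if (fm < window[1]) lo <- mid else hi <- mid
  }
  NULL
}

#' Eigenspectra versus input dimensionality, with and without noise
#'
#' For each requested intrinsic dimension d (finite values give exactly
#' d-dimensional image ensembles; `Inf` gives naturalistic power-law
#' images), drives the same edge-of-chaos reservoir in three conditions:
#' noiseless (plain PCA), noisy (xi = 0.4 by default; raw PCA over one
#' repeat), and noisy with cvPCA over two repeats sharing the signal but not
#' the noise. Reports each spectrum's decay exponent against the
#' continuity + differentiability threshold `1 + 2/d`.
#'
#' @param d_values Intrinsic dimensions, e.g. `c(4, 8, Inf)`.
#' @param rho,eps Reservoir operating point (calibrate with
#'   [calibrate_edge()] so the MLE is just below 0).
#' @param n_images,height,width Image ensemble shape.
#' @param n_units Reservoir size.
#' @param xi Noise amplitude for the noisy conditions.
#' @param spectral_slope Spectral slope of the naturalistic (d = Inf)
#'   ensemble.
#' @param seed Master seed.
#' @param fit_range Power-law fit rank range.
#' @return List with `summary` (one row per d: alpha in all three
#'   conditions, threshold, manifold classes) and `spectra` (per-d list of
#'   the three variance vectors plus the input pixel spectrum).
#' @export
run_dimensionality_experiment <- function(d_values = c(4, 8, Inf), rho, eps,
                                          n_images = 200L, height = 30L,
                                          width = 30L, n_units = 200L,
                                          xi = 0.4, spectral_slope = 2,
                                          seed = 1L, fit_range = NULL) {
  summary_rows <- list()
  spectra <- list()
  for (k in seq_along(d_values)) {
    d <- d_values[k]
    img_seed <- derive_seed(seed, k)
    images <- if (is.finite(d)) {
      generate_lowrank_images(n_images, height, width, d = d, seed = img_seed)
    } else {
      generate_naturalistic_images(n_images, height, width,
                                   spectral_slope = spectral_slope,
                                   seed = img_seed)
    }
    pixels <- t(vapply(images$images, as.vector, numeric(height * width)))
    input_spectrum <- compute_eigenspectrum(t(pixels))
    config0 <- reservoir_config(n_units, spectral_radius = rho,
                                input_scaling = eps, seed = derive_seed(seed, 1000L + k))
    weights <- build_reservoir(config0, n_inputs = height)
    act0 <- run_ensemble(weights, images, config0)
    spec0 <- compute_eigenspectrum(act0)
    fit0 <- fit_powerlaw(spec0, rank_range = fit_range)
    confn <- reservoir_config(n_units, spectral_radius = rho,
                              input_scaling = eps, noise_amplitude = xi,
                              seed = config0$seed)
    act1 <- run_ensemble(weights, images, confn,
                         rng_stream = derive_seed(seed, 2000L + k))
    act2 <- run_ensemble(weights, images, confn,
                         rng_stream = derive_seed(seed, 3000L + k))
    spec_raw <- compute_eigenspectrum(act1)
    fit_raw <- fit_powerlaw(spec_raw, rank_range = fit_range)
    cv <- cvpca(act1, act2)
    fit_cv <- fit_powerlaw(cv, rank_range = fit_range)
    thr <- cplusd_threshold(d)
    summary_rows[[k]] <- data.frame(
      d = d, rho = rho, eps = eps, xi = xi, threshold = thr,
      alpha_noiseless = fit0$alpha, alpha_noisy_raw = fit_raw$alpha,
      alpha_cvpca = fit_cv$alpha,
      class_noiseless = as.character(classify_manifold(fit0$alpha, d)),
      class_cvpca = as.character(classify_manifold(fit_cv$alpha, d)),
      stringsAsFactors = FALSE)
    spectra[[k]] <- list(d = d, input = input_spectrum$variances,
                         noiseless = spec0$variances,
                         noisy_raw = spec_raw$variances,
                         cvpca = cv$signal_variances)
  }
  list(summary = do.call(rbind, summary_rows), spectra = spectra)
}

#' Classification performance across the order-chaos transition
#'
#' For each spectral radius: build a reservoir, encode the training and
#' test images in the reservoir model space, train and evaluate the ridge
#' readout, and measure the maximum Lyapunov exponent and the eigenspectrum
#' decay exponent on the training activity. Produces the three curves
#' (error rate, lambda, alpha) against rho.
#'
#' @param rho_values Spectral radii to sweep.
#' @param eps Fixed input scaling (default 0.6).
#' @param n_units Reservoir size (default 100).
#' @param train_set,test_set Labeled [image_set]s; by default a synthetic
#'   labeled ensemble is generated and split.
#' @param n_classes,n_train_per_class,n_test_per_class,height,width,noise_sd
#'   Synthetic task settings (used only when no sets are supplied).
#' @param lambda_r,lambda_o Model-space and output ridge penalties.
#' @param density Reservoir density.
#' @param seed Master seed.
#' @param mle_steps,mle_trials Lyapunov estimator settings.
#' @param fit_range Power-law fit rank range.
#' @return data.frame with one row per rho: `error_rate`, `mle`, `alpha`.
#' @export
run_classification_sweep <- function(rho_values, eps = 0.6, n_units = 100L,
                                     train_set = NULL, test_set = NULL,
                                     n_classes = 4L, n_train_per_class = 50L,
                                     n_test_per_class = 25L, height = 28L,
                                     width = 28L, noise_sd = 0.05,
                                     lambda_r = 1, lambda_o = 1,
                                     density = 0.1, seed = 1L,
                                     mle_steps = 400L, mle_trials = 3L,
                                     fit_range = NULL) {
  if (is.null(train_set) || is.null(test_set)) {
    sets <- make_classification_task(n_classes, n_train_per_class,
                                     n_test_per_class, height, width,
                                     noise_sd, seed = derive_seed(seed, 0L))
    train_set <- sets$train; test_set <- sets$test
  }
  h <- image_dim(train_set)[1]
  rows <- lapply(seq_along(rho_values), function(i) {
    rho <- rho_values[i]
    ps <- derive_seed(seed, i)
    tryCatch({
      config <- reservoir_config(n_units, spectral_radius = rho,
                                 input_scaling = eps, density = density,
                                 seed = ps)
      weights <- build_reservoir(config, n_inputs = h)
      enc_train <- encode_images(weights, train_set, config, lambda_r)
      enc_test <- encode_images(weights, test_set, config, lambda_r)
      model <- train_readout(enc_train, train_set$labels, lambda_o)
      report <- evaluate_readout(model, enc_test, test_set$labels)
      act <- run_ensemble(weights, train_set, config)
      fit <- fit_powerlaw(compute_eigenspectrum(act), rank_range = fit_range)
      mle <- estimate_mle(weights, config, drive = train_set,
                          n_steps = mle_steps, n_trials = mle_trials,
                          seed = ps)
      data.frame(rho = rho, eps = eps, seed = ps,
                 error_rate = report$error_rate, mle = mle$mle,
                 mle_se = mle$std_error, alpha = fit$alpha, failed = FALSE)
    }, error = function(e) data.frame(rho = rho, eps = eps, seed = ps,
                                      error_rate = NA_real_, mle = NA_real_,
                                      mle_se = NA_real_, alpha = NA_real_,
                                      failed = TRUE))
  })
  do.call(rbind, rows)
}

#' Generate a synthetic train/test classification task
#'
#' One labeled ensemble per split, from the same class templates but
#' independent pixel noise.
#'
#' @param n_classes,n_train_per_class,n_test_per_class,height,width,noise_sd
#'   Task settings.
#' @param seed Master seed (train and test use derived sub-seeds).
#' @return List with `train` and `test` [image_set]s.
#' @export
make_classification_task <- function(n_classes = 4L, n_train_per_class = 50L,
                                     n_test_per_class = 25L, height = 28L,
                                     width = 28L, noise_sd = 0.05, seed = 1L) {
  list(train = generate_labeled_images(n_train_per_class, n_classes, height,
                                       width, noise_sd, seed = derive_seed(seed, 1L)),
       test = generate_labeled_images(n_test_per_class, n_classes, height,
                                      width, noise_sd, seed = derive_seed(seed, 2L)))
}
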