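#' Covariance eigenspectra, power-law fits and cross-validated PCA
#'
#' PCA is computed with units (matrix rows) as variables and time-stimulus
#' samples (columns) as observations, using the population (1/S) covariance
#' so that the cross-validated estimator reduces exactly to plain PCA for
#' identical repeats.
#'
#' @name spectrum
NULL

#' Rank-ordered covariance eigenspectrum of reservoir activity
#'
#' Mean-centers every unit across all S samples and returns the eigenvalues
#' of the unit covariance matrix, sorted in descending order. Negative
#' numerical dust (below 1e-12 of the total variance in magnitude) is
#' clipped to zero.
#'
#' @param activity N x S activity matrix, S >= 2.
#' @return An `eigen_spectrum` list: `variances` (descending, 1-based rank),
#'   `total_variance`, `n_components`.
#' @export
compute_eigenspectrum <- function(activity) {
  if (!is.matrix(activity)) activity <- as.matrix(activity)
  s <- ncol(activity)
  if (s < 2) stop("insufficient samples: need S >= 2")
  xc <- activity - rowMeans(activity)
  cv <- tcrossprod(xc) / s
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  total <- sum(diag(cv))
  ev[ev < 0 & abs(ev) < 1e-12 * total] <- 0
  structure(list(variances = ev, total_variance = total,
                 n_components = length(ev)),
            class = "eigen_spectrum")
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat(sprintf("<eigen_spectrum> %d components, total variance %.4g\n",
              x$n_components, x$total_variance))
  invisible(x)
}

#' Continuous power-law maximum-likelihood fit (Clauset-style)
#'
#' Fits the continuous power-law density p(x) ~ x^(-alpha), x >= xmin, by
#' maximum likelihood, choosing the lower cutoff xmin that minimizes the
#' Kolmogorov-Smirnov distance between the fitted distribution and the data
#' tail (the Clauset-Shalizi-Newman procedure for continuous data).
#'
#' @param x Positive numeric samples.
#' @param xmin Optional fixed lower cutoff; if NULL it is selected by KS
#'   minimization over (at most `max_xmins`) candidate data values.
#' @param max_xmins Cap on the number of candidate cutoffs scanned.
#' @return List with `alpha`, `xmin`, `ks` (KS statistic at the chosen
#'   cutoff), `n_tail` (tail sample count) and `stderr`
#'   ((alpha-1)/sqrt(n_tail), the asymptotic ML standard error).
#' @export
powerlaw_ml <- function(x, xmin = NULL, max_xmins = 150L) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 10) stop("fit error: need at least 10 positive samples")
  x <- sort(x)
  fit_at <- function(xm) {
    tail <- x[x >= xm]
    n <- length(tail)
    if (n < 10) return(NULL)
    alpha <- 1 + n / sum(log(tail / xm))
    # KS distance between empirical tail CDF and fitted CDF 1-(x/xmin)^(1-alpha)
    cdf <- 1 - (tail / xm)^(1 - alpha)
    emp_hi <- seq_len(n) / n
    emp_lo <- (seq_len(n) - 1) / n
    ks <- max(pmax(abs(emp_hi - cdf), abs(emp_lo - cdf)))
    list(alpha = alpha, xmin = xm, ks = ks, n_tail = n)
  }
  if (!is.null(xmin)) {
    f <- fit_at(xmin)
    if (is.null(f)) stop("fit error: fewer than 10 samples above xmin")
  } else {
    cand <- unique(x[seq_len(length(x) - 9L)])
    if (length(cand) > max_xmins) {
      qs <- unique(stats::quantile(cand, probs = seq(0, 1, length.out = max_xmins),
                                   type = 1, names = FALSE))
      cand <- qs
    }
    fits <- lapply(cand, fit_at)
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0) stop("fit error: no usable cutoff")
    f <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ks"))]]
  }
  f$stderr <- (f$alpha - 1) / sqrt(f$n_tail)
  f
}

#' Fit the power-law decay exponent of a rank-ordered eigenspectrum
#'
#' Two methods for the decay exponent alpha of `variance(n) ~ n^(-alpha)`:
#' \describe{
#'   \item{loglog-regression}{least-squares slope of log variance against
#'     log rank over `rank_range`; alpha = -slope, goodness = R^2. Default
#'     method: the exponent of interest is defined on the rank curve.}
#'   \item{clauset-ml}{continuous power-law maximum likelihood with
#'     KS-minimizing lower cutoff, applied to the variance values inside
#'     `rank_range` (see [powerlaw_ml()]); goodness = KS statistic.}
#' }
#' Non-positive variances inside the range (possible for cross-validated
#' spectra) are dropped with a warning; at least 10 usable ranks are
#' required.
#'
#' @param spectrum An `eigen_spectrum`, `cvpca_result`, or numeric vector of
#'   rank-ordered variances.
#' @param method `"loglog-regression"` (default) or `"clauset-ml"`.
#' @param rank_range Integer pair `c(n_min, n_max)`; default
#'   `c(11, min(500, n_components))`.
#' @return A `powerlaw_fit` list: `alpha`, `method`, `rank_range`,
#'   `goodness` (R^2 or KS), `stderr`, `n_used`.
#' @export
fit_powerlaw <- function(spectrum,
                         method = c("loglog-regression", "clauset-ml"),
                         rank_range = NULL) {
  method <- match.arg(method)
  from_cvpca <- inherits(spectrum, "cvpca_result")
  v <- if (inherits(spectrum, "eigen_spectrum")) spectrum$variances
       else if (from_cvpca) spectrum$signal_variances
       else as.numeric(spectrum)
  n <- length(v)
  if (is.null(rank_range)) rank_range <- c(11L, min(500L, n))
  if (rank_range[1] < 1 || rank_range[2] > n || rank_range[1] >= rank_range[2])
    stop("fit error: invalid rank range")
  ranks <- seq.int(rank_range[1], rank_range[2])
  vv <- v[ranks]
  ok <- is.finite(vv) & vv > 0
  if (!all(ok)) {
    # negative cross-validated variances are excluded by design; warn only
    # for plain spectra, where non-positive values are unexpected
    if (!from_cvpca) warning("non-positive variances inside the fit range were dropped")
    ranks <- ranks[ok]; vv <- vv[ok]
  }
  if (length(vv) < 10) stop("fit error: fewer than 10 usable ranks in range")
  if (method == "loglog-regression") {
    lx <- log(ranks); ly <- log(vv)
    sxx <- sum((lx - mean(lx))^2)
    slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sxx
    resid <- ly - mean(ly) - slope * (lx - mean(lx))
    rss <- sum(resid^2)
    tss <- sum((ly - mean(ly))^2)
    out <- list(alpha = -slope,
                goodness = if (tss > 0) 1 - rss / tss else 1,
                stderr = sqrt(rss / max(length(lx) - 2, 1) / sxx))
  } else {
    # A rank curve v(n) ~ n^(-alpha) has value CCDF P(V >= v) ~ v^(-1/alpha),
    # i.e. the variance values follow a power-law tail with distribution
    # exponent 1 + 1/alpha. The ML estimate on the values is therefore
    # mapped back to the rank-decay exponent via alpha = 1/(ahat - 1)
    # (delta-method standard error).
    f <- powerlaw_ml(vv)
    if (f$alpha <= 1) stop("fit error: value-distribution exponent <= 1 has no rank-decay counterpart")
    out <- list(alpha = 1 / (f$alpha - 1), goodness = f$ks,
                stderr = f$stderr / (f$alpha - 1)^2)
  }
  structure(c(out, list(method = method,
                        rank_range = c(ranks[1], ranks[length(ranks)]),
                        n_used = length(vv))),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> alpha = %.4f (%s, ranks %d-%d, goodness %.4g)\n",
              x$alpha, x$method, x$rank_range[1], x$rank_range[2], x$goodness))
  invisible(x)
}

#' Cross-validated PCA signal-variance estimate
#'
#' Estimates stimulus-related (signal) component variances from two repeats
#' that share the signal but have independent noise. Both repeats are
#' centered with repeat 1's unit means; eigenvectors u_i come from repeat
#' 1's covariance; the signal variance of component i is
#' `(1/S) * (u_i' X1c) %*% t(u_i' X2c)`. Because noise is independent across
#' repeats, its contribution averages out, leaving an unbiased estimate of
#' the signal variance along each component. Negative values are retained
#' (they are excluded from power-law fit ranges by [fit_powerlaw()]).
#'
#' With identical repeats the result equals [compute_eigenspectrum()]
#' exactly.
#'
#' @param repeat1,repeat2 N x S activity matrices for the two repeats,
#'   identical shapes and stimulus ordering.
#' @return A `cvpca_result` list: `signal_variances`, `n_components`,
#'   `basis_provenance`.
#' @export
cvpca <- function(repeat1, repeat2) {
  if (!is.matrix(repeat1)) repeat1 <- as.matrix(repeat1)
  if (!is.matrix(repeat2)) repeat2 <- as.matrix(repeat2)
  if (!identical(dim(repeat1), dim(repeat2))) stop("shape error: repeats must have identical shapes")
  s <- ncol(repeat1)
  if (s < 2) stop("insufficient samples: need S >= 2")
  mu <- rowMeans(repeat1)
  x1 <- repeat1 - mu
  x2 <- repeat2 - mu
  eg <- eigen(tcrossprod(x1) / s, symmetric = TRUE)
  p1 <- crossprod(eg$vectors, x1)   # N x S projections
  p2 <- crossprod(eg$vectors, x2)
  structure(list(signal_variances = rowSums(p1 * p2) / s,
                 n_components = nrow(repeat1),
                 basis_provenance = "repeat1"),
            class = "cvpca_result")
}

#' Critical exponent of the continuity + differentiability bound
#'
#' For stimuli of intrinsic dimension d, a continuous and differentiable
#' neural representation requires the eigenspectrum decay exponent to exceed
#' `1 + 2/d`; for high-dimensional (d = Inf) stimuli the bound approaches 1.
#'
#' @param d Intrinsic input dimension (>= 1), or `Inf`.
#' @return The critical exponent `1 + 2/d`.
#' @export
cplusd_threshold <- function(d) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d < 1)
    stop("invalid dimension: d must be >= 1 (or Inf)")
  1 + 2 / d
}

#' Classify a representation manifold from its decay exponent
#'
#' Applies the spectral criterion: alpha < 1 means the representation is
#' neither continuous nor differentiable; 1 < alpha < 1 + 2/d means
#' continuous but not differentiable; alpha > 1 + 2/d means continuous and
#' differentiable (C+D). Boundary values are labeled with the weaker class
#' and flagged via the `"boundary"` attribute.
#'
#' @param alpha Fitted decay exponent (finite).
#' @param d Intrinsic input dimension (>= 1 or Inf).
#' @return One of `"neither"`, `"continuous-not-differentiable"`, `"C+D"`.
#' @export
classify_manifold <- function(alpha, d) {
  if (!is.finite(alpha)) stop("alpha must be finite")
  thr <- cplusd_threshold(d)
  if (alpha < 1) return(structure("neither", boundary = FALSE))
  if (alpha == 1) return(structure("neither", boundary = TRUE))
  if (alpha < thr) return(structure("continuous-not-differentiable", boundary = FALSE))
  if (alpha == thr) return(structure("continuous-not-differentiable", boundary = TRUE))
  structure("C+D", boundary = FALSE)
}
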