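# Monte Carlo cross-validation and test-set error metrics.

# Pooled RMSECV from a list of per-iteration validation residual vectors:
# sqrt( sum of all squared residuals / (N * n_v) ).
pool_rmsecv_ <- function(residuals) {
  sq <- vapply(residuals, function(r) sum(r^2), numeric(1))
  sqrt(sum(sq) / sum(lengths(residuals)))
}

#' Monte Carlo cross-validation of a PLS calibration
#'
#' Repeats `N` block-stratified calibration/validation splits; on each, a PLS
#' model with a fixed latent-variable count is refitted on the calibration
#' subset (including re-centring, so no information leaks from held-out
#' samples) and evaluated on the validation subset. The pooled
#' cross-validation error is
#' \deqn{RMSECV_{MC} = \sqrt{\frac{1}{N n_v} \sum_{i=1}^{N} \sum_{j=1}^{n_v}
#'   (y_{ij} - \hat y_{ij})^2}.}
#' Compared with leave-one-out, holding out `n_v > 1` samples per iteration
#' puts more weight on validation and is less prone to overfitting; compared
#' with exhaustive leave-`n_v`-out it examines only a random subsample of
#' splits and stays tractable.
#'
#' @param X Predictor matrix (`n x p`).
#' @param y Response vector.
#' @param ncomp Latent-variable count, fixed for the whole run.
#' @param n_v Validation-set size per iteration (`n_v < n`).
#' @param N Number of iterations.
#' @param seed Integer seed; the full run is deterministic given the seed.
#' @param collect_coefficients If `TRUE`, store the per-iteration regression
#'   vector (standardized scale when `scale = TRUE`) as an `N x p` matrix,
#'   for coefficient-distribution diagnostics.
#' @param scale If `TRUE` each calibration fit standardizes its columns.
#' @return An `mccv_result`: list with `N`, `n_v`, `msec_per_iter`,
#'   `msev_per_iter`, `rmsecv_mc`, `val_sq_sums` (per-iteration summed
#'   squared validation residuals) and optionally `coefficient_samples`.
#' @export
mccv <- function(X, y, ncomp, n_v, N, seed, collect_coefficients = FALSE,
                 scale = FALSE) {
  X <- assert_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  n_v <- assert_count(n_v, "n_v")
  N <- assert_count(N, "N")
  if (n_v >= n) stop("`n_v` must be smaller than the number of samples",
                     call. = FALSE)
  ncomp <- assert_count(ncomp, "ncomp")
  if (ncomp > min(n - n_v - 1L, ncol(X)))
    stop(sprintf("ncomp = %d infeasible with %d calibration samples",
                 ncomp, n - n_v), call. = FALSE)
  msec <- numeric(N); msev <- numeric(N); vss <- numeric(N)
  coefs <- if (collect_coefficients) matrix(0, N, ncol(X)) else NULL
  with_seed(seed, {
    for (i in seq_len(N)) {
      s <- block_split_(y, n_v)
      m <- fit_pls(X[s$calibration, , drop = FALSE], y[s$calibration],
                   ncomp, scale = scale)
      msec[i] <- m$ssr_train / length(s$calibration)
      rv <- y[s$validation] - predict(m, X[s$validation, , drop = FALSE])
      vss[i] <- sum(rv^2)
      msev[i] <- vss[i] / n_v
      if (collect_coefficients) coefs[i, ] <- m$coefficients_B
    }
  })
  structure(
    list(N = N, n_v = n_v, msec_per_iter = msec, msev_per_iter = msev,
         val_sq_sums = vss, rmsecv_mc = sqrt(sum(vss) / (N * n_v)),
         coefficient_samples = coefs),
    class = "mccv_result")
}

#' @export
print.mccv_result <- function(x, ...) {
  cat(sprintf("mccv_result: N = %d, n_v = %d, RMSECV = %.4f\n",
              x$N, x$n_v, x$rmsecv_mc))
  invisible(x)
}

#' Root-mean-square error of prediction on a test set
#'
#' @param y Observed responses.
#' @param yhat Predicted responses (same length).
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmsep <- function(y, yhat) {
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  sqrt(mean((y - yhat)^2))
}

#' Percent coefficient of determination on a test set
#'
#' `(1 - SS_res / SS_tot) * 100`, with `SS_tot` taken about the test-set
#' mean. Can be negative when predictions are worse than the mean.
#'
#' @param y Observed responses (length >= 2, not constant).
#' @param yhat Predicted responses.
#' @return R-squared in percent.
#' @export
r2_test <- function(y, yhat) {
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("`y` is constant; R2 undefined", call. = FALSE)
  (1 - sum((y - yhat)^2) / ss_tot) * 100
}

#' Coefficient samples across Monte Carlo refits
#'
#' Convenience wrapper around [mccv()] that collects the per-iteration
#' regression vector of a standardized-variable PLS fit; the rows can be
#' histogrammed per wavelength to visualise how unstable individual
#' coefficients are under resampling.
#'
#' @inheritParams mccv
#' @param scale Standardize calibration columns (default `TRUE`).
#' @return An `N x p` numeric matrix of coefficient samples.
#' @export
coefficient_distribution <- function(X, y, ncomp, n_v, N, seed, scale = TRUE) {
  mccv(X, y, ncomp, n_v, N, seed, collect_coefficients = TRUE,
       scale = scale)$coefficient_samples
}
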