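#' Column standardization
#'
#' Mean-centres each column and scales it to unit sample standard deviation.
#' Used by the coefficient-based selectors, where a large raw coefficient can
#' merely reflect a variable with small values and large variance; scaling
#' with the inverse standard deviation makes coefficient magnitudes
#' comparable across wavelengths.
#'
#' @param X Numeric matrix (`n x p`, `n >= 2`).
#' @return A list with `X_std` (standardized matrix), `center` (column
#'   means) and `scale` (column standard deviations, `n - 1` denominator).
#' @export
standardize <- function(X) {
  X <- assert_matrix(X)
  if (nrow(X) < 2L) stop("standardization needs n >= 2", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  scl <- sqrt(colSums(Xc^2) / (nrow(X) - 1L))
  if (any(scl == 0))
    stop(sprintf("column %d has zero standard deviation; drop it before standardizing",
                 which(scl == 0)[1L]), call. = FALSE)
  list(X_std = sweep(Xc, 2L, scl, "/"), center = ctr, scale = scl)
}

# NIPALS core on pre-centred data. Single response; X-block deflation only.
# Returns scores, loadings, weights, the regression vector on centred scale,
# and the cumulative training SSR after 1..ncomp components.
nipals_ <- function(Xc, yc, ncomp, tol = 1e-12, maxit = 500L) {
  n <- nrow(Xc); p <- ncol(Xc)
  TT <- matrix(0, n, ncomp); P <- matrix(0, p, ncomp)
  W <- matrix(0, p, ncomp); q <- numeric(ncomp)
  ssr <- numeric(ncomp)
  res <- yc
  used <- 0L
  for (a in seq_len(ncomp)) {
    u <- res
    w_old <- NULL
    degenerate <- FALSE
    for (it in seq_len(maxit)) {
      w <- crossprod(Xc, u)[, 1L]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) { degenerate <- TRUE; break }
      w <- w / nw
      tt <- Xc %*% w
      qt <- sum(res * tt) / sum(tt^2)
      u_new <- res * qt
      if (!is.null(w_old) && sum((w - w_old)^2) < tol^2) break
      w_old <- w
      u <- u_new
    }
    # no covariance left to extract (e.g. a constant response): stop early,
    # later components stay zero and B reduces to the mean model
    if (degenerate) { ssr[a:ncomp] <- sum(res^2); break }
    tt <- drop(Xc %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-300) { ssr[a:ncomp] <- sum(res^2); break }
    pp <- crossprod(Xc, tt)[, 1L] / tt2
    qq <- sum(res * tt) / tt2
    Xc <- Xc - tcrossprod(tt, pp)
    res <- res - tt * qq
    TT[, a] <- tt; P[, a] <- pp; W[, a] <- w; q[a] <- qq
    ssr[a] <- sum(res^2)
    used <- a
  }
  # B on the centred scale: W (P'W)^-1 q, using the components extracted
  B <- if (used == 0L) numeric(p) else
    drop(W[, 1:used, drop = FALSE] %*%
           solve(crossprod(P[, 1:used, drop = FALSE],
                           W[, 1:used, drop = FALSE]), q[1:used]))
  list(scores = TT, x_loadings = P, y_loadings = q, weights = W,
       coefficients = B, ssr = ssr)
}

# Regression vectors for every truncation 1..ncomp of a fitted NIPALS
# decomposition; column a of the result predicts with the first a components.
coef_path_ <- function(fit) {
  ncomp <- length(fit$y_loadings)
  PtW <- crossprod(fit$x_loadings, fit$weights)
  B <- matrix(0, nrow(fit$weights), ncomp)
  for (a in seq_len(ncomp)) {
    B[, a] <- fit$weights[, 1:a, drop = FALSE] %*%
      solve(PtW[1:a, 1:a, drop = FALSE], fit$y_loadings[1:a])
  }
  B
}

#' Fit a partial least squares regression model
#'
#' Single-response PLS fitted by NIPALS with deflation of the X block only.
#' PLS projects the spectra onto `ncomp` latent variables chosen to maximise
#' covariance with the response, then regresses the response on the scores;
#' the result collapses to a single regression vector so that
#' `yhat = (X - x_mean) %*% B + y_mean` (after variance scaling when
#' `scale = TRUE`).
#'
#' @param X Numeric `n x p` predictor matrix (absorbance spectra).
#' @param y Numeric response vector of length `n` (concentrations).
#' @param ncomp Number of latent variables `c`, `1 <= c <= min(n - 1, p)`.
#' @param scale If `TRUE`, columns are scaled to unit standard deviation
#'   before fitting (mean-centring is always applied).
#' @return A `pls_model` object with elements `n_components`, `x_mean`,
#'   `y_mean`, `x_scale`, `scores_T`, `x_loadings_P`, `y_loadings_Q`,
#'   `weights_W`, `coefficients_B`, `ssr_train` (training sum of squared
#'   residuals at `ncomp`) and `ssr_per_component`.
#' @examples
#' X <- matrix(rnorm(60), 12, 5)
#' y <- X[, 1] - 0.5 * X[, 3] + rnorm(12, sd = 0.01)
#' m <- fit_pls(X, y, ncomp = 2)
#' predict(m, X)
#' @export
fit_pls <- function(X, y, ncomp, scale = FALSE) {
  X <- assert_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("`y` length must match nrow(X)", call. = FALSE)
  if (anyNA(y)) stop("missing values in `y`", call. = FALSE)
  ncomp <- assert_count(ncomp, "ncomp")
  if (ncomp > min(n - 1L, p))
    stop(sprintf("ncomp = %d exceeds min(n - 1, p) = %d", ncomp,
                 min(n - 1L, p)), call. = FALSE)
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2L, x_mean, "-")
  x_scale <- rep(1, p)
  if (scale) {
    x_scale <- sqrt(colSums(Xc^2) / (n - 1L))
    if (any(x_scale == 0))
      stop(sprintf("column %d has zero variance; cannot scale",
                   which(x_scale == 0)[1L]), call. = FALSE)
    Xc <- sweep(Xc, 2L, x_scale, "/")
  }
  if (all(abs(Xc) < .Machine$double.eps))
    stop("X is constant after centring; nothing to fit", call. = FALSE)
  y_mean <- mean(y)
  fit <- nipals_(Xc, y - y_mean, ncomp)
  structure(
    list(n_components = ncomp, x_mean = x_mean, y_mean = y_mean,
         x_scale = x_scale, scores_T = fit$scores,
         x_loadings_P = fit$x_loadings, y_loadings_Q = fit$y_loadings,
         weights_W = fit$weights, coefficients_B = fit$coefficients,
         ssr_train = fit$ssr[ncomp], ssr_per_component = fit$ssr,
         scaled = scale),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d latent variable(s), p = %d, training SSR = %.6g\n",
              x$n_components, length(x$coefficients_B), x$ssr_train))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Numeric matrix with the same number of columns the model
#'   was fitted on (a single spectrum may be given as a vector).
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  newdata <- assert_matrix(newdata, "newdata")
  if (ncol(newdata) != length(object$x_mean))
    stop(sprintf("newdata has %d columns but the model expects %d",
                 ncol(newdata), length(object$x_mean)), call. = FALSE)
  Xc <- sweep(newdata, 2L, object$x_mean, "-")
  Xc <- sweep(Xc, 2L, object$x_scale, "/")
  drop(Xc %*% object$coefficients_B) + object$y_mean
}

#' Serialize a PLS model to JSON
#'
#' @param model A `pls_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pls_model_json <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' PRESS curve over latent-variable counts
#'
#' Computes the predicted residual error sum of squares (PRESS) for each
#' latent-variable count `1..c_max` over `N` Monte Carlo block-stratified
#' calibration/validation splits. The same `N` splits are reused for every
#' component count so the curve is comparable across counts.
#'
#' @param X Predictor matrix, `y` response, as in [fit_pls()].
#' @param y Response vector.
#' @param c_max Largest latent-variable count to evaluate.
#' @param n_v Validation-set size per split.
#' @param N Number of Monte Carlo splits.
#' @param seed Integer seed.
#' @param scale Passed to the per-split fits.
#' @return A `press_curve` object: list with `components` (1..c_max) and
#'   `press` (summed squared validation residuals per count).
#' @seealso [select_components_elbow()]
#' @export
press_curve <- function(X, y, c_max, n_v, N, seed, scale = FALSE) {
  X <- assert_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  c_max <- assert_count(c_max, "c_max")
  n_v <- assert_count(n_v, "n_v")
  N <- assert_count(N, "N")
  if (n_v >= n) stop("`n_v` must leave at least 2 calibration samples",
                     call. = FALSE)
  if (c_max > min(n - n_v - 1L, ncol(X)))
    stop(sprintf("c_max = %d infeasible for %d calibration samples", c_max,
                 n - n_v), call. = FALSE)
  press <- numeric(c_max)
  with_seed(seed, {
    for (i in seq_len(N)) {
      s <- block_split_(y, n_v)
      cal <- s$calibration; val <- s$validation
      m <- fit_pls(X[cal, , drop = FALSE], y[cal], c_max, scale = scale)
      Bpath <- coef_path_(list(weights = m$weights_W,
                               x_loadings = m$x_loadings_P,
                               y_loadings = m$y_loadings_Q))
      Xv <- sweep(X[val, , drop = FALSE], 2L, m$x_mean, "-")
      Xv <- sweep(Xv, 2L, m$x_scale, "/")
      pred <- Xv %*% Bpath + m$y_mean          # n_v x c_max
      press <- press + colSums((y[val] - pred)^2)
    }
  })
  structure(list(components = seq_len(c_max), press = press),
            class = "press_curve")
}

#' @export
print.press_curve <- function(x, ...) {
  cat("press_curve:\n")
  print(stats::setNames(signif(x$press, 6), paste0("c", x$components)))
  invisible(x)
}

#' Choose the latent-variable count at the PRESS plateau
#'
#' A deterministic surrogate for reading the elbow off a PRESS plot: returns
#' the smallest count `c` whose relative improvement to `c + 1`,
#' `(press[c] - press[c + 1]) / press[c]`, falls below `rel_tol`; if the
#' curve keeps improving through the last point, the largest count evaluated
#' is returned.
#'
#' @param curve A `press_curve`.
#' @param rel_tol Relative-improvement tolerance (default 0.02).
#' @return The chosen component count (positive integer).
#' @export
select_components_elbow <- function(curve, rel_tol = 0.02) {
  stopifnot(inherits(curve, "press_curve"))
  k <- length(curve$press)
  if (k == 0L) stop("empty PRESS curve", call. = FALSE)
  if (k == 1L) return(1L)
  for (c in seq_len(k - 1L)) {
    pc <- curve$press[c]
    improve <- if (pc <= 0) 0 else (pc - curve$press[c + 1L]) / pc
    if (improve < rel_tol) return(c)
  }
  k
}
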