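# Coefficient-magnitude (beta) selection and elimination of uninformative
# variables (EUV) with a random-augmentation cutoff.

#' Construct a selection result
#'
#' Common container returned by all wavelength selectors: a per-wavelength
#' importance score, a boolean selection mask, and method metadata.
#'
#' @param method One of `"beta"`, `"euv"`, `"ipls"`, `"fs_ipls"`, `"mwpls"`,
#'   `"ga"`.
#' @param score Numeric importance per wavelength (length `p`).
#' @param mask Logical selection mask (length `p`).
#' @param params Named list of method parameters used.
#' @return A `selection_result` object; `n_selected` caches `sum(mask)`.
#' @export
selection_result <- function(method, score, mask, params = list()) {
  method <- match.arg(method, c("beta", "euv", "ipls", "fs_ipls", "mwpls", "ga"))
  if (length(score) != length(mask))
    stop("`score` and `mask` must have equal length", call. = FALSE)
  structure(
    list(method = method, score = as.numeric(score), mask = as.logical(mask),
         params = params, n_selected = sum(mask)),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s]: %d / %d wavelengths selected\n",
              x$method, x$n_selected, length(x$mask)))
  invisible(x)
}

#' Write a selection result to disk
#'
#' Emits three files sharing `prefix`: `<prefix>.json` (full object),
#' `<prefix>_score.tsv` (wavenumber, score) and `<prefix>_mask.tsv`
#' (wavenumber, selected 0/1).
#'
#' @param res A `selection_result`.
#' @param wavenumbers Wavenumber axis matching the score length.
#' @param prefix Output path prefix.
#' @return Invisibly, the three paths written.
#' @export
write_selection_result <- function(res, wavenumbers, prefix) {
  stopifnot(inherits(res, "selection_result"),
            length(wavenumbers) == length(res$score))
  paths <- paste0(prefix, c(".json", "_score.tsv", "_mask.tsv"))
  jsonlite::write_json(unclass(res), paths[1], auto_unbox = TRUE, digits = NA)
  utils::write.table(data.frame(wavenumber = wavenumbers, score = res$score),
                     paths[2], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(wavenumber = wavenumbers,
                                selected = as.integer(res$mask)),
                     paths[3], sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Coefficient-magnitude (beta) wavelength importance
#'
#' Scores each wavelength by the absolute regression coefficient of a PLS
#' model fitted on standardized spectra, so that coefficient size is
#' comparable across wavelengths with different variances. With `N = 1` the
#' model is fitted once on the full data (the plain method); with `N > 1`
#' the score is the mean absolute coefficient over `N` Monte Carlo
#' calibration refits, which stabilises it against resampling noise.
#'
#' @param X Spectra matrix, `y` concentrations.
#' @param y Response vector.
#' @param ncomp Latent-variable count.
#' @param n_v Validation size for the Monte Carlo refits (ignored for `N = 1`).
#' @param N Number of refits (default 1).
#' @param seed Integer seed.
#' @param quantile_threshold Scores at or above this score quantile are
#'   selected (default 0.8, i.e. the top 20 percent).
#' @return A `selection_result` with `method = "beta"`.
#' @export
beta_importance <- function(X, y, ncomp, n_v = 5, N = 1, seed = 1,
                            quantile_threshold = 0.8) {
  X <- assert_matrix(X)
  y <- as.numeric(y)
  q <- assert_prob(quantile_threshold, "quantile_threshold")
  N <- assert_count(N, "N")
  sds <- apply(X, 2L, stats::sd)
  keep <- sds > 0
  if (!all(keep))
    warning(sprintf("%d zero-variance column(s) excluded from beta scoring",
                    sum(!keep)))
  Xk <- X[, keep, drop = FALSE]
  score_k <- if (N == 1L) {
    abs(fit_pls(Xk, y, ncomp, scale = TRUE)$coefficients_B)
  } else {
    res <- mccv(Xk, y, ncomp, n_v, N, seed, collect_coefficients = TRUE,
                scale = TRUE)
    colMeans(abs(res$coefficient_samples))
  }
  score <- numeric(ncol(X))
  score[keep] <- score_k
  thr <- stats::quantile(score[keep], q, names = FALSE)
  mask <- score >= thr & keep
  selection_result("beta", score, mask,
                   params = list(ncomp = ncomp, n_v = n_v, N = N, seed = seed,
                                 quantile_threshold = q, threshold = thr))
}

#' Reliability of resampled regression coefficients
#'
#' For each variable, the ratio of the mean to the sample standard deviation
#' (denominator `N - 1`) of its coefficient across resampled refits —
#' the analogue of a t-statistic for the hypothesis that the coefficient is
#' zero. Variables whose coefficient keeps its sign and size across
#' resamples get large magnitudes; noise variables hover near zero.
#'
#' @param coef_samples `N x p` matrix of coefficient samples, `N >= 2`.
#' @return Numeric vector of length `p`. Columns with zero standard
#'   deviation are flagged with a warning and returned as `Inf` carrying the
#'   sign of the mean (0 when the mean is also 0).
#' @export
euv_reliability <- function(coef_samples) {
  coef_samples <- assert_matrix(coef_samples, "coef_samples")
  if (nrow(coef_samples) < 2L)
    stop("need at least 2 coefficient samples per variable", call. = FALSE)
  mu <- colMeans(coef_samples)
  sdv <- apply(coef_samples, 2L, stats::sd)
  out <- numeric(length(mu))
  zero <- sdv == 0
  out[!zero] <- mu[!zero] / sdv[!zero]
  if (any(zero)) {
    warning(sprintf("%d column(s) with zero coefficient spread; reliability set to signed Inf",
                    sum(zero)))
    out[zero] <- sign(mu[zero]) * Inf
  }
  out
}

#' Elimination of uninformative variables (EUV)
#'
#' Appends `n_artificial` small random-noise columns to the spectra, computes
#' the reliability ([euv_reliability()]) of every coefficient under
#' resampling, and keeps only real wavelengths whose absolute reliability
#' exceeds the largest absolute reliability attained by any artificial
#' column. Since the artificial columns carry no information, any real
#' variable that cannot beat them is deemed uninformative. By construction
#' artificial columns are never selected.
#'
#' Coefficients are computed on mean-centred (not variance-scaled) data, so
#' the amplitude of the artificial columns is meaningful. The default
#' matches their standard deviation to the median standard deviation of the
#' real columns: although the reliability ratio is scale-free in theory,
#' under finite resampling artificial columns that are orders of magnitude
#' weaker than the real ones stop being a valid null for the uninformative
#' real columns, and the cutoff becomes too permissive.
#'
#' @param X Spectra matrix, `y` concentrations.
#' @param y Response vector.
#' @param ncomp Latent-variable count.
#' @param n_artificial Number of appended noise columns (default
#'   `min(p, 300)`).
#' @param noise_amplitude Upper bound of the uniform noise in the artificial
#'   columns; default `sqrt(12)` times the median column standard deviation,
#'   which gives the artificial columns the same standard deviation as a
#'   typical real column.
#' @param resampling `"loo"` (leave-one-out, default) or `"mccv"`.
#' @param n_v,N Monte Carlo parameters when `resampling = "mccv"`.
#' @param seed Integer seed (drives both the noise draw and any resampling).
#' @return A `selection_result` with `method = "euv"`; `score` holds the
#'   absolute reliabilities of the real wavelengths and `params$cutoff` the
#'   artificial-column cutoff.
#' @export
euv_select <- function(X, y, ncomp, n_artificial = NULL, noise_amplitude = NULL,
                       resampling = c("loo", "mccv"), n_v = 5, N = 100,
                       seed = 1) {
  X <- assert_matrix(X)
  y <- as.numeric(y)
  resampling <- match.arg(resampling)
  n <- nrow(X); p <- ncol(X)
  if (is.null(n_artificial)) n_artificial <- min(p, 300L)
  n_artificial <- assert_count(n_artificial, "n_artificial")
  if (is.null(noise_amplitude)) {
    # sd of U(0, a) is a/sqrt(12); match the median real column sd
    noise_amplitude <- sqrt(12) * stats::median(apply(X, 2L, stats::sd))
    if (noise_amplitude == 0) noise_amplitude <- 1e-6
  }
  if (noise_amplitude <= 0)
    stop("`noise_amplitude` must be positive", call. = FALSE)
  samples <- with_seed(seed, {
    Xa <- cbind(X, matrix(stats::runif(n * n_artificial) * noise_amplitude,
                          n, n_artificial))
    if (resampling == "loo") {
      t(vapply(seq_len(n), function(i) {
        fit_pls(Xa[-i, , drop = FALSE], y[-i], ncomp)$coefficients_B
      }, numeric(ncol(Xa))))
    } else {
      mccv(Xa, y, ncomp, n_v, N, seed = stats::runif(1) * 1e6,
           collect_coefficients = TRUE)$coefficient_samples
    }
  })
  rel <- abs(euv_reliability(samples))
  cutoff <- max(rel[(p + 1L):(p + n_artificial)])
  score <- rel[seq_len(p)]
  mask <- score > cutoff
  selection_result("euv", score, mask,
                   params = list(ncomp = ncomp, n_artificial = n_artificial,
                                 noise_amplitude = noise_amplitude,
                                 resampling = resampling, cutoff = cutoff,
                                 seed = seed))
}
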