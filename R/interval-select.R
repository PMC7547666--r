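# Interval-based selectors: iPLS, forward-selection iPLS with interval
# micro-optimisation, and moving-window PLS.

#' Partition wavelengths into equidistant intervals
#'
#' Splits positions `1..p` into `k` contiguous intervals whose sizes differ
#' by at most one, larger intervals first.
#'
#' @param p Number of wavelengths.
#' @param k Number of intervals (`1 <= k <= p`).
#' @param wavenumbers Optional axis of length `p` used to annotate interval
#'   bounds in physical units.
#' @return A data frame with columns `start`, `end` (1-based, inclusive) and,
#'   when an axis is given, `start_wavenumber`, `end_wavenumber`.
#' @examples
#' make_intervals(10, 3)
#' @export
make_intervals <- function(p, k, wavenumbers = NULL) {
  p <- assert_count(p, "p")
  k <- assert_count(k, "k")
  if (k > p) stop("`k` cannot exceed the number of wavelengths", call. = FALSE)
  base <- p %/% k
  sizes <- rep(base, k)
  extra <- p %% k
  if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
  ends <- cumsum(sizes)
  out <- data.frame(start = c(1L, ends[-k] + 1L), end = ends)
  if (!is.null(wavenumbers)) {
    stopifnot(length(wavenumbers) == p)
    out$start_wavenumber <- wavenumbers[out$start]
    out$end_wavenumber <- wavenumbers[out$end]
  }
  out
}

# RMSECV of a PLS model restricted to `cols`, pooled over a fixed list of
# splits (shared across candidates for comparability). ncomp is capped at
# what the narrowest calibration set and the column count allow.
interval_rmsecv_ <- function(X, y, cols, ncomp, splits, warn_cap = TRUE) {
  k <- length(cols)
  n_cal <- min(lengths(lapply(splits, `[[`, "calibration")))
  cap <- min(k, n_cal - 1L)
  if (ncomp > cap) {
    if (warn_cap)
      warning(sprintf("ncomp reduced from %d to %d for a %d-wavelength interval",
                      ncomp, cap, k))
    ncomp <- cap
  }
  tot <- 0; cnt <- 0L
  for (s in splits) {
    m <- fit_pls(X[s$calibration, cols, drop = FALSE], y[s$calibration], ncomp)
    r <- y[s$validation] - predict(m, X[s$validation, cols, drop = FALSE])
    tot <- tot + sum(r^2)
    cnt <- cnt + length(r)
  }
  sqrt(tot / cnt)
}

# N block-stratified splits drawn under `seed`, reused across candidate
# wavelength subsets so their RMSECVs are directly comparable.
draw_splits_ <- function(y, n_v, N, seed) {
  with_seed(seed, lapply(seq_len(N), function(i) block_split_(y, n_v)))
}

#' Interval PLS (iPLS)
#'
#' Splits the spectrum into `k` equidistant intervals, fits a local PLS
#' calibration on each, and scores every interval by its Monte Carlo
#' cross-validated RMSECV on a shared set of splits. The best interval is
#' the argmin (ties broken by lower interval index).
#'
#' @param ds A [spectra_dataset].
#' @param k Number of intervals.
#' @param ncomp Latent-variable count (reduced with a warning for intervals
#'   narrower than `ncomp`).
#' @param n_v,N,seed Monte Carlo cross-validation parameters.
#' @return An `interval_report`: list with `intervals` (data frame),
#'   `rmsecv_per_interval`, `best_interval`, `selected_sequence`,
#'   `rmsecv_trajectory` and `final_mask` (logical length `p`, the best
#'   interval).
#' @export
ipls <- function(ds, k, ncomp, n_v = 5, N = 20, seed = 1) {
  stopifnot(inherits(ds, "spectra_dataset"))
  X <- ds$absorbance; y <- ds$concentration
  iv <- make_intervals(ncol(X), k, ds$wavenumbers)
  splits <- draw_splits_(y, n_v, N, seed)
  rmse <- vapply(seq_len(nrow(iv)), function(j) {
    interval_rmsecv_(X, y, iv$start[j]:iv$end[j], ncomp, splits)
  }, numeric(1))
  best <- which.min(rmse)          # which.min takes the first minimum
  mask <- logical(ncol(X))
  mask[iv$start[best]:iv$end[best]] <- TRUE
  structure(
    list(intervals = iv, rmsecv_per_interval = rmse, best_interval = best,
         selected_sequence = best, rmsecv_trajectory = rmse[best],
         final_mask = mask,
         params = list(k = k, ncomp = ncomp, n_v = n_v, N = N, seed = seed)),
    class = "interval_report")
}

#' @export
print.interval_report <- function(x, ...) {
  cat(sprintf("interval_report: %d intervals, best = %d (RMSECV %.4f), %d wavelengths selected\n",
              nrow(x$intervals), x$best_interval,
              min(x$rmsecv_per_interval), sum(x$final_mask)))
  invisible(x)
}

#' Forward-selection interval PLS (FS-iPLS)
#'
#' Greedy forward selection over the equidistant intervals: starting from
#' the single best interval, each step adds the interval that most lowers
#' the combined model's RMSECV on a shared set of Monte Carlo splits, and
#' stops when the relative improvement falls below `rel_improve` or
#' `max_intervals` have been accepted. Optionally the edges of the final
#' union are micro-optimised (see [micro_optimize()]).
#'
#' @inheritParams ipls
#' @param max_intervals Cap on the number of intervals accepted.
#' @param rel_improve Minimum relative RMSECV decrease required to accept a
#'   further interval (default 0.005).
#' @return An `interval_report`; `selected_sequence` records the acceptance
#'   order and `rmsecv_trajectory` the RMSECV after each accepted step.
#' @export
fs_ipls <- function(ds, k, ncomp, n_v = 5, N = 20, seed = 1,
                    max_intervals = k, rel_improve = 0.005) {
  stopifnot(inherits(ds, "spectra_dataset"))
  X <- ds$absorbance; y <- ds$concentration
  iv <- make_intervals(ncol(X), k, ds$wavenumbers)
  splits <- draw_splits_(y, n_v, N, seed)
  cols_of <- function(idx) {
    sort(unlist(lapply(idx, function(j) iv$start[j]:iv$end[j])))
  }
  remaining <- seq_len(nrow(iv))
  chosen <- integer(0)
  traj <- numeric(0)
  best_rmse <- Inf
  while (length(chosen) < max_intervals && length(remaining) > 0L) {
    cand <- vapply(remaining, function(j) {
      interval_rmsecv_(X, y, cols_of(c(chosen, j)), ncomp, splits,
                       warn_cap = FALSE)
    }, numeric(1))
    j_best <- remaining[which.min(cand)]
    r_best <- min(cand)
    if (length(chosen) > 0L &&
        (best_rmse - r_best) / best_rmse < rel_improve) break
    chosen <- c(chosen, j_best)
    remaining <- setdiff(remaining, j_best)
    traj <- c(traj, r_best)
    best_rmse <- r_best
  }
  mask <- logical(ncol(X))
  mask[cols_of(chosen)] <- TRUE
  structure(
    list(intervals = iv,
         rmsecv_per_interval = NULL, best_interval = chosen[1L],
         selected_sequence = chosen, rmsecv_trajectory = traj,
         final_mask = mask,
         params = list(k = k, ncomp = ncomp, n_v = n_v, N = N, seed = seed,
                       max_intervals = max_intervals,
                       rel_improve = rel_improve)),
    class = "interval_report")
}

#' Micro-optimise the edges of an interval
#'
#' Hill-climbing refinement of a selected interval: one wavelength at a time,
#' each admissible edge move (expand left, expand right, truncate left,
#' truncate right — tried in that order, first improving move accepted) is
#' evaluated by RMSECV on a fixed set of Monte Carlo splits, and the search
#' stops at a local minimum. The returned interval's RMSECV is never worse
#' than the input's on the same splits.
#'
#' @param ds A [spectra_dataset].
#' @param interval Either a length-2 integer vector `c(start, end)` or a
#'   one-row data frame with `start` and `end` columns (1-based, inclusive).
#' @param ncomp,n_v,N,seed As in [ipls()].
#' @param mode `"two_sided"` (default) adjusts both edges; `"one_sided"`
#'   locks onto whichever edge yields the first improvement.
#' @return A list with `start`, `end`, `start_wavenumber`, `end_wavenumber`,
#'   `rmsecv` (at the optimum) and `rmsecv_initial`.
#' @export
micro_optimize <- function(ds, interval, ncomp, n_v = 5, N = 20, seed = 1,
                           mode = c("two_sided", "one_sided")) {
  stopifnot(inherits(ds, "spectra_dataset"))
  mode <- match.arg(mode)
  if (is.data.frame(interval)) interval <- c(interval$start[1], interval$end[1])
  start <- as.integer(interval[1]); end <- as.integer(interval[2])
  p <- length(ds$wavenumbers)
  if (start < 1L || end > p || start > end)
    stop("invalid interval bounds", call. = FALSE)
  X <- ds$absorbance; y <- ds$concentration
  splits <- draw_splits_(y, n_v, N, seed)
  score <- function(s, e) interval_rmsecv_(X, y, s:e, ncomp, splits,
                                           warn_cap = FALSE)
  cur <- score(start, end)
  initial <- cur
  locked_edge <- NULL   # for one_sided mode: "left" or "right"
  repeat {
    moves <- list(
      list(edge = "left",  s = start - 1L, e = end),       # expand left
      list(edge = "right", s = start,      e = end + 1L),  # expand right
      list(edge = "left",  s = start + 1L, e = end),       # truncate left
      list(edge = "right", s = start,      e = end - 1L))  # truncate right
    improved <- FALSE
    for (mv in moves) {
      if (mv$s < 1L || mv$e > p || mv$s > mv$e) next
      if (mode == "one_sided" && !is.null(locked_edge) &&
          mv$edge != locked_edge) next
      val <- score(mv$s, mv$e)
      if (val < cur) {
        start <- mv$s; end <- mv$e; cur <- val
        if (mode == "one_sided" && is.null(locked_edge)) locked_edge <- mv$edge
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(start = start, end = end,
       start_wavenumber = ds$wavenumbers[start],
       end_wavenumber = ds$wavenumbers[end],
       rmsecv = cur, rmsecv_initial = initial)
}

#' Moving-window PLS (MWPLS)
#'
#' Slides a window of fixed odd length across the spectrum one wavelength at
#' a time and, for every position, fits local PLS models with `1..c_max`
#' latent variables, recording the training sum of squared residuals (SSR)
#' at each complexity. Informative windows reach a low SSR with few
#' components and gain little from more; windows over noise keep a high SSR
#' or improve only by absorbing noise into extra components.
#'
#' @param ds A [spectra_dataset].
#' @param window_length Odd window width in wavelengths (default 31).
#' @param c_max Largest latent-variable count per window.
#' @return An `mwpls_report`: `window_length`, `centers` (window-centre
#'   indices), and `ssr_curves` (`length(centers) x c_max` matrix, row `i`
#'   giving the SSR of the window centred at `centers[i]` for each count).
#' @seealso [mwpls_regions()]
#' @export
mwpls <- function(ds, window_length = 31, c_max = 5) {
  stopifnot(inherits(ds, "spectra_dataset"))
  window_length <- assert_count(window_length, "window_length")
  if (window_length %% 2L == 0L)
    stop("`window_length` must be odd so windows are centred", call. = FALSE)
  p <- length(ds$wavenumbers)
  if (window_length > p) stop("window longer than the spectrum", call. = FALSE)
  c_max <- assert_count(c_max, "c_max")
  n <- nrow(ds$absorbance)
  if (c_max > min(n - 1L, window_length))
    stop("`c_max` infeasible for this window length", call. = FALSE)
  half <- (window_length - 1L) %/% 2L
  centers <- seq.int(half + 1L, p - half)
  y <- ds$concentration
  ssr <- matrix(0, length(centers), c_max)
  for (i in seq_along(centers)) {
    cols <- (centers[i] - half):(centers[i] + half)
    m <- fit_pls(ds$absorbance[, cols, drop = FALSE], y, c_max)
    ssr[i, ] <- m$ssr_per_component
  }
  structure(
    list(window_length = window_length, centers = centers, ssr_curves = ssr,
         wavenumbers = ds$wavenumbers[centers]),
    class = "mwpls_report")
}

#' @export
print.mwpls_report <- function(x, ...) {
  cat(sprintf("mwpls_report: %d windows of length %d, up to %d components\n",
              length(x$centers), x$window_length, ncol(x$ssr_curves)))
  invisible(x)
}

#' Infer informative regions from a moving-window PLS report
#'
#' Deterministic helper implementing the qualitative low-SSR-with-few-
#' components criterion: window centres whose SSR at `c_ref` components
#' falls below `fraction` times the median SSR at `c_ref` across all
#' windows are flagged informative.
#'
#' @param report An `mwpls_report`.
#' @param c_ref Component count at which to read the SSR (default 3).
#' @param fraction Fraction of the median SSR used as threshold (default 0.5).
#' @return Logical vector over window centres.
#' @export
mwpls_regions <- function(report, c_ref = 3, fraction = 0.5) {
  stopifnot(inherits(report, "mwpls_report"))
  c_ref <- assert_count(c_ref, "c_ref")
  if (c_ref > ncol(report$ssr_curves))
    stop("`c_ref` exceeds the component counts stored", call. = FALSE)
  s <- report$ssr_curves[, c_ref]
  s < fraction * stats::median(s)
}
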