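# Comparison harness: selection -> MCCV -> independent-test evaluation, one
# report row per method.

#' Compare wavelength-selection methods on one dataset
#'
#' Runs the full benchmarking workflow: (1) a representative test set of
#' `test_n` samples is held out from all selection steps; (2) each requested
#' method selects wavelengths on the remaining training samples; (3) the
#' reduced model is Monte Carlo cross-validated (`mccv_N` iterations,
#' `mccv_n_v` held out per iteration); (4) the reduced model, fitted on the
#' training samples, is evaluated on the held-out test set (RMSEP and
#' percent R-squared). One row per method is returned.
#'
#' @param ds A [spectra_dataset].
#' @param methods Character vector drawn from `"full"`, `"beta"`, `"euv"`,
#'   `"ipls"`, `"fs_ipls"`, `"mwpls"`, `"ga"`.
#' @param test_n Independent test-set size (default 8).
#' @param mccv_N Monte Carlo iterations for the reported RMSECV (default
#'   10000).
#' @param mccv_n_v Held-out samples per Monte Carlo iteration (default 5).
#' @param n_components `"auto"` (PRESS elbow on the selected-variable
#'   training matrix) or a fixed integer.
#' @param seed Integer master seed; every stage derives its own stream.
#' @param method_params Named list of per-method parameter lists forwarded
#'   to the selectors, e.g. `list(ipls = list(k = 20))`.
#' @param mccv_on_all If `TRUE` (default) the reported RMSECV resamples the
#'   full dataset; if `FALSE` only the training samples enter the MCCV.
#' @param output_dir If given, the report is written there as TSV and JSON
#'   together with per-method selection masks.
#' @param verbose Print one line per method as it completes.
#' @return A `comparison_report` data frame with columns `method`, `n_vars`,
#'   `n_LVs`, `RMSECV`, `RMSEP`, `R2_test`.
#' @export
run_comparison <- function(ds,
                           methods = c("full", "beta", "euv", "ipls",
                                       "fs_ipls", "mwpls", "ga"),
                           test_n = 8, mccv_N = 10000, mccv_n_v = 5,
                           n_components = "auto", seed = 1,
                           method_params = list(), mccv_on_all = TRUE,
                           output_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(ds, "spectra_dataset"))
  methods <- match.arg(methods, several.ok = TRUE)
  p <- length(ds$wavenumbers)
  split <- representative_test_split(ds, test_n, seed)
  tr <- split$calibration; te <- split$validation
  Xtr <- ds$absorbance[tr, , drop = FALSE]
  ytr <- ds$concentration[tr]

  pick_ncomp <- function(X, y, sd_seed) {
    if (identical(n_components, "auto")) {
      cmax <- min(10L, nrow(X) - mccv_n_v - 1L, ncol(X))
      select_components_elbow(
        press_curve(X, y, cmax, n_v = mccv_n_v, N = 20, seed = sd_seed))
    } else assert_count(n_components, "n_components")
  }

  rows <- vector("list", length(methods))
  masks <- list()
  for (mi in seq_along(methods)) {
    method <- methods[mi]
    mseed <- seed + 1000L * mi
    mp <- method_params[[method]]
    mask <- switch(
      method,
      full = rep(TRUE, p),
      beta = {
        a <- c(list(X = Xtr, y = ytr,
                    ncomp = pick_ncomp(Xtr, ytr, mseed), seed = mseed), mp)
        do.call(beta_importance, a)$mask
      },
      euv = {
        a <- c(list(X = Xtr, y = ytr,
                    ncomp = pick_ncomp(Xtr, ytr, mseed), seed = mseed), mp)
        do.call(euv_select, a)$mask
      },
      ipls = {
        dtr <- spectra_dataset(ds$wavenumbers, Xtr, ytr)
        a <- c(list(ds = dtr, ncomp = pick_ncomp(Xtr, ytr, mseed),
                    seed = mseed),
               if (is.null(mp$k)) list(k = 20) else NULL, mp)
        do.call(ipls, a)$final_mask
      },
      fs_ipls = {
        dtr <- spectra_dataset(ds$wavenumbers, Xtr, ytr)
        a <- c(list(ds = dtr, ncomp = pick_ncomp(Xtr, ytr, mseed),
                    seed = mseed),
               if (is.null(mp$k)) list(k = 20) else NULL, mp)
        do.call(fs_ipls, a)$final_mask
      },
      mwpls = {
        dtr <- spectra_dataset(ds$wavenumbers, Xtr, ytr)
        a <- c(list(ds = dtr), mp)
        rep_ <- do.call(mwpls, a)
        reg <- mwpls_regions(rep_)
        m <- logical(p)
        half <- (rep_$window_length - 1L) %/% 2L
        for (ci in rep_$centers[reg])
          m[max(1L, ci - half):min(p, ci + half)] <- TRUE
        if (!any(m)) {
          warning("mwpls criterion selected no region; falling back to the lowest-SSR window")
          ci <- rep_$centers[which.min(rep_$ssr_curves[, ncol(rep_$ssr_curves)])]
          m[max(1L, ci - half):min(p, ci + half)] <- TRUE
        }
        m
      },
      ga = {
        base <- list(n_components = pick_ncomp(Xtr, ytr, mseed), seed = mseed)
        cfg <- do.call(ga_config, utils::modifyList(base, if (is.null(mp)) list() else mp))
        ens <- ensemble_ga(Xtr, ytr, cfg)
        select_by_probability(ens, 0.6)$mask
      })
    masks[[method]] <- mask
    cols <- which(mask)
    Xsel_tr <- Xtr[, cols, drop = FALSE]
    nc <- pick_ncomp(Xsel_tr, ytr, mseed + 1L)
    Xcv <- if (mccv_on_all) ds$absorbance[, cols, drop = FALSE] else Xsel_tr
    ycv <- if (mccv_on_all) ds$concentration else ytr
    cv <- mccv(Xcv, ycv, nc, mccv_n_v, mccv_N, seed = mseed + 2L)
    m_fit <- fit_pls(Xsel_tr, ytr, nc)
    yhat <- predict(m_fit, ds$absorbance[te, cols, drop = FALSE])
    rows[[mi]] <- data.frame(
      method = method, n_vars = length(cols), n_LVs = nc,
      RMSECV = cv$rmsecv_mc,
      RMSEP = rmsep(ds$concentration[te], yhat),
      R2_test = r2_test(ds$concentration[te], yhat))
    if (verbose)
      message(sprintf("%-8s n_vars=%5d LVs=%d RMSECV=%.4f RMSEP=%.4f R2=%.4f",
                      method, length(cols), nc, cv$rmsecv_mc,
                      rows[[mi]]$RMSEP, rows[[mi]]$R2_test))
  }
  report <- do.call(rbind, rows)
  class(report) <- c("comparison_report", "data.frame")
  attr(report, "test_indices") <- te
  attr(report, "masks") <- masks
  attr(report, "seed") <- seed
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(format_report(report), file.path(output_dir, "report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    for (m in names(masks))
      utils::write.table(
        data.frame(wavenumber = ds$wavenumbers,
                   selected = as.integer(masks[[m]])),
        file.path(output_dir, paste0("mask_", m, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
  }
  report
}

# Report with RMSECV/RMSEP to 4 decimals, R2 to 4 decimals, for printing.
format_report <- function(report) {
  out <- as.data.frame(report)
  out$RMSECV <- sprintf("%.4f", out$RMSECV)
  out$RMSEP <- sprintf("%.4f", out$RMSEP)
  out$R2_test <- sprintf("%.4f", out$R2_test)
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report (errors in mmol/L, R2 in percent):\n")
  print(format_report(x), row.names = FALSE)
  invisible(x)
}
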