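# Genetic-algorithm wavelength selection with resampled fitness, per-run
# holdout acceptance, and multi-run co-selection statistics.

#' Genetic-algorithm configuration
#'
#' Collects every tunable of the GA selector. The three anti-overfitting
#' devices are baked into the defaults: (1) each run sets aside its own
#' holdout split and accepts its final solution only if the holdout RMSEV is
#' at most `acceptance_factor` times that of the full-spectrum model;
#' (2) chromosome fitness is the mean calibration MSE over
#' `fitness_mccv_iters` Monte Carlo resampling iterations rather than a
#' single fit; (3) the whole algorithm is repeated `n_runs` times and
#' wavelength importance is read off the across-run selection frequency.
#'
#' @param n_components Latent-variable count used inside every fitness
#'   evaluation and for the full-model baseline.
#' @param population_size Number of chromosomes per generation (default 64).
#' @param generations Number of generations per run (default 100).
#' @param crossover_rate Probability that a selected pair recombines
#'   (default 0.9).
#' @param crossover_type `"uniform"` (default) mixes bits independently;
#'   `"two_point"` swaps one contiguous segment, preserving the positional
#'   linkage of neighbouring wavelengths (spectral bands are contiguous bit
#'   blocks, so segment crossover propagates them as units).
#' @param mutation_rate Per-bit mutation probability; default `NULL` means
#'   `1/p`, resolved when the data are seen.
#' @param init_density Probability that a bit starts selected (default 0.5).
#' @param tournament_size Individuals drawn per tournament selection event
#'   (default 2; larger values increase selection pressure).
#' @param fitness_mccv_iters Resampling iterations per fitness evaluation
#'   (default 100).
#' @param fitness_n_v Validation size inside fitness resampling; default
#'   `NULL` means `max(2, floor(0.2 * n))` resolved against the data.
#' @param holdout_n_v Run-level holdout size (default 5).
#' @param acceptance_factor Holdout acceptance multiplier (default 1.5).
#' @param n_runs Number of GA repetitions for the ensemble (default 100).
#' @param seed Master seed; run `i` uses `seed + i`.
#' @return A `ga_config` list.
#' @export
ga_config <- function(n_components,
                      population_size = 64,
                      generations = 100,
                      crossover_rate = 0.9,
                      crossover_type = c("uniform", "two_point"),
                      mutation_rate = NULL,
                      init_density = 0.5,
                      tournament_size = 2,
                      fitness_mccv_iters = 100,
                      fitness_n_v = NULL,
                      holdout_n_v = 5,
                      acceptance_factor = 1.5,
                      n_runs = 100,
                      seed = 1) {
  cfg <- list(
    n_components = assert_count(n_components, "n_components"),
    population_size = assert_count(population_size, "population_size", min = 2L),
    generations = assert_count(generations, "generations"),
    crossover_rate = assert_prob(crossover_rate, "crossover_rate"),
    crossover_type = match.arg(crossover_type),
    mutation_rate = if (!is.null(mutation_rate))
      assert_prob(mutation_rate, "mutation_rate"),
    init_density = assert_prob(init_density, "init_density"),
    tournament_size = assert_count(tournament_size, "tournament_size", min = 2L),
    fitness_mccv_iters = assert_count(fitness_mccv_iters, "fitness_mccv_iters"),
    fitness_n_v = if (!is.null(fitness_n_v))
      assert_count(fitness_n_v, "fitness_n_v"),
    holdout_n_v = assert_count(holdout_n_v, "holdout_n_v"),
    acceptance_factor = as.numeric(acceptance_factor),
    n_runs = assert_count(n_runs, "n_runs"),
    seed = seed)
  if (cfg$acceptance_factor <= 0)
    stop("`acceptance_factor` must be positive", call. = FALSE)
  structure(cfg, class = "ga_config")
}

# Worst-possible unfitness sentinel for infeasible chromosomes (too few bits
# to support the latent variables). Keeps the GA loop exception-free.
GA_WORST <- .Machine$double.xmax

# Evaluate one chromosome on (X, y) using the current RNG stream.
# Returns mean MSEC (the unfitness), mean MSEV, pooled RMSECV; optionally
# appends every validation-index set to `tracker` (an environment) for
# holdout-isolation instrumentation. Uses the compiled fit/predict kernel;
# numerically equivalent to fit_pls + predict (asserted in the tests).
ga_eval_ <- function(chrom, X, y, ncomp, n_v, iters, tracker = NULL,
                     splits = NULL) {
  cols <- which(chrom)
  if (length(cols) < ncomp + 1L)
    return(list(msec = GA_WORST, msev = GA_WORST, rmsecv = NA_real_))
  Xs <- X[, cols, drop = FALSE]
  msec <- 0; msev <- 0; vss <- 0; nv_tot <- 0L
  for (i in seq_len(iters)) {
    s <- if (is.null(splits)) block_split_(y, n_v) else splits[[i]]
    if (!is.null(tracker)) tracker$splits[[length(tracker$splits) + 1L]] <- s$validation
    f <- .pls_fit_predict_cpp(Xs, y, s$calibration - 1L, s$validation - 1L,
                              ncomp)
    msec <- msec + f$msec
    r <- y[s$validation] - drop(f$pred)
    msev <- msev + sum(r^2) / length(r)
    vss <- vss + sum(r^2); nv_tot <- nv_tot + length(r)
  }
  list(msec = msec / iters, msev = msev / iters, rmsecv = sqrt(vss / nv_tot))
}

#' Resampled fitness of a chromosome
#'
#' The unfitness (lower is better) of a wavelength subset: the spectra are
#' restricted to the selected columns and `fitness_mccv_iters` random
#' block-stratified calibration/validation splits are run; the returned
#' value is the mean calibration MSE across iterations. The mean validation
#' MSE and the pooled RMSECV are attached as attributes `"msev_mean"` and
#' `"rmsecv"` for diagnostics. A chromosome with fewer than
#' `n_components + 1` selected wavelengths receives a worst-possible
#' sentinel value instead of raising an error.
#'
#' @param chromosome Logical (or 0/1) vector over wavelengths.
#' @param X Spectra matrix, `y` concentrations.
#' @param y Response vector.
#' @param cfg A [ga_config()].
#' @param seed Integer seed.
#' @return Scalar mean MSEC with diagnostic attributes.
#' @export
ga_fitness <- function(chromosome, X, y, cfg, seed) {
  X <- assert_matrix(X)
  chromosome <- as.logical(chromosome)
  if (length(chromosome) != ncol(X))
    stop("chromosome length must equal ncol(X)", call. = FALSE)
  n_v <- if (is.null(cfg$fitness_n_v)) max(2L, floor(0.2 * nrow(X)))
         else cfg$fitness_n_v
  ev <- with_seed(seed,
    ga_eval_(chromosome, X, y, cfg$n_components, n_v, cfg$fitness_mccv_iters))
  structure(ev$msec, msev_mean = ev$msev, rmsecv = ev$rmsecv)
}

#' One run of the genetic-algorithm wavelength search
#'
#' Splits a run-level holdout off the training data (block-stratified,
#' `holdout_n_v` samples), evolves a population of bit-string chromosomes on
#' the remainder with tournament selection (size 2), uniform crossover,
#' per-bit mutation and single elitism, then evaluates the final best
#' chromosome on the holdout exactly once. The run is accepted when that
#' holdout RMSEV is at most `acceptance_factor` times the holdout RMSEV of
#' the full-spectrum model with the same latent-variable count; otherwise
#' the solution is discarded by the ensemble. Elites are exempt from
#' mutation and carry their stored fitness, so the best fitness per
#' generation is non-increasing.
#'
#' @param X Training spectra (`n x p`), `y` training concentrations.
#' @param y Response vector.
#' @param cfg A [ga_config()].
#' @param run_seed Integer seed; the run is fully deterministic given it.
#' @param store_history If `TRUE`, keep the generation-best chromosome per
#'   generation as a bit matrix.
#' @param instrument If `TRUE`, record every fitness-evaluation validation
#'   index set (in training-row coordinates) in `fitness_val_indices`, to
#'   audit that the holdout never leaks into fitness evaluation.
#' @return A `ga_run_result`: `best_chromosome` (logical `p`),
#'   `fitness_history` (best mean-MSEC per generation), `rmsev_history`
#'   (holdout RMSEV of each generation's best, diagnostic), `rmsecv_history`
#'   (pooled RMSECV of each generation's best), `holdout_rmsev`,
#'   `holdout_rmsev_full`, `accepted`, `holdout_indices`, and optionally
#'   `chromosome_history` / `fitness_val_indices`.
#' @export
run_ga <- function(X, y, cfg, run_seed, store_history = FALSE,
                   instrument = FALSE) {
  X <- assert_matrix(X)
  y <- as.numeric(y)
  stopifnot(inherits(cfg, "ga_config"))
  n <- nrow(X); p <- ncol(X)
  if (cfg$holdout_n_v >= n - 1L)
    stop("holdout_n_v leaves too few samples for evolution", call. = FALSE)
  n_rem <- n - cfg$holdout_n_v
  n_v <- if (is.null(cfg$fitness_n_v)) max(2L, floor(0.2 * n_rem))
         else cfg$fitness_n_v
  if (n_v >= n_rem)
    stop("fitness_n_v must be smaller than the non-holdout sample count",
         call. = FALSE)
  if (cfg$n_components > min(n_rem - n_v - 1L, p))
    stop("n_components infeasible for the fitness splits", call. = FALSE)
  mut <- if (is.null(cfg$mutation_rate)) 1 / p else cfg$mutation_rate
  tracker <- if (instrument) new.env() else NULL
  if (instrument) tracker$splits <- list()

  with_seed(run_seed, {
    hold <- block_split_(y, cfg$holdout_n_v)
    rem <- hold$calibration; ho <- hold$validation
    Xr <- X[rem, , drop = FALSE]; yr <- y[rem]
    # full-spectrum baseline on the same holdout
    m_full <- fit_pls(Xr, yr, cfg$n_components)
    rmsev_full <- rmsep(y[ho], predict(m_full, X[ho, , drop = FALSE]))

    pop <- matrix(stats::runif(cfg$population_size * p) < cfg$init_density,
                  cfg$population_size, p)
    fit_hist <- numeric(cfg$generations)
    rmsev_hist <- numeric(cfg$generations)
    rmsecv_hist <- numeric(cfg$generations)
    chrom_hist <- if (store_history)
      matrix(FALSE, cfg$generations, p) else NULL
    elite <- NULL; elite_fit <- Inf

    for (g in seq_len(cfg$generations)) {
      scores <- numeric(cfg$population_size)
      evals <- vector("list", cfg$population_size)
      for (i in seq_len(cfg$population_size)) {
        if (!is.null(elite) && i == 1L && all(pop[1L, ] == elite)) {
          # the carried elite keeps its stored fitness; re-evaluating it on
          # fresh splits would let the per-generation best worsen
          scores[i] <- elite_fit
          evals[[i]] <- elite_eval
        } else {
          ev <- ga_eval_(pop[i, ], Xr, yr, cfg$n_components, n_v,
                         cfg$fitness_mccv_iters, tracker)
          scores[i] <- ev$msec
          evals[[i]] <- ev
        }
      }
      b <- which.min(scores)
      elite <- pop[b, ]; elite_fit <- scores[b]; elite_eval <- evals[[b]]
      fit_hist[g] <- elite_fit
      rmsecv_hist[g] <- elite_eval$rmsecv
      rmsev_hist[g] <- if (sum(elite) >= cfg$n_components + 1L) {
        mg <- fit_pls(Xr[, elite, drop = FALSE], yr, cfg$n_components)
        rmsep(y[ho], predict(mg, X[ho, elite, drop = FALSE]))
      } else NA_real_
      if (store_history) chrom_hist[g, ] <- elite

      if (g < cfg$generations) {
        newpop <- matrix(FALSE, cfg$population_size, p)
        newpop[1L, ] <- elite
        i <- 2L
        while (i <= cfg$population_size) {
          p1 <- tournament_(scores, cfg$tournament_size)
          p2 <- tournament_(scores, cfg$tournament_size)
          kids <- crossover_(pop[p1, ], pop[p2, ], cfg$crossover_rate,
                             cfg$crossover_type)
          for (kid in kids) {
            if (i > cfg$population_size) break
            flip <- stats::runif(p) < mut
            newpop[i, ] <- xor(kid, flip)
            i <- i + 1L
          }
        }
        pop <- newpop
      }
    }

    holdout_rmsev <- rmsev_hist[cfg$generations]
    accepted <- is.finite(holdout_rmsev) &&
      holdout_rmsev <= cfg$acceptance_factor * rmsev_full
    out <- list(best_chromosome = elite, fitness_history = fit_hist,
                rmsev_history = rmsev_hist, rmsecv_history = rmsecv_hist,
                holdout_rmsev = holdout_rmsev,
                holdout_rmsev_full = rmsev_full, accepted = accepted,
                holdout_indices = ho, run_seed = run_seed)
    if (store_history) out$chromosome_history <- chrom_hist
    if (instrument)
      out$fitness_val_indices <- lapply(tracker$splits, function(v) rem[v])
    structure(out, class = "ga_run_result")
  })
}

tournament_ <- function(scores, k = 2L) {
  i <- sample.int(length(scores), k, replace = TRUE)
  i[which.min(scores[i])]
}

crossover_ <- function(a, b, rate, type = "uniform") {
  if (stats::runif(1) >= rate) return(list(a, b))
  if (type == "uniform") {
    m <- stats::runif(length(a)) < 0.5
  } else {                       # two_point: swap one contiguous segment
    cut <- sort(sample.int(length(a) + 1L, 2L) - 1L)
    m <- rep(FALSE, length(a))
    if (cut[2L] > cut[1L]) m[(cut[1L] + 1L):cut[2L]] <- TRUE
  }
  list(ifelse(m, a, b), ifelse(m, b, a))
}

#' @export
print.ga_run_result <- function(x, ...) {
  cat(sprintf("ga_run_result: %d generations, final fitness %.6g, holdout RMSEV %.4f (full %.4f), %s\n",
              length(x$fitness_history), x$fitness_history[length(x$fitness_history)],
              x$holdout_rmsev, x$holdout_rmsev_full,
              if (x$accepted) "accepted" else "discarded"))
  invisible(x)
}

#' Multi-run GA ensemble with co-selection statistics
#'
#' Repeats [run_ga()] `n_runs` times with child seeds `seed + 1 .. seed +
#' n_runs`, stacks the accepted best chromosomes into the bit matrix `G`
#' (one row per accepted run), and computes the co-selection matrix
#' `H = t(G) %*% G` — entry `(i, j)` counts the runs in which wavelengths
#' `i` and `j` were selected together — and the per-wavelength selection
#' probability `p_ga`. Runs whose holdout check fails are discarded and do
#' not enter `G`.
#'
#' @param X Training spectra, `y` training concentrations.
#' @param y Response vector.
#' @param cfg A [ga_config()]; `cfg$seed` and `cfg$n_runs` drive the runs.
#' @param p_ga_denominator `"accepted"` (default) divides selection counts
#'   by the number of accepted runs; `"total"` divides by all runs launched.
#'   Both counts are recorded either way.
#' @return A `ga_ensemble`: `G` (integer bit matrix, accepted runs x p),
#'   `H` (integer `p x p`), `p_ga`, `n_runs_total`, `n_runs_accepted`,
#'   `runs` (the per-run results).
#' @export
ensemble_ga <- function(X, y, cfg, p_ga_denominator = c("accepted", "total")) {
  stopifnot(inherits(cfg, "ga_config"))
  p_ga_denominator <- match.arg(p_ga_denominator)
  X <- assert_matrix(X)
  # child seeds drawn once from the master seed: reproducible, independent
  # of execution order, and without overlap between nearby master seeds
  child_seeds <- with_seed(cfg$seed,
                           sample.int(.Machine$integer.max, cfg$n_runs))
  runs <- lapply(seq_len(cfg$n_runs), function(i)
    run_ga(X, y, cfg, run_seed = child_seeds[i]))
  acc <- vapply(runs, `[[`, logical(1), "accepted")
  if (!any(acc))
    stop("no GA run passed the holdout acceptance check; reconsider the configuration (more generations, more components, or a larger acceptance_factor)",
         call. = FALSE)
  G <- do.call(rbind, lapply(runs[acc], function(r) as.integer(r$best_chromosome)))
  storage.mode(G) <- "integer"
  H <- crossprod(G)
  storage.mode(H) <- "integer"
  denom <- if (p_ga_denominator == "accepted") sum(acc) else cfg$n_runs
  structure(
    list(G = G, H = H, p_ga = diag(H) / denom,
         n_runs_total = cfg$n_runs, n_runs_accepted = sum(acc),
         p_ga_denominator = p_ga_denominator, runs = runs, config = cfg),
    class = "ga_ensemble")
}

#' @export
print.ga_ensemble <- function(x, ...) {
  cat(sprintf("ga_ensemble: %d/%d runs accepted, p = %d wavelengths, max p_ga = %.2f\n",
              x$n_runs_accepted, x$n_runs_total, ncol(x$G), max(x$p_ga)))
  invisible(x)
}

#' Threshold the GA selection probabilities
#'
#' Selects every wavelength whose across-run selection probability `p_ga`
#' reaches `threshold` (default 0.6, i.e. present in the final solution of
#' at least 60 percent of runs).
#'
#' @param ens A `ga_ensemble`.
#' @param threshold Probability threshold in `[0, 1]`.
#' @return A `selection_result` with `method = "ga"` and `score = p_ga`.
#' @export
select_by_probability <- function(ens, threshold = 0.6) {
  stopifnot(inherits(ens, "ga_ensemble"))
  threshold <- assert_prob(threshold, "threshold")
  selection_result("ga", ens$p_ga, ens$p_ga >= threshold,
                   params = list(threshold = threshold,
                                 n_runs_total = ens$n_runs_total,
                                 n_runs_accepted = ens$n_runs_accepted,
                                 p_ga_denominator = ens$p_ga_denominator))
}

#' Synchronous two-dimensional correlation spectrum
#'
#' The synchronous correlation matrix of a spectra set:
#' `Phi = t(Xc) %*% Xc / (n - 1)` with `Xc` the column-mean-centred spectra.
#' Its diagonal is the per-wavelength variance and off-diagonal entries the
#' covariance between wavelength pairs across samples. Useful as a
#' model-free comparison surface for the GA co-selection matrix `H`.
#'
#' @param X Spectra matrix (`n x p`, `n >= 2`).
#' @return A symmetric `p x p` matrix.
#' @export
synchronous_2d_correlation <- function(X) {
  X <- assert_matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 spectra", call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  crossprod(Xc) / (nrow(X) - 1L)
}

#' Write a GA ensemble to disk
#'
#' Emits `<prefix>_G.tsv` (bit matrix, one accepted run per row),
#' `<prefix>_H.tsv` (co-selection counts), `<prefix>_p_ga.tsv`
#' (wavenumber, selection probability) and `<prefix>_config.json`.
#'
#' @param ens A `ga_ensemble`.
#' @param wavenumbers Wavenumber axis of length `p`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_ga_ensemble <- function(ens, wavenumbers, prefix) {
  stopifnot(inherits(ens, "ga_ensemble"),
            length(wavenumbers) == ncol(ens$G))
  paths <- paste0(prefix, c("_G.tsv", "_H.tsv", "_p_ga.tsv", "_config.json"))
  utils::write.table(ens$G, paths[1], sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(ens$H, paths[2], sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(data.frame(wavenumber = wavenumbers, p_ga = ens$p_ga),
                     paths[3], sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- ens$config
  jsonlite::write_json(
    c(unclass(cfg),
      list(n_runs_accepted = ens$n_runs_accepted,
           p_ga_denominator = ens$p_ga_denominator)),
    paths[4], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
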