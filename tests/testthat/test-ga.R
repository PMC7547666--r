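# Small configurations keep these runs in seconds; the full-scale behaviour
# is exercised by the recovery benchmark in test-acceptance.R.
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_components = 2, population_size = 12, generations = 8,
         fitness_mccv_iters = 5, holdout_n_v = 4, n_runs = 3, seed = 17),
    list(...))
  do.call(ga_config, args)
}

test_that("the compiled fit/predict kernel agrees with the R NIPALS path", {
  set.seed(61)
  for (rep in 1:5) {
    n <- sample(12:25, 1); p <- sample(3:30, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% rnorm(p) * 0.3) + rnorm(n)
    s <- block_stratified_split(y - min(y), 4, seed = rep)
    nc <- min(3L, p)
    f <- wavesel:::.pls_fit_predict_cpp(X, y, s$calibration - 1L,
                                        s$validation - 1L, nc)
    m <- fit_pls(X[s$calibration, , drop = FALSE], y[s$calibration], nc)
    expect_equal(f$msec, m$ssr_train / length(s$calibration), tolerance = 1e-10)
    expect_equal(drop(f$pred),
                 predict(m, X[s$validation, , drop = FALSE]),
                 tolerance = 1e-8)
  }
})

test_that("fitness is near zero for a perfect subset and sentinel for infeasible ones", {
  # selected submatrix has rank 2 (third column is the sum of the first
  # two), so two latent variables reproduce the noiseless response exactly
  # while the chromosome still satisfies the >= ncomp + 1 feasibility rule
  set.seed(67)
  X <- matrix(rnorm(30 * 10), 30, 10)
  X[, 3] <- X[, 1] + X[, 2]
  y <- drop(X[, 1:2] %*% c(1, -2))
  cfg <- tiny_cfg(n_components = 2, fitness_mccv_iters = 10)
  chrom <- rep(FALSE, 10); chrom[1:3] <- TRUE
  f <- ga_fitness(chrom, X, y, cfg, seed = 5)
  expect_lt(as.numeric(f), 1e-16)
  expect_true(is.finite(attr(f, "rmsecv")))

  f0 <- ga_fitness(rep(FALSE, 10), X, y, cfg, seed = 5)
  expect_equal(as.numeric(f0), .Machine$double.xmax)
  f1 <- ga_fitness(c(TRUE, rep(FALSE, 9)), X, y, cfg, seed = 5)  # < ncomp+1 bits
  expect_equal(as.numeric(f1), .Machine$double.xmax)
})

test_that("a superset of the true variables beats a noise-only chromosome", {
  set.seed(71)
  X <- matrix(rnorm(30 * 12), 30, 12)
  y <- 2 * X[, 4] + rnorm(30, sd = 0.4)
  cfg <- tiny_cfg(fitness_mccv_iters = 20)
  super <- rep(FALSE, 12); super[c(4, 7, 9)] <- TRUE
  noise <- rep(FALSE, 12); noise[c(7, 9, 11)] <- TRUE
  expect_lt(as.numeric(ga_fitness(super, X, y, cfg, seed = 9)),
            as.numeric(ga_fitness(noise, X, y, cfg, seed = 9)))
})

test_that("run_ga handles boundary configurations and is deterministic", {
  sim <- reduced_sim(noise_sd = 2e-3)
  X <- sim$dataset$absorbance[, 1:40]
  y <- sim$dataset$concentration
  cfg <- tiny_cfg(population_size = 2, generations = 1)
  r <- run_ga(X, y, cfg, run_seed = 3)
  expect_length(r$fitness_history, 1L)
  expect_length(r$rmsev_history, 1L)

  cfg2 <- tiny_cfg()
  r1 <- run_ga(X, y, cfg2, run_seed = 23, store_history = TRUE)
  r2 <- run_ga(X, y, cfg2, run_seed = 23, store_history = TRUE)
  expect_identical(r1, r2)
  expect_equal(dim(r1$chromosome_history), c(8L, 40L))
})

test_that("elitism makes the best fitness non-increasing, even on permuted responses", {
  sim <- reduced_sim(noise_sd = 6e-3)
  X <- sim$dataset$absorbance[, seq(1, 300, by = 5)]
  y <- sim$dataset$concentration
  r <- run_ga(X, y, tiny_cfg(generations = 12), run_seed = 2)
  expect_true(all(diff(r$fitness_history) <= 0))

  set.seed(83)
  yp <- sample(y)
  rp <- run_ga(X, yp, tiny_cfg(generations = 12), run_seed = 2)
  expect_true(all(diff(rp$fitness_history) <= 0))
})

test_that("the run-level holdout never enters a fitness-evaluation split", {
  sim <- reduced_sim(noise_sd = 6e-3)
  X <- sim$dataset$absorbance[, seq(1, 300, by = 10)]
  y <- sim$dataset$concentration
  r <- run_ga(X, y, tiny_cfg(generations = 3), run_seed = 11, instrument = TRUE)
  expect_gt(length(r$fitness_val_indices), 0)
  leaks <- vapply(r$fitness_val_indices,
                  function(v) length(intersect(v, r$holdout_indices)),
                  integer(1))
  expect_identical(sum(leaks), 0L)
})

test_that("ensembles are reproducible and co-selection follows H = G'G", {
  sim <- reduced_sim(noise_sd = 6e-3)
  X <- sim$dataset$absorbance[, seq(1, 300, by = 20)]  # p = 15
  y <- sim$dataset$concentration
  cfg <- tiny_cfg(n_runs = 4, generations = 6)
  e1 <- ensemble_ga(X, y, cfg)
  e2 <- ensemble_ga(X, y, cfg)
  expect_identical(e1$G, e2$G)
  expect_identical(e1$H, e2$H)
  expect_identical(e1$p_ga, e2$p_ga)

  # brute-force oracle for H on p <= 20: double loop over wavelength pairs
  G <- e1$G
  H_oracle <- matrix(0L, ncol(G), ncol(G))
  for (i in seq_len(ncol(G))) for (j in seq_len(ncol(G)))
    H_oracle[i, j] <- sum(G[, i] * G[, j])
  expect_identical(unname(e1$H), H_oracle)
  expect_identical(e1$H, t(e1$H))
  expect_true(all(diag(e1$H) >= e1$H - .Machine$double.eps))
  expect_equal(unname(e1$p_ga), unname(diag(e1$H)) / e1$n_runs_accepted)
})

test_that("probability thresholding follows the hand-worked convention", {
  G <- rbind(c(1L, 1L, 0L), c(0L, 1L, 0L))
  H <- crossprod(G)
  storage.mode(H) <- "integer"
  ens <- structure(list(G = G, H = H, p_ga = c(0.5, 1, 0), n_runs_total = 2,
                        n_runs_accepted = 2, p_ga_denominator = "accepted"),
                   class = "ga_ensemble")
  expect_identical(unname(ens$H),
                   rbind(c(1L, 1L, 0L), c(1L, 2L, 0L), c(0L, 0L, 0L)))
  sel <- select_by_probability(ens, 0.6)
  expect_identical(sel$mask, c(FALSE, TRUE, FALSE))
  expect_identical(select_by_probability(ens, 0)$mask, rep(TRUE, 3))
  expect_error(select_by_probability(ens, 1.01), "probability")
})

test_that("the synchronous 2D correlation spectrum has its closed-form structure", {
  set.seed(91)
  X <- matrix(rnorm(40), 10, 4)
  X[, 2] <- 2 * X[, 1]                      # perfectly correlated pair
  phi <- synchronous_2d_correlation(X)
  expect_identical(phi, t(phi))
  expect_equal(diag(phi), apply(X, 2, var))
  expect_equal(phi[1, 2], sqrt(var(X[, 1]) * var(X[, 2])))

  Xo <- cbind(c(-1, 1, -1, 1), c(-1, -1, 1, 1))  # centred orthogonal columns
  expect_equal(synchronous_2d_correlation(Xo)[1, 2], 0)
  expect_error(synchronous_2d_correlation(matrix(1, 1, 3)), "at least 2")
})

test_that("holdout acceptance applies the stated rule and discards some no-signal runs", {
  sim <- reduced_sim(noise_sd = 6e-3)
  X <- sim$dataset$absorbance[, seq(1, 300, by = 5)]   # p = 60
  y <- sim$dataset$concentration
  set.seed(97)
  yp <- sample(y)
  cfg <- tiny_cfg(population_size = 16, generations = 10,
                  fitness_mccv_iters = 10, n_runs = 1)
  runs <- lapply(1:8, function(i) run_ga(X, yp, cfg, run_seed = 400 + i))
  # the recorded decision always equals the recorded quantities' comparison
  for (r in runs)
    expect_identical(r$accepted,
                     r$holdout_rmsev <= cfg$acceptance_factor *
                       r$holdout_rmsev_full)
  # with a permuted (signal-free) response, not every run survives the rule
  expect_lt(sum(vapply(runs, `[[`, logical(1), "accepted")), 8L)
})
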