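# Small high-SNR fixture with one analyte band confined to a known region.
interval_fixture <- function(seed = 7, centers = 1090, widths = 10,
                             heights = 0.004, noise = 2e-4, bg_var = 0.02) {
  generate_spectra(sim_config(
    wavenumber_start = 1000, wavenumber_end = 1199,
    analyte_peaks = data.frame(center = centers, width = widths,
                               height = heights),
    background_peaks = data.frame(center = 1100, width = 60, height = 0.4),
    background_amplitude_sd = bg_var,
    noise_sd = noise, baseline_drift_amplitude = 1e-4,
    concentration_grid = seq(0, 18, length.out = 30), seed = seed))
}

overlaps_truth <- function(sim, from, to) {
  any(sim$ground_truth$informative_mask[from:to])
}

test_that("make_intervals partitions the axis into near-equal blocks, larger first", {
  iv <- make_intervals(10, 3)
  expect_equal(iv$end - iv$start + 1L, c(4L, 3L, 3L))
  iv20 <- make_intervals(3151, 20)
  sizes <- iv20$end - iv20$start + 1L
  expect_equal(sort(sizes), sort(c(rep(158L, 11), rep(157L, 9))))
  expect_equal(make_intervals(5, 1), data.frame(start = 1L, end = 5L))
  expect_error(make_intervals(3, 4), "exceed")

  # exact partition for all p <= 60 and every k
  for (p in c(1:12, 37, 60)) for (k in seq_len(p)) {
    iv <- make_intervals(p, k)
    covered <- unlist(Map(seq, iv$start, iv$end))
    expect_identical(sort(covered), 1:p)
  }
})

test_that("iPLS ranks the interval containing the analyte band first", {
  sim <- interval_fixture()
  rep_ <- ipls(sim$dataset, k = 10, ncomp = 2, n_v = 5, N = 15, seed = 3)
  best <- rep_$best_interval
  iv <- rep_$intervals
  # the winning interval overlaps the analyte band; all intervals without
  # any band wavelength score far worse
  expect_true(overlaps_truth(sim, iv$start[best], iv$end[best]))
  off_band <- vapply(seq_len(nrow(iv)), function(j)
    !overlaps_truth(sim, iv$start[j], iv$end[j]), logical(1))
  expect_gt(min(rep_$rmsecv_per_interval[off_band]),
            5 * min(rep_$rmsecv_per_interval))
  expect_equal(sum(rep_$final_mask), iv$end[best] - iv$start[best] + 1L)
})

test_that("iPLS with a single interval reduces to full-spectrum MCCV", {
  sim <- interval_fixture()
  ds <- sim$dataset
  rep_ <- ipls(ds, k = 1, ncomp = 2, n_v = 5, N = 10, seed = 9)
  cv <- mccv(ds$absorbance, ds$concentration, 2, 5, 10, seed = 9)
  expect_equal(rep_$rmsecv_per_interval[1], cv$rmsecv_mc)
})

test_that("identical informative intervals tie and break to the lower index", {
  set.seed(44)
  n <- 25
  z <- rnorm(n)
  y <- 2 * z + rnorm(n, sd = 0.1)
  half <- matrix(rnorm(n * 4, sd = 0.05), n, 4) + z  # informative block
  X <- cbind(half, half)                              # duplicated block
  ds <- spectra_dataset(1:8, X, y - min(y))
  rep_ <- ipls(ds, k = 2, ncomp = 1, n_v = 4, N = 8, seed = 5)
  expect_equal(rep_$rmsecv_per_interval[1], rep_$rmsecv_per_interval[2])
  expect_equal(rep_$best_interval, 1L)
})

test_that("FS-iPLS accumulates intervals covering split signal and stops on noise", {
  sim <- interval_fixture(centers = c(1030, 1160), widths = c(8, 8),
                          heights = c(0.004, 0.004))
  rep_ <- fs_ipls(sim$dataset, k = 10, ncomp = 2, n_v = 5, N = 15, seed = 3,
                  max_intervals = 5)
  iv <- rep_$intervals
  first2 <- rep_$selected_sequence[1:2]
  # both early picks land on informative regions, and together the two
  # disjoint bands (1014-1046 and 1144-1176 cm-1) are covered
  in_lo <- function(j) any(sim$dataset$wavenumbers[iv$start[j]:iv$end[j]] <= 1046)
  expect_true(all(vapply(first2, function(j)
    overlaps_truth(sim, iv$start[j], iv$end[j]), logical(1))))
  expect_length(unique(vapply(first2, in_lo, logical(1))), 2L)
  expect_true(all(diff(rep_$rmsecv_trajectory) <= 0))

  # no-signal spectra: forward selection stops almost immediately
  for (seed in c(2, 5)) {
    set.seed(300 + seed)
    ds0 <- spectra_dataset(1:60, matrix(rnorm(30 * 60), 30, 60),
                           seq(0, 18, length.out = 30))
    r0 <- fs_ipls(ds0, k = 6, ncomp = 2, n_v = 5, N = 10, seed = seed)
    expect_lte(length(r0$selected_sequence), 2L)
  }
})

test_that("FS-iPLS with max_intervals = 1 equals the iPLS best interval", {
  sim <- interval_fixture()
  r1 <- fs_ipls(sim$dataset, k = 8, ncomp = 2, n_v = 5, N = 10, seed = 6,
                max_intervals = 1)
  r2 <- ipls(sim$dataset, k = 8, ncomp = 2, n_v = 5, N = 10, seed = 6)
  expect_equal(r1$selected_sequence, r2$best_interval)
  expect_identical(r1$final_mask, r2$final_mask)
})

test_that("micro-optimisation moves an interval edge toward a straddling peak", {
  # band only, no background: off-band wavelengths carry nothing but noise,
  # so the only improving direction is into the band
  sim <- generate_spectra(sim_config(
    wavenumber_start = 1000, wavenumber_end = 1199,
    analyte_peaks = data.frame(center = 1120, width = 10, height = 0.004),
    background_peaks = data.frame(center = numeric(0), width = numeric(0),
                                  height = numeric(0)),
    noise_sd = 2e-4, baseline_drift_amplitude = 0,
    concentration_grid = seq(0, 18, length.out = 30), seed = 7))
  ds <- sim$dataset
  i1120 <- which(ds$wavenumbers == 1120)
  # interval straddles only the left flank: optimisation should extend right
  iv <- c(i1120 - 30L, i1120 - 10L)
  out <- micro_optimize(ds, iv, ncomp = 2, n_v = 5, N = 10, seed = 8)
  expect_gt(out$end, iv[2])
  expect_lte(out$rmsecv, out$rmsecv_initial)

  # an interval already matching the informative region is a local optimum
  # for at least one step in each direction; re-optimising its own output
  # returns it unchanged
  again <- micro_optimize(ds, c(out$start, out$end), ncomp = 2, n_v = 5,
                          N = 10, seed = 8)
  expect_equal(c(again$start, again$end), c(out$start, out$end))

  # width-1 interval cannot truncate below one wavelength
  w1 <- micro_optimize(ds, c(5L, 5L), ncomp = 1, n_v = 5, N = 5, seed = 2)
  expect_gte(w1$end, w1$start)
})

test_that("MWPLS geometry and the SSR-vs-components criterion behave as designed", {
  sim <- interval_fixture(noise = 1e-3)
  ds <- sim$dataset
  rep_ <- mwpls(ds, window_length = 21, c_max = 4)
  p <- length(ds$wavenumbers)
  expect_length(rep_$centers, p - 21 + 1)
  expect_true(all(apply(rep_$ssr_curves, 1, function(r) all(diff(r) <= 1e-12))))
  expect_error(mwpls(ds, window_length = 20, c_max = 3), "odd")

  # windows on the analyte band absorb variance with few components
  on_band <- which(rep_$wavenumbers == 1090)
  expect_lt(rep_$ssr_curves[on_band, 2], 0.1 * rep_$ssr_curves[on_band, 1])
  expect_true(mwpls_regions(rep_, c_ref = 2, fraction = 0.5)[on_band])

  # windows over pure noise have little structure for components to absorb
  set.seed(55)
  ds0 <- spectra_dataset(1:80, matrix(rnorm(60 * 80), 60, 80),
                         seq(0, 18, length.out = 60))
  r0 <- mwpls(ds0, window_length = 21, c_max = 4)
  expect_true(all(r0$ssr_curves[, 4] > 0.5 * r0$ssr_curves[, 1]))
})
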