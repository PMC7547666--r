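# Synthetic Beer-Lambert spectra with a known informative-wavelength mask.

#' The 47-level lactate concentration grid
#'
#' Concentrations in mmol/L covering 0-18: steps of 0.25 from 0 to 5
#' (21 levels) and steps of 0.5 from 5.5 to 18 (26 levels). This is the
#' design grid used for in-vitro lactate calibration standards in buffer.
#'
#' @return Numeric vector of length 47.
#' @examples
#' length(lactate_grid())
#' @export
lactate_grid <- function() {
  c(seq(0, 5, by = 0.25), seq(5.5, 18, by = 0.5))
}

#' Simulation configuration for synthetic absorbance spectra
#'
#' Describes a mixture design in which each spectrum is a sum of
#' concentration-independent background bands (solvent/buffer), analyte
#' bands whose height is exactly proportional to concentration
#' (Beer-Lambert linearity), a smooth random per-sample baseline drift, and
#' iid Gaussian noise. All bands are Gaussian in shape.
#'
#' The defaults emulate a mid-infrared lactate-in-buffer design: axis
#' 850-4000 cm-1 at 1 cm-1 spacing (p = 3151), analyte bands in the
#' fingerprint region near 1090 and 1230 cm-1 plus a weak band near
#' 3505 cm-1, a dominant broad water background, and the 47-level
#' concentration grid of [lactate_grid()].
#'
#' @param wavenumber_start,wavenumber_end Axis limits in cm-1.
#' @param spacing Axis spacing in cm-1 (default 1).
#' @param analyte_peaks Data frame with columns `center`, `width`
#'   (Gaussian standard deviation, cm-1) and `height` (absorbance units per
#'   mmol/L).
#' @param background_peaks Data frame with columns `center`, `width`,
#'   `height` (absorbance units), concentration-independent.
#' @param background_amplitude_sd Relative standard deviation of the
#'   per-sample, per-band random variation in background band amplitude
#'   (default 0.02). This emulates the sample-to-sample variability of
#'   solvent bands (crystal contact, temperature) that makes uninformative
#'   spectral regions actively harmful to a calibration rather than merely
#'   redundant.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param baseline_drift_amplitude Scale of the smooth per-sample quadratic
#'   baseline drift.
#' @param concentration_grid Sample concentrations in mmol/L.
#' @param informative_halfwidth Multiplier `w`: wavelengths within
#'   `w * width` of an analyte band centre are marked informative in the
#'   ground-truth mask (default 2, covering ~95 percent of each band).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(wavenumber_start = 850,
                       wavenumber_end = 4000,
                       spacing = 1,
                       analyte_peaks = data.frame(
                         center = c(1090, 1230, 3505),
                         width = c(25, 18, 10),
                         height = c(0.004, 0.003, 0.0015)),
                       background_peaks = data.frame(
                         center = c(1640, 2120, 3350),
                         width = c(60, 100, 180),
                         height = c(0.45, 0.08, 1.0)),
                       background_amplitude_sd = 0.02,
                       noise_sd = 2e-4,
                       baseline_drift_amplitude = 5e-4,
                       concentration_grid = lactate_grid(),
                       informative_halfwidth = 2,
                       seed = 1) {
  if (spacing <= 0) stop("`spacing` must be positive", call. = FALSE)
  if (length(concentration_grid) < 2L)
    stop("`concentration_grid` needs at least 2 samples", call. = FALSE)
  if (any(concentration_grid < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  check_peaks <- function(pk, what) {
    if (nrow(pk) == 0L) return(invisible())
    stopifnot(all(c("center", "width", "height") %in% names(pk)))
    if (any(pk$width <= 0)) stop(what, " widths must be positive", call. = FALSE)
    if (any(pk$center < wavenumber_start | pk$center > wavenumber_end))
      stop(what, " centres must lie within the wavenumber range", call. = FALSE)
  }
  check_peaks(analyte_peaks, "analyte peak")
  check_peaks(background_peaks, "background peak")
  if (noise_sd < 0 || baseline_drift_amplitude < 0 ||
      background_amplitude_sd < 0)
    stop("noise, drift and background-variation amplitudes must be non-negative",
         call. = FALSE)
  structure(
    list(wavenumber_start = wavenumber_start, wavenumber_end = wavenumber_end,
         spacing = spacing, analyte_peaks = analyte_peaks,
         background_peaks = background_peaks,
         background_amplitude_sd = background_amplitude_sd,
         noise_sd = noise_sd,
         baseline_drift_amplitude = baseline_drift_amplitude,
         concentration_grid = as.numeric(concentration_grid),
         informative_halfwidth = informative_halfwidth, seed = seed),
    class = "sim_config")
}

gauss_profile_ <- function(wn, peaks) {
  out <- numeric(length(wn))
  for (i in seq_len(nrow(peaks)))
    out <- out + peaks$height[i] *
      exp(-0.5 * ((wn - peaks$center[i]) / peaks$width[i])^2)
  out
}

#' Generate synthetic spectra with ground truth
#'
#' Realises the design described by a [sim_config()]:
#' `A[i, k] = background(k) + conc[i] * analyte(k) + drift_i(k) + noise`,
#' so the analyte contribution is exactly linear in concentration before
#' noise. The drift is a per-sample random quadratic over the axis scaled by
#' `baseline_drift_amplitude`. Deterministic given `cfg$seed`.
#'
#' @param cfg A `sim_config`.
#' @return A list with `dataset` (a [spectra_dataset]) and `ground_truth`
#'   (list with logical `informative_mask` over wavelengths and the pure
#'   `analyte_profile` per unit concentration).
#' @export
generate_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  wn <- seq(cfg$wavenumber_start, cfg$wavenumber_end, by = cfg$spacing)
  p <- length(wn)
  conc <- cfg$concentration_grid
  n <- length(conc)
  bg <- gauss_profile_(wn, cfg$background_peaks)
  an <- gauss_profile_(wn, cfg$analyte_peaks)
  A <- with_seed(cfg$seed, {
    A <- matrix(rep(bg, each = n), n, p) + outer(conc, an)
    if (cfg$background_amplitude_sd > 0 && nrow(cfg$background_peaks) > 0) {
      for (b in seq_len(nrow(cfg$background_peaks))) {
        band <- gauss_profile_(wn, cfg$background_peaks[b, , drop = FALSE])
        A <- A + stats::rnorm(n, sd = cfg$background_amplitude_sd) %o% band
      }
    }
    if (cfg$baseline_drift_amplitude > 0) {
      t <- seq(-1, 1, length.out = p)
      coefs <- matrix(stats::runif(3 * n, -1, 1), n, 3)
      A <- A + cfg$baseline_drift_amplitude *
        (coefs[, 1] + coefs[, 2] %o% t + coefs[, 3] %o% t^2)
    }
    if (cfg$noise_sd > 0)
      A <- A + matrix(stats::rnorm(n * p, sd = cfg$noise_sd), n, p)
    A
  })
  mask <- logical(p)
  for (i in seq_len(nrow(cfg$analyte_peaks)))
    mask <- mask | (abs(wn - cfg$analyte_peaks$center[i]) <=
                      cfg$informative_halfwidth * cfg$analyte_peaks$width[i])
  list(dataset = spectra_dataset(wn, A, conc),
       ground_truth = list(informative_mask = mask, analyte_profile = an))
}

#' Subtract a reference spectrum
#'
#' Subtracts the spectrum of one sample (typically the zero-concentration
#' blank) from every spectrum, highlighting the analyte contribution that is
#' otherwise buried under the dominant solvent background.
#'
#' @param ds A [spectra_dataset].
#' @param reference_index Row index of the reference sample.
#' @return A new `spectra_dataset`; the reference row becomes all zero.
#' @export
baseline_subtract <- function(ds, reference_index) {
  stopifnot(inherits(ds, "spectra_dataset"))
  reference_index <- assert_count(reference_index, "reference_index")
  if (reference_index > nrow(ds$absorbance))
    stop("`reference_index` out of range", call. = FALSE)
  ref <- ds$absorbance[reference_index, ]
  spectra_dataset(ds$wavenumbers,
                  sweep(ds$absorbance, 2L, ref, "-"),
                  ds$concentration, ds$sample_ids)
}
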