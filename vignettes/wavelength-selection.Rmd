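---
title: "Wavelength selection for PLS calibration of absorbance spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength selection for PLS calibration of absorbance spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavesel)
```

## The problem

Quantitative vibrational spectroscopy maps an absorbance spectrum — here a
vector of a few thousand wavenumbers (cm⁻¹) — to the concentration of one
analyte (mmol/L). Sample preparation limits the number of spectra to tens,
so the data are severely "small *n*, large *p*". Partial least squares (PLS)
handles the collinearity, but including uninformative wavelengths still
degrades both accuracy and interpretability, and a sensor built on a handful
of wavelengths is far cheaper than one that needs the whole band. `wavesel`
implements a family of wavelength-selection strategies around a common PLS
core, along with the cross-validation scaffolding needed to compare them
fairly, and a synthetic spectra generator with a known ground truth for
benchmarking.

The motivating design is an in-vitro lactate calibration: 47 buffer
solutions spanning 0–18 mmol/L (0.25 mmol/L steps up to 5, 0.5 above;
`lactate_grid()`), measured by ATR-FTIR at 1 cm⁻¹ intervals. No public
dataset of this kind is available, so the package ships a generator that
emulates the design rather than a copy of any measured data.

## The PLS core

`fit_pls()` is a single-response NIPALS implementation with deflation of the
X block. The bilinear model is

$$X = T P^{\top} + E, \qquad y = T q + f,$$

and the fitted model collapses to one regression vector $B$ so that
$\hat y = (X - \bar x) B + \bar y$. Mean-centring is always applied;
unit-variance scaling (`scale = TRUE`) is used only where a method requires
comparable coefficient magnitudes (the β and EUV selectors). The NIPALS
inner loop uses a convergence tolerance of 1e-12 and at most 500 iterations;
with a single response it converges in one pass, and the loop exists for
structural fidelity. If the response residual carries no covariance with
the X block (for example a constant response), component extraction stops
early and the model degrades to the mean model rather than failing —
important inside search loops that must never throw.

The number of latent variables is chosen from a PRESS curve
(`press_curve()`): predicted residual error summed over Monte Carlo
block-stratified splits, shared across component counts so the curve is
internally comparable. Reading "the plateau" off a plot is subjective, so
`select_components_elbow()` makes it a rule: the smallest count whose
relative improvement to the next count falls below `rel_tol` (default 0.02).
The default is deliberately conservative; per-dataset latent-variable counts
are better chosen by inspecting the curve.

## Validation machinery

All resampling uses the block-stratified split of `block_stratified_split()`:
samples are sorted by concentration, cut into `n_v` contiguous blocks whose
sizes differ by at most one (larger blocks first; ties in concentration
break by original index), and one sample is drawn per block. This guarantees
every validation set spans the concentration range, which matters when a
random 5-of-47 draw could easily land in a narrow range. Monte Carlo
cross-validation (`mccv()`) repeats such splits `N` times, refits the model
(including re-centring) on each calibration subset, and pools

$$\mathrm{RMSECV}_{MC} = \sqrt{\tfrac{1}{N n_v} \sum_{i=1}^{N}
  \sum_{j=1}^{n_v} (y_{ij} - \hat y_{ij})^2}.$$

Test-set quality is reported as RMSEP and the percent coefficient of
determination, both computed on a representative held-out test set drawn
with the same block mechanics (`representative_test_split()`), so eight test
samples of 47 still cover the range.

## The selectors

**β (coefficient magnitude).** Wavelengths are scored by the absolute
regression coefficient of a PLS fit on standardized spectra. The selection
threshold is expressed as a score quantile (default 0.8, keeping the top
20%), because an absolute coefficient threshold does not transfer across
datasets. With `N > 1` the score is averaged over Monte Carlo refits, which
stabilises it; `N = 1` is the plain single-fit method.

**EUV (elimination of uninformative variables).** The spectra are augmented
with random columns, the reliability $c_i = \bar b_i / \sigma(b_i)$ of every
coefficient is computed under resampling (leave-one-out by default), and
only real wavelengths whose $|c_i|$ exceed the worst artificial column
survive. Because the cutoff is the maximum over the artificial columns, an
artificial column can never be selected — the method's defining guarantee.
One numerical choice matters here: the amplitude of the artificial columns.
The reliability ratio is scale-free in exact arithmetic, but we found that
artificial columns orders of magnitude weaker than the real ones stop
behaving as an exchangeable null under finite resampling, and the cutoff
becomes too permissive (no-signal false-positive rates well above 10%). The
default therefore matches the artificial columns' standard deviation to the
median real column standard deviation (`noise_amplitude = sqrt(12) ×`
median column sd, since the noise is uniform), which restores the rank-based
behaviour of the cutoff.

**iPLS and FS-iPLS.** The axis is cut into `k` equidistant intervals
(sizes differing by at most one, larger first) and each interval is scored
by MCCV RMSECV on one shared set of splits; ties break to the lower index.
Forward-selection iPLS greedily accumulates intervals while the combined
RMSECV improves by at least 0.5% relative (the stop rule has to be explicit
somewhere; 0.5% stops noise-driven growth). `micro_optimize()` then refines
interval edges by hill climbing — expand-left, expand-right, truncate-left,
truncate-right, first improving move accepted, all evaluated on the same
fixed splits so the refined interval is never worse than its input.

**MWPLS.** A window of fixed odd length (default 31 wavelengths) slides one
wavelength at a time; for every position local models with 1..`c_max`
components record the training SSR. The criterion is qualitative — good
windows reach low SSR with few components — so the report stores the full
SSR curves and `mwpls_regions()` offers one deterministic reading
(SSR at `c_ref` below a fraction of the across-window median).

## The GA selector

The genetic algorithm treats wavelength selection as minimisation of a
resampled calibration error over bit strings (1 = wavelength selected).
Three devices guard against overfitting in the small-*n*, large-*p* regime:

1. **Per-run holdout acceptance.** Each run first sets aside its own
   block-stratified holdout (default 5 samples). The final best chromosome
   is evaluated on that holdout exactly once, and the run is discarded
   unless its RMSEV is at most 1.5× the holdout RMSEV of the full-spectrum
   model with the same component count. (The holdout RMSEV of the running
   best is also recorded per generation for diagnostics, but never feeds
   back into the search.)
2. **Resampled fitness.** A chromosome's unfitness is the mean calibration
   MSE over `fitness_mccv_iters` (default 100) random block-stratified
   splits of the non-holdout data; the matching validation statistics are
   retained as diagnostics. A chromosome must select at least
   `n_components + 1` wavelengths; smaller ones receive a worst-possible
   sentinel rather than raising.
3. **Multi-run ensembling.** The algorithm is repeated `n_runs` (default
   100) times with child seeds `seed + 1..n_runs`. Accepted best
   chromosomes are stacked into `G`; `H = G^\top G` counts co-selections of
   wavelength pairs, and `p_ga = diag(H) /` (number of accepted runs) is
   each wavelength's selection probability. `select_by_probability()`
   thresholds `p_ga` (default 0.6).

Evolution itself is a plain generational GA: tournament selection (size 2,
configurable), uniform crossover (rate 0.9; a two-point variant that
preserves the positional linkage of neighbouring wavelengths is available
via `crossover_type`), per-bit mutation (rate 1/p), one elite exempt from
mutation that carries its stored fitness (making the per-generation best
non-increasing by construction). Component count inside the GA is
fixed before evolution (PRESS elbow of the full model) — re-selecting per
chromosome would be a different method. Child-run seeds are derived by a
counter so results do not depend on execution order.

Whether `p_ga` should divide by all runs launched or only the accepted ones
is ambiguous when runs can be discarded; the package defaults to accepted
runs and records both counts (`p_ga_denominator = "total"` switches).

Two numerical notes. First, the fit-and-predict step inside the resampled
fitness is the package's only hot loop (hundreds of thousands of small PLS
fits per ensemble), so it is implemented once in compiled code
(RcppArmadillo) and cross-checked against the R NIPALS path in the test
suite; everything user-facing goes through the R implementation. Second,
each chromosome is evaluated on its own independent random splits. We
experimented with sharing one set of splits per generation (common random
numbers) to sharpen fitness comparisons, and found it counterproductive:
because a mean-calibration-error objective always improves slightly when
more columns are added, low-noise comparisons accelerate chromosome growth
into uninformative regions, while independent-split noise masks those tiny
spurious gains and leaves band content as the dominant selection signal.
The independent-split design is also the straightforward reading of the
method.

## The synthetic generator

`generate_spectra()` builds `absorbance = background + concentration ×
analyte + drift + interference + noise`:

* Gaussian line shapes for all bands — adequate for testing purposes; no
  claim about true band shapes is intended.
* concentration-proportional analyte bands (Beer–Lambert linearity is exact
  before noise);
* fixed background bands plus, by default, a per-sample random variation of
  each background band's amplitude (`background_amplitude_sd`, default 2%).
  This interference term deserves explanation: with a strictly
  sample-invariant background, uninformative wavelengths are merely
  redundant, the full-spectrum model is near-optimal, and no selection
  method can beat it — contrary to what motivates wavelength selection in
  practice. Sample-to-sample variability of solvent bands (crystal contact,
  temperature) is the physical reason uninformative regions actively hurt,
  so the generator includes it. Set it to zero to probe exact linearity.
* a smooth random per-sample quadratic baseline drift and iid Gaussian
  noise.

The ground truth marks wavelengths within twice the Gaussian width of any
analyte band centre (~95% of the band) as informative. The default
full-scale configuration uses an 850–4000 cm⁻¹ axis at 1 cm⁻¹ (p = 3151),
analyte bands at 1090 and 1230 cm⁻¹ (fingerprint region) and a weak band at
3505 cm⁻¹, and the 47-level concentration grid. The informative fraction is
about 7%. The true band positions and intensities of lactate in buffer are
not modelled — the defaults are a test scaffold with the right statistical
shape (dominant solvent background, weak analyte signal, realistic axis),
not a spectroscopic claim, which is also why passing recovery tests here
says nothing about any particular real dataset beyond "the methods find
what the generator hides".

### Reduced-scale benchmark

Exhaustive benchmarking at p = 3151 with 100 GA runs is a cluster-scale
computation. The package's tests and the acceptance script instead use a
committed reduced-scale fixture: 1000–1299 cm⁻¹ (p = 300), two analyte
bands (1090 and 1230 cm⁻¹, widths 12 and 9 cm⁻¹), one broad background
band with 2% amplitude interference, noise such that the stronger band's
full-range signal is about 12× the noise floor, and the 47-sample grid. The
GA benchmark runs 10 runs × 30 generations × 20 fitness-resampling
iterations with population 32 and initial density 0.1. The sparse
initial density is a deliberate choice for this benchmark: a
mean-calibration-error objective carries no parsimony pressure, so dense
random starts drift, while sparse starts let selection build chromosomes up
from the strongly informative bits. At full scale with 100 runs and 100
generations the default 0.5 is appropriate.

This budget is honest about what it can and cannot show. The band-versus-
background contrast in `p_ga` is robust: wavelengths inside the true bands
are selected clearly more often than background ones at every configuration
we examined. The *thresholded mask*, however, is another matter. The mean-
MSEC objective measurably rewards adding uninformative columns (on this
fixture, appending 100 noise columns to the true-band chromosome lowers the
resampled mean MSEC by a factor of about two), so evolved solutions retain
an appreciable background density; 30 generations cannot fixate ~86 largely
interchangeable in-band bits; and with only the handful of runs that survive
the 1.5× holdout rule, `p_ga` takes coarse values and binomial spread pushes
background wavelengths over the 0.6 threshold. The precision of
`select_by_probability(0.6)` against ground truth therefore hovers around
0.3–0.6 at this scale and is seed-sensitive. Sharpening it would take the
full-scale default budget (100 runs × 100 generations) or a parsimony-aware
objective, which is deliberately out of scope.

## Comparison harness

`run_comparison()` reproduces the standard benchmarking workflow: hold out
a representative test set (default 8 samples) before anything else; let
each method select wavelengths on the training remainder; Monte Carlo
cross-validate the reduced model (default 10,000 iterations, 5 held out per
iteration); report RMSEP and %R² on the untouched test set. By default the
reported RMSECV resamples all samples (so the per-iteration calibration
size on a 47-sample design is 42); `mccv_on_all = FALSE` restricts the MCCV
to the 39 training samples instead — both conventions appear in practice
and the choice is recorded in the report parameters.

## Known limitations

* Single-response PLS only; multi-analyte calibration is out of scope.
* The generator does not model ATR penetration depth, water-vapour
  artefacts, band shifts, or pH effects; interference enters only through
  band-amplitude variation.
* The GA's objective is the plain resampled mean calibration MSE; a
  parsimony-augmented objective would remove the growth pressure discussed
  above but is deliberately not implemented.
* EUV reliabilities are reported, not tested: no multiple-testing control
  is applied, and type I errors are expected by design.
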