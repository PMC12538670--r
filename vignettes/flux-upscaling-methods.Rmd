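---
title: "Methods: GP regression upscaling of terrestrial carbon fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GP regression upscaling of terrestrial carbon fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Eddy-covariance (EC) towers measure terrestrial carbon fluxes — gross
primary productivity (GPP), ecosystem respiration (RECO) and net ecosystem
exchange (NEE), all in µmol CO₂ m⁻² s⁻¹ — at a few hundred points on
Earth. Gridded predictors (satellite leaf area index and reanalysis
climate) are available everywhere. `fluxgpr` learns the mapping from
daily-mean predictors to daily fluxes at the towers and applies it
per pixel to gridded predictor stacks, producing flux maps together with a
per-pixel *epistemic* uncertainty that grows wherever the gridded inputs
leave the conditions the towers sampled.

NEE is stored throughout in the uptake-positive convention (positive =
flux from atmosphere to biosphere). Micrometeorological files use the
opposite sign; `read_tower_table(nee_sign = "release_positive")` negates
on read, and the intercomparison functions refuse to mix sign tags.

## The regression model

Each flux gets its own zero-mean Gaussian process on standardized inputs
and target, with the anisotropic (ARD) squared-exponential kernel

$$k(x_i, x_j) = \sigma_s^2 \exp\!\left(-\tfrac12 \sum_{b=1}^{D}
  \left[\frac{x_i(b) - x_j(b)}{\sigma_b}\right]^2\right),$$

one lengthscale $\sigma_b$ per predictor. Hyperparameters
$\theta = \{\sigma_s^2, \sigma_1, \dots, \sigma_D, \sigma_n^2\}$ are
chosen by maximizing the log marginal likelihood

$$\log p(y \mid X, \theta) = -\tfrac12 y^\top (K + \sigma_n^2 I)^{-1} y
  - \tfrac12 \log\det(K + \sigma_n^2 I) - \tfrac{n}{2}\log 2\pi,$$

evaluated through a Cholesky factorization $LL^\top = K + \sigma_n^2 I$
(never an explicit inverse or determinant), with the analytic gradient in
log-hyperparameter space. Predictions at $x_*$ are the posterior mean
$k_*^\top \alpha$ with $\alpha = (K + \sigma_n^2 I)^{-1} y$ and the
latent-function standard deviation

$$\sigma_f(x_*) = \sqrt{\max\!\big(0,\; k(x_*, x_*) - v^\top v\big)},
  \qquad v = L \backslash k_*.$$

The reported sigma is deliberately the *epistemic* (model) uncertainty:
it excludes observation noise, vanishes at noise-free training points and
reverts to the prior $\sigma_s$ far from all training data. For
predictive-observation intervals, `predict(..., include_noise = TRUE)`
adds $\sigma_n^2$. The quantity $k_{**} - v^\top v$ is a variance, so the
square root is taken before de-standardization.

The relevance interpretation drives the `ard_relevance()` ranking: the
larger a fitted lengthscale (on standardized inputs, so units cancel),
the less that predictor informs the fit. Scores are $1/\sigma_b$
normalized to a maximum of 1; ties share a score, and an alternative
`log_inverse` scaling compresses the dynamic range for plotting.

### Optimizer and numerics

* **Parameterization / bounds.** Optimization runs on
  $\log \theta$ with L-BFGS-B. Lengthscales and signal variance are
  boxed to $[10^{-2}, 10^{2}]$ in standardized units — wide enough to
  declare a predictor irrelevant (a lengthscale of 100 on unit-variance
  inputs is flat) without letting the kernel degenerate. The noise
  variance may fall to $10^{-6}$ so noise-free simulations interpolate.
* **Restarts.** The first start is a fixed heuristic (unit lengthscales
  and signal variance, noise variance 0.1); further restarts draw
  log-uniform within the bounds. The restart with the highest marginal
  likelihood wins; exact ties go to the lowest restart index. Because
  L-BFGS-B requests the objective and gradient separately at the same
  point, the pair is computed once and memoized.
* **Jitter.** If the Cholesky fails, a diagonal jitter of
  $10^{-10}\,\mathrm{tr}(K)/n$ is added and escalated tenfold up to
  $10^{-4}\,\mathrm{tr}(K)/n$ before erroring — this is what lets
  duplicated training rows or constant targets fit.
* **Degenerate inputs.** A constant target standardizes to zeros (scale
  forced to 1) and predicts the constant; constant predictor columns are
  centred but not scaled.
* **Chunk determinism.** Map prediction evaluates pixels in chunks.
  Cross-kernels are computed dimension-wise rather than through the
  Gram-matrix identity, and the posterior mean through column-wise sums,
  so the resulting rasters are bit-identical for any chunk size. Training
  self-kernels, which never split, use the faster Gram identity.
* **Exact GP.** At the tower-data scale this package targets
  (n ≈ 1000–1400) exact inference is the right tool; no sparse or
  inducing-point approximation is provided.

### Portable model export

`export_model()` writes JSON containing the schema, $\theta$, the
standardization constants, the standardized training inputs and the
precomputed weight vector $\alpha$, at full double precision.
`standalone_predict()` reproduces predictions from that record using only
kernel arithmetic, dot products and a triangular solve — the contract
that makes a fitted model portable to any runtime that can do arithmetic,
with round-trip agreement at the 10⁻¹⁰ level verified in the tests.

## Predictor schema

`predictor_schema()` fixes D = 13 predictors: LAI plus the 12 climate
bands available in a gridded reanalysis stack (shortwave radiation; soil
temperature and soil water content at three depths; sensible and latent
heat; precipitation; air temperature; wind speed). Vapour pressure
deficit is observed at towers but has no band in that stack, so it is not
part of the model schema; every module reads the dimension from the
schema, never from a literal. Towers that measure fewer than three soil
depths have the deeper columns filled by copying the deepest available
measurement (with a flag) — copying preserves monotone depth profiles
better than imputing zeros.

## The synthetic data generator

All analyses run on synthetic data, so the generator defines the study
conditions:

* **Marginals.** Each predictor follows its documented distribution
  family (exponential, uniform, chi-square with 5 df, or gamma with shape
  2), scaled so that ~99.5% of the mass lies inside the valid range, and
  truncated to the range. Truncation is implemented by inverse-CDF
  sampling of the truncated distribution rather than rejection: it is
  exactly equivalent in distribution, has no acceptance-rate failure
  mode, and composes naturally with the Gaussian copula that supplies
  mild cross-predictor rank correlation (radiation–temperature coupling,
  coherent soil profiles). Fully independent predictors would make ARD
  ranking trivially easy.
* **Flux function.** Noise-free fluxes follow a light-use-efficiency
  form: GPP = $g_{max}(1 - e^{-k_L \mathrm{LAI}})\cdot
  \mathrm{SW}/(\mathrm{SW}+S_{1/2})\cdot
  \mathrm{SWC_1}/(\mathrm{SWC_1}+W_{1/2})\cdot
  e^{-((\mathrm{TA}-T_{opt})/T_{width})^2}$; RECO =
  $r_b Q_{10}^{(\mathrm{TS_1}-T_{ref})/10} + f_g\,\mathrm{GPP}$;
  NEE = GPP − RECO. Defaults ($g_{max}=25$ µmol m⁻² s⁻¹, $k_L=0.5$,
  $S_{1/2}=100$ W m⁻², $W_{1/2}=15$%, $T_{opt}=20$ °C, $T_{width}=15$ °C,
  $r_b=2$ µmol m⁻² s⁻¹, $Q_{10}=2$, $T_{ref}=10$ °C, $f_g=0.3$) give
  daily flux magnitudes typical of mid-latitude towers. Noise defaults to
  10% of each flux's noise-free standard deviation. The noise-free values
  and parameters travel with every table as ground truth, so recovery is
  testable exactly.
* **Tower series.** Daily series follow class-specific sinusoidal
  seasonal cycles plus AR(1) noise on the copula scale (so values stay in
  range and in family); soil moisture, precipitation and wind peak
  off-season.
* **Scenes.** Spatial fields are smoothed random fields (bilinearly
  enlarged coarse noise, correlation length ~10 pixels) with additive
  offsets from a categorical vegetation mosaic, mapped linearly onto each
  band's range. The top 1% tail of each band is stretched beyond the
  upper range limit by up to 10% of the range width, so a small fraction
  of pixels (~10% union across bands) is genuinely outside the tower
  training ranges — the extrapolation regime whose inflated uncertainty
  the sigma maps are meant to expose. Climate bands are block-averaged to
  a 3×-coarser grid; ground-truth fluxes are computed on the
  co-registered fine grid before coarsening.

What the generator does *not* emulate: real site geography, actual
satellite/reanalysis error structure, snow contamination of LAI
retrievals, measurement-footprint variability, or the mixing of LAI/PAI/
GAI measurement types. Passing closed-loop tests therefore demonstrates
that the machinery recovers a known data-generating process under
realistic ranges and noise — not that real-archive skill metrics would
reach the same values.

## Assembly, cross-validation, metrics

`assemble_training_table()` averages sub-daily rows to daily means, then
keeps only site-days with all D predictors and the target present, finite
and inside the schema ranges, emitting a per-rule drop audit.
`make_folds()` builds balanced partitions (sizes differing by at most
one), stratified by vegetation class by default — for 1369 samples and
k = 10 this yields nine folds of 137 and one of 136, i.e. train sizes of
1232 or 1233; a "1232 train / 136 held out" split of 1369 is not an exact
partition, and the audit notes this rather than reproducing it.

Metrics: R² is the coefficient of determination $1 - SS_{res}/SS_{tot}$
(scatterplot-validation convention — it can be negative; the squared
Pearson correlation is reported alongside in the audit field); rmse in
flux units; nrmse = 100·rmse/range(obs), normalized by the observed range
(consistent with reporting alongside the predictor range table) and
undefined for constant observations, returned as missing with a reason.

## Upscaling conventions

* **Grids.** Pixel-centre registration on row-major, north-up grids; the
  geotransform stores the centre of the top-left pixel and positive pixel
  sizes. One CRS tag per scene; no reprojection.
* **Compositing.** Daily stacks aggregate to the 46-window 8-day
  calendar; the final window covers 5 days (6 in leap years). Windows
  with fewer than 4 valid days (capped at the window length) are masked.
* **Resampling.** Bilinear for continuous fields with mask-aware weights
  (invalid neighbours are excluded and weights renormalized, so nodata
  never bleeds), nearest-neighbour for categorical maps, block mean for
  fine-to-coarse aggregation.
* **Out-of-range pixels.** Clamped to the schema range with a per-pixel
  flag count (the default), because masking would hide exactly the
  extrapolation behaviour the sigma layer is meant to reveal; `mask` and
  `none` modes are available.
* **Annual totals.** Day-weighted mean flux converted with the molar mass
  of carbon (12.011 g mol⁻¹): 1 µmol m⁻² s⁻¹ sustained over 365 days is
  12.011·10⁻⁶ g/µmol × 86400 s/day × 365 days ≈ 378.8 gC m⁻² y⁻¹. Sigma
  aggregates as the day-weighted root mean square of composite sigmas,
  converted identically — a stated upper-bound convention, not a
  calibrated interval (composite-to-composite error correlation is
  unknown). Pixels covering less than 80% of the year's days are masked.

## Validation and intercomparison

Tower validation extracts the single pixel containing each tower (no
footprint model; a 3×3-mean option exists but is unclaimed) and
summarises R²/rmse per vegetation class by median and quartiles. Gridded
intercomparison always regrids fine→coarse by area-weighted block mean,
then computes per-pixel temporal Pearson R and rmse over the common
periods (pixels with fewer than 3 common composites are masked) and
global medians. The NEE consistency check compares (GPP − RECO) from the
two partitioned-flux models against the directly modelled NEE and
refuses mismatched sign tags.

## File formats

Tower tables are CSV with ISO-8601 dates and schema column names
(FLUXNET-style aliases via a user-supplied map). Models are JSON. Scenes
and flux maps are written either as native `.rds` (lossless float64) or
as a directory of ESRI ASCII Grid files — a standard plain-text raster
format — plus a JSON manifest for band names, time index, CRS and
geotransform; values print with 17 significant digits, so doubles survive
the text round-trip exactly. ASCII Grid assumes square pixels; the `.rds`
path has no such restriction.

## Problem sizes

The test suite and the acceptance script exercise the pipeline at the
sizes the analyses use: oracle and gradient checks on hundreds of random
instances with n ≤ 20; lengthscale-recovery simulations at n = 300 and
D = 3 over 20 seeds; and a closed loop that trains on 1,000 tower samples
(D = 13, 10% noise), cross-validates with 10 stratified folds, and
upscales onto a 60×60×46 scene with stored ground truth. Fits at these
sizes use 1–2 optimizer starts; the marginal-likelihood surface for this
smooth generative process has shown no sensitivity to additional
restarts.

## Known limitations

* Epistemic sigma is conditional on the fitted hyperparameters;
  hyperparameter uncertainty is not propagated.
* Annual sigma aggregation ignores temporal error correlation (stated
  upper-bound convention).
* Whether to average LAI before prediction or predict before averaging
  when changing resolution is left to the caller — prediction happens on
  whatever grid is supplied, and the flux function's nonlinearity makes
  the two inequivalent.
* Correlation analyses run on raw 8-day series; a deseasonalized-anomaly
  mode can be built from `regional_series()` output but no claims are
  made for it.
* No significance testing on the correlation tables: coefficients are
  descriptive.
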