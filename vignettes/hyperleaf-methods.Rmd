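---
title: "Estimating leaf water content from NIR hyperspectral reflectance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf water content from NIR hyperspectral reflectance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperleaf)
```

## The problem

Gravimetric leaf water content (LWC) — the water fraction of fresh mass,
$M = (G - G_0)/G$ with fresh mass $G$ and oven-dry mass $G_0$ — is a core
physiological indicator for irrigation scheduling and stress monitoring.
Destructive oven drying is slow; near-infrared (NIR) reflectance offers a
fast proxy because O–H overtone vibrations absorb strongly in the
900–1700 nm window, with a particularly strong absorption feature near
1440 nm. As a leaf dries, reflectance rises across the window and the
1440 nm trough becomes shallower, so both band reflectance and local
spectral slope carry water information.

`hyperleaf` implements the full estimation chain on hyperspectral leaf
images: ENVI cube I/O with black/white calibration
$R = (I - B)/(W - B)$, leaf/background segmentation, per-sample mean
spectra, spectral preprocessing, water-sensitive index construction,
characteristic-wavelength selection, four regression back-ends, per-pixel
water maps, and a cross-species evaluation harness. Because raw orchard
data of this kind are rarely deposited, the package ships a synthetic-data
generator that reproduces the statistical structure the analysis relies
on; every stage is exercised end to end against it.

## The NISDI index

The package's central index is the Near-Infrared Slope Difference Index,

$$\mathrm{NISDI} = 1.3\times10^{3}\, D_{1559} - 1.9\, R_{1439},$$

where $R_{1439}$ is reflectance at the band nearest 1439 nm (inside the
water absorption trough) and $D_{1559}$ is the spectral slope (nm$^{-1}$)
at the band nearest 1559 nm, on the recovery shoulder of the same trough.
Both terms become more negative as water content rises, and their weighted
difference is close to linear in LWC, so a univariate ordinary
least-squares model (intercept included) maps NISDI to water content.

Two conventions deserve note, since the slope definition admits
variants:

* **Slope stencil.** $D$ is computed as a central difference per nm,
  $(R_{k+1} - R_{k-1})/(\lambda_{k+1} - \lambda_{k-1})$, one-sided at the
  grid ends. The $1.3\times10^3$ coefficient is only dimensionally
  sensible for per-nm slopes, which motivates this choice.
* **Anchor snapping.** 1439 and 1559 nm are mapped to the nearest grid
  band (instrument grids rarely contain the exact integers); the snapped
  wavelengths are attached to every NISDI result.

The index uses three distinct wavelengths in total (the slope stencil's
two neighbours plus the trough band), which is how the package counts its
wavelengths in model ranking.

Alongside NISDI, `search_pairs()` scans all ordered band pairs of the
empirical families DVI $=R_i - R_j$, RVI $=R_i/R_j$ and NDVI
$=(R_i-R_j)/(R_i+R_j)$ for the pair maximizing $|r|$ against LWC, with a
two-tailed $t$ test on $r$. The full $|r|$ heatmap is returned; ties
break deterministically toward the lowest band indices. Pairs with
undefined values (zero RVI/NDVI denominators) are dropped pairwise and
counted.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the
conditions under which the package's properties are verified.

A noiseless spectrum at water content $w$ is a quadratic continuum minus
Gaussian absorption troughs whose depth is proportional to $w$:

$$R(\lambda; w) = C(\lambda) - w\sum_k d_k
  \exp\!\left(-\tfrac{(\lambda-\mu_k)^2}{2\sigma_k^2}\right),$$

with troughs at 1440 nm ($\sigma = 65$ nm, $d = 0.55$) and 1190 nm
($\sigma = 40$ nm, $d = 0.15$). A drawn spectrum is then
$(1+\varepsilon_m) R + \varepsilon_a$ plus i.i.d. band noise, clipped at
zero: multiplicative scatter ($\sigma_m = 0.08$), additive scatter
($\sigma_a = 0.02$) and band noise ($\sigma = 5\times10^{-4}$).

Choices and what they emulate:

* **Grid.** 224 bands uniformly spanning 900–1700 nm
  ($\Delta\lambda \approx 3.59$ nm), the nominal specification of
  line-scan NIR imagers in this class. Real instrument grids are slightly
  non-uniform; all downstream code treats the grid as data and never
  assumes uniform spacing.
* **Water-content range.** Uniform on $[0.14, 0.77]$, a typical
  fresh-to-oven-dry range for broadleaf drying series.
* **1440 nm trough width (65 nm).** Wide enough that the 1559 nm shoulder
  slope is water-dependent, as in real leaf spectra where the absorption
  feature is broad; with a narrow trough the slope anchor would sit
  outside the feature and NISDI would lose its slope term.
* **Band noise ($5\times10^{-4}$).** Sample tables emulate mean spectra
  over all leaf pixels of an image (thousands of pixels), so random noise
  is far smaller than single-pixel noise; between-sample scatter, which
  averaging does not remove, is kept as the dominant nuisance. Under
  these defaults the NISDI–LWC correlation sits near $0.98$, the regime
  reported for field data of this kind.
* **Drying series.** Water mass decays geometrically toward dry mass
  across four weighings; masses and water contents follow the gravimetric
  relation exactly. The thermal drying protocol itself is not modeled.
* **Image cubes.** An elliptical leaf on a dark flat background, a
  smooth lamina water field, and a procedural vein skeleton offset wetter
  by a configurable amount (default $+0.10$), mirroring the observation
  that veins stay wetter than lamina during drying.

Planted-signal modes support oracle tests: `planted_pair()` recomputes
the recorded water content as an exact affine function of a chosen band
difference of the *realized* spectra (so the planted pair is the unique
exact pair, and per-band noise decorrelates all others);
`planted_nisdi()` keeps spectra noiseless — making NISDI exactly affine
in the latent water content — and perturbs the recorded water content so
a chosen fraction (default 0.96) of its variance is carried by the
spectral signal, giving a known target for prediction $R^2$.

What the generator does **not** emulate: wavelength-dependent scatter
(path-length effects vary spectrally in real tissue), instrument
striping and bad pixels, specular glint, vein anatomy beyond a skeleton,
and between-species differences in continuum shape other than the
parameter shifts used by the cross-species harness. Passing tests
therefore demonstrate correctness of the algorithms and recovery of
planted structure, not field-level accuracy claims.

## Preprocessing

`snv()` (per-spectrum standardization, $n-1$ denominator), `msc()`
(per-spectrum affine regression on a reference spectrum, then inversion),
`savitzky_golay()` (local polynomial filtering in wavelength units, so
derivatives are per nm on any grid; edges are refit on truncated windows
rather than padded, keeping every band defined for index extraction),
`normalize_minmax()` and `first_derivative()` (central differences,
one-sided ends). SG defaults are window 11, polyorder 2 — standard
chemometric smoothing values. "Nor" is interpreted as per-spectrum
min–max scaling to $[0,1]$.

The MSC reference is the calibration-set mean spectrum, frozen and
reused for validation/prediction/external sets to avoid leakage; the
`apply_prep()` state object carries it.

`compare_preprocessing()` ranks the nine standard methods plus "none" by
fitting PLS1 per method with the component count (up to 10) chosen at
the minimum 10-fold RMSECV. Fold assignment depends only on
$(n, k, \mathrm{seed})$. Two regimes are worth understanding, and the
tests pin both:

* Methods that act *linearly* on spectra (SG, FD) preserve a linear
  LWC–spectrum relation exactly; on noiseless tables they reach
  $R^2_{cv} \approx 1$.
* Amplitude-normalizing methods (SNV, min–max, MSC) deliberately discard
  per-spectrum scale. When the signal is partly amplitude-coded they
  trade some of it away, and they pay off precisely when per-spectrum
  scatter would otherwise consume model capacity — the comparison
  harness shows them winning when the component budget is tight and
  scatter is strong, and roughly tying otherwise, consistent with the
  near-ties reported in field studies.

## Wavelength selection

All three selectors return sorted unique band subsets, are pure
functions of `(X, y, seed)`, and carry diagnostic traces.

**CARS.** `n_mc = 50` Monte-Carlo iterations; each fits PLS on a random
80% sample subset and weights retained variables by $|b|$ (PLS
regression coefficients). The retained count follows the standard
exponentially decreasing schedule fitted through "all $p$ at iteration
1" and "2 at iteration `n_mc`". The competitive reweighting draws
exactly the scheduled number of variables *without* replacement with
probability $\propto |b|$ — chosen over the
sample-with-replacement-then-deduplicate variant so the retained-count
curve follows the schedule exactly, which also makes the trace easier to
reason about. Each iteration's subset is scored by 10-fold RMSECV under
a fold assignment fixed once per call: using common folds across
iterations means the trace compares subsets rather than fold luck, which
measurably sharpens the minimum toward parsimonious subsets. The subset
at the global trace minimum is returned. PLS component counts inside
selectors are chosen once by inner 10-fold CV, capped at 10.

**SPA.** For every start band, a projection chain: each next variable
maximizes the norm of its projection onto the orthogonal complement of
those already chosen, directly minimizing collinearity. Candidate sets
(start × size, sizes 2–30) are scored by MLR RMSE on a fixed seeded
2/3–1/3 split; rank-deficient chains truncate with a warning.

**UVE.** Appends $p$ artificial noise variables at negligible scale
($10^{-10}$; the stability statistic is scale-free), fits PLS under
leave-one-out resampling ($n \le 200$) or 100 Monte-Carlo leave-10%-out
rounds, and computes per-variable stability $c = \bar b / s_b$. Real
variables must beat the largest noise-variable $|c|$; survivors are
ordered by $|c|$ and the count minimizing 10-fold RMSECV is kept. All
selector-internal RNG streams are derived from the user seed rather than
used raw, so they cannot collide with a data-generating stream seeded
with the same integer (a collision would, for UVE, make the appended
noise an exact copy of the data columns).

## Regression back-ends and metrics

* **PLSR** — the package's NIPALS PLS1 engine (mean-centered, unscaled;
  nested in component count), default 7 components for the
  characteristic-wavelength workflow. The preprocessing harness instead
  re-selects components by CV.
* **MLR** — QR-based least squares; rank deficiency errors with the
  collinear columns named. Note that a full set of SNV-processed bands is
  exactly collinear with the intercept (each row sums to zero), which is
  the classic reason MLR is paired with selected subsets rather than full
  spectra.
* **RF** — the `randomForest` package, 100 trees, seed 42.
* **ANN** — a fully connected ReLU network with hidden layers
  (64, 32, 16, 8), linear output, He-uniform initialization under a fixed
  seed, inputs/response standardized internally, trained by exactly 1000
  full-batch Adam steps (lr 0.01). The widths are a free design choice
  documented here; depth, activation and iteration count are fixed by the
  workflow the package implements. Training is deterministic.

`split_table()` partitions 70/30 at random (or stratified by LWC
quartile) under a seed. `kfold_cv()` pools out-of-fold predictions
(folds differ in size by at most one); RMSECV is the pooled RMS error
and $R^2_{cv}$ is computed on pooled predictions. `evaluate()` uses
$R^2 = 1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ about the evaluation set's
own mean — the most common convention for prediction-set $R^2$, stated
here because conventions differ.

## Model ranking

`rank_models()` implements an accuracy-with-parsimony rule: among models
whose prediction $R^2$ is within 0.025 of the best, choose the fewest
wavelengths; break ties by lower RMSEP; outside the window the plain
arg-max wins. On the packaged benchmark metrics table this rule prefers
a 3-wavelength index model over a 12-wavelength ensemble model that is
0.0225 higher in $R_P^2$ — a 75% reduction in wavelengths for a small
accuracy trade, the decision pattern the rule is designed to encode.

## Water maps and cross-species evaluation

`predict_map()` applies any fitted model with a feature extractor
(NISDI or selected bands) to every leaf pixel; predictions are stored
unclipped with an out-of-range count, and only rendering clips (default
display range $[0,1]$, blue = dry to red = wet, neutral background,
deterministic PNG encoding with a gradient strip and JSON bounds
sidecar). For models linear in the spectrum, spatial averaging and
prediction commute exactly; the tests assert this for the NISDI linear
model and assert only the ordering (veins wetter than lamina) for
nonlinear models.

`cross_species_eval()` applies a frozen model bundle to external tables
without refitting, interpolating linearly onto the training grid when
grids differ (the external grid must cover the model's span), and
reports $r$ (with $p$), $R_P^2$ and RMSEP overall and per subgroup. The
pipeline's default external tables are one matched draw from the
training generator and one distribution-shifted draw (wider LWC range,
shallower/wider absorption, stronger scatter) emulating a different
species and growth form; the matched table reproduces internal accuracy
while the shifted one degrades, the qualitative pattern expected when
transferring a single-species model across species.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes the whole study from one configuration and one
seed, fanned out deterministically to stages: simulate → split →
preprocessing comparison → index searches + NISDI → selectors ×
regressors (+ full spectrum) → ranking → water map → cross-species. The
default grid (3 selectors × 4 regressors + 4 full-spectrum + 4 index
models) yields 20 model rows. Model rows whose fit is impossible
(e.g. MLR on an exactly collinear band set) are skipped with a warning
rather than aborting the study. The JSON report is byte-identical across
repeated runs with the same seed.

Default problem sizes — 360 samples × 224 bands for the study table,
48 × 48 pixel cubes, 10 seeds for recovery properties — were chosen as
the smallest sizes at which the statistical properties of interest are
stable and a full run completes in well under a minute on a laptop core;
the methods scale to instrument-sized data unchanged.

## Known limitations

* The synthetic spectra are a two-trough Gaussian model; real leaf
  spectra have additional features (e.g. near 970 and 1200 nm water
  bands, cellulose/protein absorption beyond 1600 nm).
* SNV/MSC behavior on amplitude-coded synthetic signal slightly
  overstates their cost relative to field data, where path-length
  scatter is stronger and their benefit correspondingly larger.
* The segmenter is a linear discriminant / band-ratio threshold; heavily
  overlapping reflectance distributions (wet soil backgrounds) would
  need a richer classifier.
* UVE's leave-one-out branch is $O(n)$ PLS fits; for $n$ in the
  thousands the Monte-Carlo branch is used automatically.
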