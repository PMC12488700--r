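---
title: "Methods: wavelength selection and feature fusion for hyperspectral growth monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelength selection and feature fusion for hyperspectral growth monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsiphen)
```

# The problem

Visible/NIR hyperspectral imagers record hundreds of contiguous
reflectance bands (here 380–1,022 nm, ~2.1 nm spacing) per plant.
Physiological targets such as the SPAD chlorophyll index (unitless,
~0–100) or aboveground dry biomass (g) depend on a small number of
spectral features — chlorophyll absorption, the red-edge inflection,
NIR scattering — while the remaining bands are redundant and strongly
collinear. The toolkit's job is to (i) stabilize the spectra, (ii) find
a compact, physiologically interpretable wavelength subset, (iii)
augment it with vegetation-index and spatial-texture information, and
(iv) fit and honestly evaluate regression models.

# Spectral pretreatment

Four row-wise pretreatments are provided. SNV centers and scales each
spectrum (n−1 denominator); MSC regresses each spectrum on a reference
(the training-partition mean inside model pipelines, to avoid leakage)
and corrects to `(x − a)/b`; Savitzky–Golay smoothing fits local
polynomials; the first derivative (reflectance per nm) amplifies slope
features. Choices the method descriptions leave open, fixed here:

* SG defaults: window 11, polynomial order 2 for smoothing; the
  derivative uses the SG derivative (window 7, order 2) because plain
  differencing amplifies noise. A central finite-difference mode exists.
* Edge handling: the SG filter's edge rows perform one-sided polynomial
  fits, so the output length equals the input length and no reflectance
  is fabricated beyond the spectrum ends.
* The derivative is applied to raw (not pre-smoothed) spectra by
  default; the SG derivative already smooths while differentiating.
* Constant spectra make SNV/MSC undefined and raise an error naming the
  sample rather than propagating NaNs.

`compare_preprocessing()` scores each pretreatment with a
fixed-parameter PLSR (5 components) on a seeded 7:2:1 split and ranks by
test-set R².

# PLS core

The PLS1 engine uses SIMPLS with mean-centering (unit-variance scaling
optional; off by default, the classical convention when ranking bands by
coefficient magnitude). Coefficients for all component counts are
retained from one fit, so cross-validation over 1..10 components costs a
single decomposition per fold. RMSECV uses 5-fold CV by default (fold
count is not prescribed by the method literature; 5 balances variance
against the 200-sample scale used throughout). Ties in the component
search resolve to fewer components. Rank exhaustion truncates the model
with a warning; a constant response yields zero coefficients and
mean predictions.

R² is defined as `1 − SS_res/SS_tot` (not squared correlation) — the
stricter convention. RPD is `sd(y_true)/RMSE` with the n−1 denominator,
so `RPD × RMSE = sd(y_true)` holds identically.

# CARS

At sampling run *i* of *N* (default 200): a random 80% subsample
(`mc_ratio = 0.8`, the standard choice) is drawn; PLS (≤ 10 components)
is fitted on the current working set; bands are ranked by absolute
regression coefficient; the exponentially decreasing schedule
`edf_retain_count()` — calibrated so run 1 retains all *p* bands and run
*N* retains 2 — forces removal of the weakest bands; and adaptive
reweighted sampling (draws proportional to |coefficient|) forms the
*next* run's working set. The subset evaluated and recorded at run *i*
is the post-forced-removal set, scored by RMSECV on the full sample set
with one fixed fold assignment, so run 1 evaluates the full spectrum and
the winning subset can never be worse than the full-band model. Ties
between runs resolve to fewer bands, then the earlier run. All-zero
coefficient vectors (degenerate subsample) fall back to uniform weights
with a warning.

# DRSA and its coupling to CARS

The dynamic reptile search algorithm is a box-bounded population
minimizer with four behavior updates (high walking, belly walking,
coordination hunting, cooperation hunting) built from the derived
quantities `R = (Best − x_r)/(Best + ε)`,
`P = α + (x − mean(x))/(Best·(UB − LB) + ε)` and `η = Best·P`.
Exploration (walking) is chosen with probability
`exp(−λ·t/t_max)`; the belly walk carries the disturbance factor
`ES = 2·r·(1 − t/t_max)`, `r ∈ {−1, 0, 1}`. The best-so-far solution is
elitist. Parameter defaults and why:

* `λ = 3`, `t_max = 100`, `pop_size = 30`: the exploration probability
  then spans 1 → ~0.05 over a run, giving a full
  exploration-to-exploitation sweep at a population size conventional
  for swarm optimizers of this family.
* `α = 0.1`, `β = 0.005`: the sensitivity conventions of the original
  reptile search algorithm; both configurable.
* `ε = 1e−10` guards every division; updates are clipped to the bounds,
  which absorbs the large excursions the `R` term produces when a
  best-coordinate approaches zero.
* Behavior granularity: the update equations are ambiguous about
  whether the behavior is drawn per individual or per dimension; the
  default draws once per individual per iteration (dimension-wise draws
  are available via `per_dimension_behavior`), which keeps the four
  equations' coordinate coupling intact.

**Subset encoding.** For wavelength selection each individual is a
continuous vector in `[0, 1]^d`; band *j* is selected iff its coordinate
exceeds `threshold = 0.5`. An empty decode is repaired by forcing the
single highest coordinate. Fitness is
`RMSECV(subset) × (1 + γ·k/d)` with `γ = 0.05`: the method literature
says the variable count is adjusted adaptively but not how, so the
package makes the pressure explicit and tunable (γ = 0 recovers
pure-RMSECV fitness). Fold assignment is fixed per run so all subsets
are scored on identical folds, and subset scores are memoized.

**Coupling mode.** The default *refine* mode searches within a candidate
pool recorded by CARS and injects the CARS-optimal subset as one initial
individual. The literal "union of all bands CARS ever retained" is
degenerate — run 1 retains the full spectrum — so the pool is defined as
the union of the subsets from the best decile of CARS runs by RMSECV
(always including the winner). A *standalone* mode searches the full
band range. Neither interleaving is asserted as canonical; both are
exposed.

**Trace semantics.** For CARS, `best_rmsecv = min(rmsecv_trace)` by
construction. For DRSA-CARS the trace records the unpenalized RMSECV of
the best-so-far subset under the penalized fitness ordering, so
`best_rmsecv` equals the final trace entry and coincides with the trace
minimum when γ = 0.

# Vegetation indices

Eight indices are computed from raw reflectance at nearest-grid bands
(ties to the lower wavelength). Search regions for band-pair
optimization: red edge 680–750 nm, NIR 700–1,000 nm, green 540–560 nm;
the search is exhaustive over instrument bands, maximizes |Pearson r|
against the target (so inversely scaled indices are not discarded), and
reports the signed correlation; ties resolve to the lowest wavelengths
and constant indices are skipped. Decisions worth flagging:

* The published flattened formulas for MSR<sub>REG</sub> and
  RDVI<sub>REG</sub> lose their radicals, under which MSR collapses to
  NDRE's algebraic form; the standard square-root forms are the default
  and `sqrt_dialect = FALSE` reproduces the literal flattened reading.
* EVI mixes two nearby NIR wavelengths (871 nm numerator, 873 nm
  denominator) as tabulated; implemented literally with a `unify_nir`
  switch.
* The NDVI variant takes its "red" band at 720 nm — a red-edge
  wavelength, not a classical red band — as published for this
  instrument configuration.
* Zero denominators yield NaN with a warning naming the samples, never
  silently.

# Texture features

Per cube, PCA (mean-centered, unscaled) of the masked-pixels × bands
matrix selects, for each of the first 3 components, the band with the
largest absolute loading (duplicates fall through to the next-highest
unused band). Each selected band image is quantized to 64 gray levels
over the masked min–max range — making the features invariant to
intensity shifts and rescaling — and co-occurrences are counted only for
pixel pairs wholly inside the ROI (a rectangle crop would contaminate
the statistics with background). The matrix is symmetrized, averaged
over four unit-distance orientations (0°, 45°, 90°, 135°) and normalized
to sum 1; MEA, CON, DIS and ENT follow, with natural-log entropy
(base-2 switch available). GLCM settings are unstated in the method
literature; these defaults are conventional and configurable. A
spatially constant ROI (possible at zero texture contrast) has no
principal spatial structure: `pca_band_select()` refuses it, and
`texture_pipeline()` falls back to evenly spaced representative bands
with a warning so the (all-zero) texture features are still defined.

# Models and evaluation

The dataset splits 7:2:1 by a seeded permutation with largest-remainder
rounding (ties to the earlier partition). Normalization (z-score by
default), the MSC reference and band selection inside model pipelines
are fitted on the training partition only and frozen for
validation/test. The validation columns of the evaluation report are
hold-out metrics (consistent with a fixed 7:2:1 split), not k-fold CV.

Model hyperparameters are not published for the motivating study; the
defaults are documented conventions: SVR (RBF, C = 10, ε = 0.1,
γ = 1/p on z-scored inputs); FNN (hidden layers 64/32, ReLU, Adam
1e-3, batch 32, ≤ 500 epochs, early stopping patience 30 with
best-weight restoration); CNN (two valid-mode 1-D conv blocks, kernel 5,
channels 16/32, global average pooling, dense 32) consuming feature
*vectors*, not images. The FNN/CNN trainers are a compact in-package
backpropagation engine (exact gradients, verified against finite
differences in the test suite) because the R stack here has no
multi-layer network framework; training is fully deterministic given the
spec seed. The kernel shrinks automatically when the feature vector is
too short for two valid convolutions. A perfect test fit gives infinite
RPD, reported capped with a flag.

# Synthetic data: what it emulates and what it does not

`gen_spectra()` builds leaf-like curves — visible plateau with a green
bump, logistic red-edge rise near 700 nm (width 14 nm), NIR plateau
~0.5 — perturbed per sample by amplitude (sd 2%), red-edge shift
(sd 2 nm), plateau jitter, a smooth low-order harmonic deviation, and
iid per-band measurement noise (sd 0.03 reflectance), clipped to
[0, 1.2]. The target is a linear combination of planted bands plus
Gaussian noise (default sd 0.3). The balance deliberately favors
per-band independent noise over shared latent variation: real leaf
spectra are smoother and more collinear, but planted-band recovery is
only *identifiable* when informative bands carry unique variance.
Passing selection tests therefore demonstrates correct mechanics and
ranking behavior, not expected performance on field data, where
physiological factors correlate whole spectral regions.

`gen_cube()` renders an elliptical plant blob (~50% of pixels) over a
flat dark background; inside the mask, reflectance is the leaf curve
modulated by sinusoidal vein ridges whose amplitude is linear in
`texture_contrast` plus a bounded fine-grain term growing quadratically.
Because GLCM quantization cancels pure rescaling, monotonicity of
texture contrast is carried by the changing ridge/grain mixture. At zero
contrast the ROI is exactly constant. `gen_fusion_dataset()` couples
per-sample cubes (texture strength uniform on [0.5, 2.5]) with a target
depending on two reflectance bands and quadratically on texture
strength, while a 15% amplitude jitter confounds the overall reflectance
level — so the texture contribution is recoverable from GLCM features
but only weakly from spectra, giving fused models a real, quantifiable
advantage. No radiative-transfer (PROSPECT/SAIL-class) realism is
attempted.

# Problem sizes and reproducibility

The test suite and the acceptance script run selection studies at 50
bands × 200 samples (10 seeds), fusion studies at 150 samples with
24 × 24 × 40 cubes, and sphere-function optimizer checks at 5
dimensions — sizes chosen so the full synthetic study design executes in
a few minutes on one CPU while leaving every mechanism (EDF schedule,
behavior mixing, fold-fixed RMSECV, texture quantization) fully
exercised. Every stochastic function takes an explicit seed, restores
the caller's RNG state, and fans out derived stage seeds (`run_full()`
documents the offsets), so all reported artifacts are bit-reproducible.

# Known limitations

* The ENVI reader supports 32/64-bit float raw cubes with a wavelength
  list; vendor-specific binary dialects are out of scope.
* PLS1 only (single response); no kernel or multi-response variants.
* The refine-mode candidate pool (best-decile union) is a design choice;
  other pools are plausible and easily substituted.
* The feature-vector CNN has limited positional sensitivity after global
  pooling; it is included for completeness of the model family, not as
  the recommended architecture.
* Published benchmark values ship only as fixed reference inputs for the
  summary arithmetic; the underlying field data are unavailable, so no
  claim of reproducing field-scale accuracy is made.
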