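# hsiphen

Hyperspectral growth monitoring for cultivated plants: estimate leaf
chlorophyll status (SPAD) and aboveground biomass from reflectance
spectra and imagery, with compact, physiologically interpretable
wavelength subsets.

`hsiphen` is aimed at plant-phenotyping and chemometrics practitioners
working with visible/NIR hyperspectral data (hundreds of contiguous
bands, typically 380–1,022 nm). It implements the full workflow:

1. **I/O** — ENVI-style cubes (`read_envi()`, `write_envi()`), ROI masks,
   per-plant mean spectra (`extract_roi_mean_spectrum()`), tabular
   spectra/target CSVs.
2. **Pretreatment** — SNV, MSC, Savitzky–Golay smoothing and first
   derivative (`snv()`, `msc()`, `sg_smooth()`, `first_derivative()`),
   plus a fixed-parameter PLSR bake-off (`compare_preprocessing()`).
3. **Wavelength selection** — classical competitive adaptive reweighted
   sampling (`run_cars()`) and a **dynamic reptile search algorithm
   coupled to CARS** (`drsa_cars_select()`), the toolkit's core method.
4. **Vegetation indices** — eight red-edge/NIR indices (NDVI, NDRE,
   CI<sub>green</sub>, CI<sub>rededge</sub>, EVI, MSR<sub>REG</sub>,
   OSAVI<sub>REG</sub>, RDVI<sub>REG</sub>) with exhaustive band-pair
   optimization against the target (`optimize_band_pair()`).
5. **Texture** — PCA-guided representative-band selection and masked
   GLCM features MEA/CON/DIS/ENT (`texture_pipeline()`).
6. **Models** — feature fusion (`fuse_features()`), a seeded 7:2:1
   split, and PLSR / SVR / feed-forward / 1-D convolutional regression
   with R², RMSE and RPD reporting (`train_model()`, `evaluate()`).

A seeded synthetic module (`gen_spectra()`, `gen_cube()`,
`gen_fusion_dataset()`) produces leaf-like spectra and textured plant
cubes with *known planted ground truth*, so every stage is testable
without field data.

## The core method

CARS eliminates wavelengths over Monte Carlo sampling runs: at run *i* a
PLS model is fitted to a random 80% subsample, bands are ranked by
|regression coefficient|, an exponentially decreasing schedule forces
the retained count from *p* down to 2, and adaptive reweighted sampling
forms the next working set; the subset minimizing the cross-validated
RMSE (RMSECV) wins.

DRSA-CARS replaces the greedy end-game with a population search. Each
individual is a continuous vector **x** ∈ [0, 1]^d over the CARS
candidate bands, decoded by thresholding (band *j* in the subset iff
x<sub>j</sub> > 0.5). The dynamic reptile search algorithm alternates
four behavior updates (high walking, belly walking, coordination and
cooperation hunting), choosing exploration with probability

&nbsp;&nbsp;&nbsp;&nbsp;P<sub>explore</sub>(t) = exp(−λ·t/T<sub>max</sub>),

with a disturbance factor ES = 2·r·(1 − t/T<sub>max</sub>), r ∈ {−1, 0, 1},
in the belly walk. The fitness of a decoded subset of size *k* is

&nbsp;&nbsp;&nbsp;&nbsp;RMSECV(PLS on subset) · (1 + γ·k/d),

so accuracy and parsimony are balanced (γ = 0.05 by default; γ = 0 gives
pure-RMSECV fitness). The result is a smaller, equally accurate band
subset.

## Worked example

```r
library(hsiphen)

spec <- planted_band_spec(
  informative_band_indices = c(5, 12, 20, 31, 44),
  coefficients = c(2, -3, 2.5, 1.5, -2),
  noise_sd = 0.05, n_samples = 200, n_bands = 50, seed = 42)
d <- gen_spectra(spec)

cars <- run_cars(d$spectra, d$target, seed = 42)
drsa <- drsa_cars_select(d$spectra, d$target,
                         drsa_config(seed = 42), cars_result = cars)
dplyr::bind_rows(glance(cars), glance(drsa))
#> # A tibble: 2 × 7
#>   method    n_selected best_rmsecv best_run n_components r2_fit  seed
#>   <chr>          <int>       <dbl>    <int>        <int>  <dbl> <int>
#> 1 CARS               7      0.0519        3            3 NA        42
#> 2 DRSA-CARS          5      0.0511      100            5  0.905    42

tidy(drsa)
#> # A tibble: 5 × 3
#>   method    band_index wavelength_nm
#>   <chr>          <int>         <dbl>
#> 1 DRSA-CARS          5          432.
#> 2 DRSA-CARS         12          524.
#> 3 DRSA-CARS         20          629.
#> 4 DRSA-CARS         31          773.
#> 5 DRSA-CARS         44          943.
```

Five bands were planted into the target; CARS keeps 7 bands, DRSA-CARS
keeps exactly the 5 planted ones at a slightly lower RMSECV — fewer
features, no loss of accuracy. `autoplot()` methods visualize spectra,
RMSECV traces and evaluation reports; `run_full()` chains every stage
and writes JSON reports with config-hash/seed provenance.

A thin command-line front end ships in `inst/cli/hsiphen.R` with
`simulate`, `preprocess`, `select`, `vi`, `texture` and `train`
subcommands over CSV/JSON files.

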