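# hyperleaf

Estimation of gravimetric leaf water content (LWC) from near-infrared
(900–1700 nm) hyperspectral reflectance, for plant physiologists and
chemometricians working with line-scan NIR imagers.

Leaf water content is the water fraction of fresh mass,
`M = (G − G0) / G` (fresh mass `G`, oven-dry mass `G0`). Water's O–H
overtones absorb strongly in the NIR — most prominently near 1440 nm — so
reflectance and local spectral slope track LWC. `hyperleaf` implements the
full estimation chain:

* **Cube handling** — ENVI (`.hdr` + BIL/BIP/BSQ) reading and writing,
  black/white reflectance calibration `R = (I − B)/(W − B)`,
  leaf/background segmentation (linear discriminant or band-ratio Otsu
  threshold), per-sample mean spectra.
* **Indices** — the Near-Infrared Slope Difference Index
  `NISDI = 1.3e3·D(1559) − 1.9·R(1439)` (slope `D` in nm⁻¹, anchors
  snapped to the grid), plus exhaustive ordered band-pair searches over
  DVI/RVI/NDVI with Pearson screening (two-tailed t test) and full |r|
  heatmaps, and univariate linear index → LWC models.
* **Preprocessing** — SNV, MSC, Savitzky–Golay (wavelength-aware,
  truncated-window edges), min–max normalization, first derivative, the
  SG+X combinations, and a PLSR harness that ranks methods by 10-fold
  RMSECV.
* **Wavelength selection** — CARS, SPA and UVE with RMSE/RMSECV
  diagnostic traces.
* **Regression** — PLSR (in-package NIPALS PLS1), MLR, random forest
  (100 trees, seed 42) and a deterministic 4-hidden-layer ReLU network,
  with 70/30 splitting, 10-fold CV, and the R²/RMSE metric suite
  (R², RMSE, R²cv, RMSECV, R²P, RMSEP).
* **Application** — per-pixel water-content maps (blue = dry, red = wet)
  and a cross-species evaluation harness that applies a frozen model to
  external tables, resampling grids by interpolation.
* **Synthetic data** — a tested generator for 224-band leaf spectra,
  4-step drying series, sample tables and vein-structured image cubes,
  including planted-signal modes for oracle testing, so the whole
  pipeline runs without any external data.

## Worked example

```r
library(hyperleaf)

# simulate a drying study: 300 leaves, 224 bands, LWC in [0.14, 0.77]
cfg <- sim_config(seed = 42)
tab <- simulate_sample_table(300, cfg, seed = 42)

# NISDI against measured water content
v <- as.numeric(nisdi(tab$reflectance, tab$grid))
pearson(v, tab$water_content)
#> $r
#> [1] 0.9827852
#> $p
#> [1] 1.304373e-220
#> $n
#> [1] 300

# calibrate / predict split and a univariate NISDI model
parts <- split_table(tab, 0.3, seed = 42)
m <- fit_index_model(
  as.numeric(nisdi(parts$calibration$reflectance, tab$grid)),
  parts$calibration$water_content,
  as.numeric(nisdi(parts$prediction$reflectance, tab$grid)),
  parts$prediction$water_content)
unlist(m$metrics)
#>     r2_cal   rmse_cal    r2_pred      rmsep
#> 0.96821399 0.03348318 0.95800819 0.03504244

# per-pixel water map of a simulated leaf: veins predict wetter
sc <- simulate_cube(48, 48, cfg, vein_offset = 0.1, seed = 43)
wm <- predict_map(sc$cube, m, nisdi_extractor(), model_id = "NISDI-LR")
c(vein = mean(wm$values[sc$veins]),
  lamina = mean(wm$values[sc$cube$mask & !sc$veins]))
#>      vein    lamina
#> 0.5879665 0.4984239
render_map(wm, "water_map.png")
```

The Pearson r of 0.983 says NISDI explains ~96% of LWC variance in the
simulated study; the index model carries that to held-out leaves
(R²P = 0.958, RMSEP = 0.035, i.e. about 3.5 percentage points of water
content), and the map recovers the planted 0.1 vein–lamina contrast at
about 0.09 after spectral noise.

The full study — preprocessing comparison, three selectors crossed with
four regressors, index searches, ranking, mapping and cross-species
checks — runs from one seed:

```r
report <- run_pipeline(pipeline_config(seed = 1, out_dir = "study_out"))
report
#> <study_report> 20 model rows; chosen: RVI-LR (R_P^2 = 0.9979, RMSEP = 0.0088, 2 wavelengths)
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/hyperleaf` (subcommands `simulate`, `prep-compare`,
`index-search`, `select`, `fit`, `map`, `cross-eval`, `run`;
`--show-config` prints the YAML defaults).

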