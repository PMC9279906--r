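# canopyspec

Hyperspectral canopy phenotyping in R: from raw Vis–NIR hypercubes to
non-destructive predictions of biochemical quality traits such as soluble
solids content (SSC, %) and pH.

Destructive trait assays (juicing a plant for a refractometer or pH meter)
are slow and kill the sample. A calibrated canopy reflectance spectrum —
400–1,000 nm, 256 bands — carries pigment, structure and water signals
that co-vary with those traits, so a regression model can predict them
from a single image. `canopyspec` implements the whole chain for
high-throughput phenotyping work:

* **Cube I/O and calibration** — ENVI hypercubes (BSQ/BIL/BIP), white/dark
  reflectance calibration `R = (R_raw − R_d)/(R_w − R_d)` with masking of
  degenerate reference positions.
* **Canopy segmentation** — spectral angle mapper (SAM) against
  user-supplied plant/background endmembers,
  `θ = arccos(⟨t,r⟩ / ‖t‖‖r‖)`, illumination-invariant; per-plant mean
  spectrum extraction.
* **Pretreatments** — moving window smoothing, Savitzky–Golay filtering,
  first/second derivatives, wavelet denoising (db4, soft universal
  threshold).
* **Sampling** — Kennard–Stone max–min partitioning into a 2:1
  calibration:prediction split with a seeded 15% validation carve-out
  (387 samples → 219/39/129).
* **Wavelength selection** — competitive adaptive reweighted sampling
  (CARS): Monte-Carlo PLS fits, an exponentially decreasing forced
  retention schedule, adaptive reweighted sampling, RMSECV-minimizing run.
* **Models** — five chemometric baselines (PLSR, LWR, MLR, ANN, SVR)
  behind one fit/predict contract, plus two purpose-built neural
  regressors written natively in R: `Deep2D` (spectrum reshaped to a
  16×16 grid, three parallel convolution branches at kernel sizes 1/3/5
  with ELU, channel concatenation, linear FC reduction) and `DeepFC`
  (expand-then-contract fully connected stack, 256→512→256→64→16→1,
  dropout on the first two hidden layers, linear activations), trained
  with Adam (batch 4, lr 1e-4) on an RMSE loss with early stopping.
* **Evaluation** — R², RMSE and RPD per split
  (`RPD = SD(reference)/RMSE`, prediction set).
* **Synthetic data** — a seeded generator of canopy-like spectra with
  known trait structure (green peak, red edge, 980 nm water dip;
  truncated-normal traits) so the entire pipeline is testable without
  field data.

## Worked example

```r
library(canopyspec)

g <- generate_spectra(generator_config(seed = 42))   # 387 synthetic canopies
y <- g$traits$ssc
s <- split_samples(g$spectra, seed = 42)
s
#> <split_indices> calibration 219 / validation 39 / prediction 129 (seed 42)

fit <- fit_plsr(g$spectra[s$calibration, ], y[s$calibration], n_components = 10)
evaluate_model(fit, s, g$spectra, y, model_tag = "PLSR")
#> <eval_report> PLSR / raw
#>   calibration (n=219): R2 = 0.9999, RMSE = 0.0061
#>   validation  (n=39): R2 = 0.9965, RMSE = 0.0380
#>   prediction  (n=129): R2 = 0.9962, RMSE = 0.0359, RPD = 16.2401
```

The split counts are the canonical 2:1 + 15% arithmetic. The report rows
are the seven headline statistics of a trait-calibration study: R² and
RMSE on the calibration, validation and prediction sets, and the RPD of
the prediction set (values above 3 conventionally read as excellent
quantitative prediction — easy on clean synthetic data, much harder in
the field). Wavelength selection works the same way:

```r
cars_select(g$spectra[s$calibration, ], y[s$calibration], runs = 50, seed = 42)
#> <cars_result> 142 wavelengths selected at run 1/10 (RMSECV 0.02473)
```

Deep models consume raw spectra directly:

```r
m <- train_deep(build_deepfc(deepfc_spec(seed = 1)),
                g$spectra[s$calibration, ], y[s$calibration],
                g$spectra[s$validation, ], y[s$validation],
                train_config(max_epochs = 150, patience = 30, seed = 2))
r_squared(predict(m, g$spectra[s$prediction, ]), y[s$prediction])
```

A full experiment grid (pretreatment × selection × model) runs through
`run_config()`/`run_grid()`, or from a shell via the bundled CLI
(`inst/cli/canopyspec`) with subcommands `simulate`, `calibrate`,
`segment`, `extract`, `preprocess`, `split`, `select`, `fit`, `evaluate`
and `grid`.

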