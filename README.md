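# presspulse

Analysis of phytoplankton responses to combined **press** (stepwise
eutrophication) and **pulse** (transient mortality) perturbations in
mesocosm experiments.

Aquatic mesocosm studies increasingly superimpose repeated mortality pulses
(e.g. oxidant-induced kill events applied to a volume fraction of each
vessel) on a sustained nutrient-enrichment press, and follow chlorophyll-a,
dissolved nutrients and total microbial biovolume through time. The
scientific questions — does eutrophication amplify the response to shocks?
does the community resist and recover less after repeated shocks? — are
answered through three per-cycle indices computed from each replicate's
chlorophyll-a series. With `C0` the pre-response condition, `Peak` the
response maximum, and `Dx = |post-event level − C0|` the residual
displacement:

```
D0 = |C0 − Peak|                 maximum displacement (µg chl-a/L)
RS = 1 − 2·D0/(C0 + D0)          resistance,  1 = no change, 0 = 100% change
RC = 2·D0/(D0 + Dx) − 1          recovery,    1 = full, 0 = none, <0 = drift
```

Both relative indices are rescaled to a 0–10 scale anchored at
`RS: 1→10, 0→9, −1→0` and `RC: 1→10, 0→1, −1→0`.

The package provides, as composable functions plus an end-to-end pipeline:

- `simulate_experiment()` — a synthetic-data generator reproducing the
  canonical layout (3 treatments × 6 replicates, 105 days sampled every
  other day, pulses at days 4/40/68 killing 50%/15%/30%, stepwise TP dosing
  toward 0.41/0.82 mg/L) with known ground-truth effect sizes;
- `segment_experiment()` / `detect_pre_response()` — automated least-
  variance moving-window detection of the pre-response condition, response
  peak and post-event state, with cross-cycle chaining;
- `compute_metrics()` and the index functions above;
- `fit_metric_trends()` — linear mixed-effects estimation (lme4/lmerTest)
  of eutrophication and sequential-perturbation effects, with automatic
  random-structure fallback and marginal/conditional variance explained;
- `predict_tp()` / `solve_dose_volume()` / `classify_limitation()` — the
  dilution mass balance behind phosphorus dosing and molar N:P limitation
  bands (16:1 / 25:1);
- `run_pipeline()` — simulation (or CSV ingestion) → segmentation →
  metrics → limitation classes → biovolume period averages → effect
  estimates, written as CSVs plus a JSON summary and run log.

## Worked example

```r
library(presspulse)

design  <- experiment_design()          # the canonical 18-mesocosm layout
params  <- simulation_params(seed = 42) # enriched response multiplier = 2
ts      <- simulate_experiment(design, params)
windows <- segment_experiment(ts, design)
metrics <- compute_metrics(windows, design)

head(metrics[, c("treatment","replicate","cycle","c0","peak","d0",
                 "rs_scaled","rc_scaled")])
#>   treatment replicate cycle   c0  peak    d0 rs_scaled rc_scaled
#> 1   control control_1     1 12.9 106.6  93.8      2.18      7.28
#> 2   control control_1     2 29.6  80.1  50.5      6.64      5.58
#> 3   control control_1     3 46.0 161.9 115.9      5.11      4.34
#> 4   control control_2     1 11.8 111.3  99.5      1.91      8.10
#> 5   control control_2     2 23.6  74.7  51.1      5.68      4.99
#> 6   control control_2     3 43.3 142.1  98.9      5.48      3.84

estimate_displacement_ratio(metrics)
#> [1] 1.79

fit_metric_trends(metrics)
#> Perturbation-metric trend estimates (reference: control)
#>     metric            term  f_value  p_value marginal_r2 conditional_r2
#>         c0 n_perturbations 229.6000 2.53e-20       0.843          0.843
#>         c0  eutrophication  27.3300 9.54e-09       0.843          0.843
#>         d0 n_perturbations  52.7800 2.31e-09       0.593          0.593
#>         d0  eutrophication  12.2800 4.60e-05       0.593          0.593
#>  rs_scaled n_perturbations  22.5100 1.79e-05       0.304          0.304
#>  rs_scaled  eutrophication   0.2972 7.44e-01       0.304          0.304
#>  rc_scaled n_perturbations   7.9990 6.72e-03       0.192          0.192
#>  rc_scaled  eutrophication   2.2850 1.12e-01       0.192          0.192
```

Reading the output: 54 perturbations (18 replicates × 3 cycles) were
quantified. Pre-response chlorophyll rises strongly with the number of
perturbations experienced; the enriched treatments displace ~1.8× the
control in absolute units (`d0`, eutrophication term significant) while the
*relative* resistance shows no treatment effect — the generator's built-in
contrast, recovered by the estimator. Resistance rises and recovery falls
across cycles.

Desk checks of the index conventions:

```r
resistance(20, 20)   # 100% change         -> 0
recovery(10, 10)     # residual = maximum  -> 0 (no recovery)
rescale_resistance(c(1, 0))  # -> 10 9
rescale_recovery(c(1, 0))    # -> 10 1
```

## Package layout

```
R/                 implementation (design, simulate, dosing, windows,
                   metrics, trends, io)
tests/testthat/    unit, property and acceptance tests
scripts/           acceptance script
vignettes/         methods vignette: models, assumptions, design choices
```
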