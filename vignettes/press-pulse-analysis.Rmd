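---
title: "Quantifying phytoplankton resistance and recovery under combined press and pulse perturbations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phytoplankton resistance and recovery under combined press and pulse perturbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presspulse)
```

## The problem

Freshwater systems are increasingly exposed to two kinds of perturbation at
once: a *press* — a sustained pressure such as eutrophication, which does not
dissipate and forces the system toward a new equilibrium — and *pulses* —
transient shocks such as storm- or chemically-induced mortality events, after
which the system may (or may not) bounce back. Mesocosm experiments probe
their interaction by enriching replicated vessels of natural lake water
stepwise with phosphorus while applying repeated mortality pulses to a
defined volume fraction of each vessel, and following chlorophyll-a (the
phytoplankton biomass proxy), dissolved nutrients, and total microbial
biovolume through time.

`presspulse` implements the full quantification chain for such experiments:

1. **segmentation** of each replicate's chlorophyll-a series into
   perturbation cycles, extracting the *pre-response condition* C0, the
   *response peak*, and the *post-event condition*;
2. **perturbation metrics** — maximum displacement, resistance, and
   recovery, raw and rescaled to a 0–10 scale;
3. **effect estimation** — linear mixed-effects models of eutrophication and
   sequential-perturbation effects, plus the biovolume/chlorophyll
   regression stage;
4. **dosing arithmetic** — the dilution mass balance used to plan phosphorus
   additions, and stoichiometric N:P limitation classification;
5. a **synthetic-data generator** that reproduces the statistical structure
   of such experiments with known ground truth, so every stage can be
   validated end to end.

## Perturbation metrics

Within one cycle, let `C0` be the stable chlorophyll-a level just before the
system visibly reacts to the pulse, `Peak` the maximum level in the cycle,
and `Dx_level` the stable level at the cycle's end. The three indices are:

- **Maximum displacement** `D0 = |C0 − Peak|` (µg/L): the *absolute* size of
  the response, in chlorophyll units.
- **Resistance** `RS = 1 − 2·D0/(C0 + D0)`: a *relative* index in (−1, 1].
  `RS = 1` means the pulse changed nothing; `RS = 0` corresponds to a 100%
  change relative to `C0` (e.g. `C0 = 20`, `D0 = 20`); values below 0 mean
  the system was displaced by more than its own pre-response level.
- **Recovery** `RC = 2·D0/(D0 + Dx) − 1`, where `Dx = |Dx_level − C0|` is
  the *residual* displacement at the post-event state. `RC = 1` is full
  recovery (`Dx = 0`), `RC = 0` is no recovery (`Dx = D0`, e.g. `C0 = 10`,
  `Peak = 20`, post-event level 20), and negative values mean the system
  drifted beyond its maximum displacement.

Both relative indices are scale-invariant — multiplying `C0`, `D0` and `Dx`
by a common factor leaves them unchanged — which is what makes treatments
with very different absolute chlorophyll levels comparable. Note that the
displacement formula is used as a magnitude: in nutrient-turnover systems
the "displacement" is usually an overshoot *above* baseline.

Because both indices compress severe responses into a narrow numeric range,
they are also reported on a 0–10 scale. The rescaling maps are strictly
increasing piecewise-linear maps pinned at the conventional anchors:

```{r}
rescale_resistance(c(1, 0, -1))   # no change -> 10, 100% change -> 9, -> 0
rescale_recovery(c(1, 0, -1))     # full -> 10, none -> 1, drift -> below 1
```

The negative branch of the resistance map (and the positive branch of the
recovery map) is expanded so that the ecologically interesting region
occupies most of the scale. Exact anchor placement between those points is a
convention; both maps are injectable arguments of `compute_metrics()` so an
alternative anchored map can be swapped in without touching callers.
A rescaled recovery of exactly 1 marks the *point of no recovery*
(`Dx = D0`).

## Finding the windows

The pre-response condition is detected automatically, because responses lag
pulses: the last quiet moment is usually *after* the pulse was applied, and
chaining requires consistency across cycles. The rule: among all contiguous
sample windows containing at least 2 samples and spanning at least 3
calendar days (inclusive), pick the one with minimum unbiased sample
variance; `C0` is its mean. Ties break to the earliest start day, then the
shortest window. `detect_pre_response()` implements this as an explicit
enumeration, and the test suite holds it equal to an independently written
brute-force oracle on random fixtures.

`segment_cycles()` composes the per-cycle extraction:

- a cycle runs from one pulse day (exclusive) to the next (inclusive), the
  last one to the series end; the sample taken on a pulse day precedes the
  pulse (morning sampling) and so closes the previous cycle;
- the **peak** is the maximum raw chlorophyll-a after the pulse day;
- the **pre-response search region** starts halfway between the previous
  cycle's peak and the current pulse day (`lookback_frac = 0.5`) and ends
  just before the current peak — restricting the search to before the peak
  prevents a late plateau from posing as "pre-response", while the lookback
  implements the observation that the quiet window need not precede the
  pulse itself. If the region is too sparse the lookback widens stepwise
  (previous peak, previous pulse day, series start);
- **chaining**: the post-event condition of cycle *p* *is* the pre-response
  window of cycle *p + 1*, exactly — one level per boundary, used by both
  cycles;
- the **final cycle** has no successor; its post-event condition is the
  least-variance window within the cycle's last quarter
  (`final_frac = 0.25`), flagged *unrecovered* when its variance exceeds
  `unrecovered_mult = 5` times the pre-response variance (a window whose
  spread is below 1% of its own level always counts as stable, so smooth
  noiseless series are not flagged spuriously).

Before the variance scan the series is smoothed with a centered moving
average spanning `smooth_span_days = 5` days (three samples at every-other-
day cadence); the peak is always taken from raw samples. The smoothing is
part of the detection rule: with as few as two samples per candidate window
and multiplicative noise, a raw scan is occasionally won by an incidentally
flat pair of points on the *shoulder of the response peak*, which corrupts
`C0` badly. Averaging three neighbouring samples makes such coincidences
rare while leaving genuinely quiet periods quiet. Set
`smooth_span_days = 0` to scan raw samples. Variance is computed on
untransformed chlorophyll; no imputation is done — windows are built from
available samples only.

## Effect estimation

`fit_metric_trends()` models each metric (pre-response `C0`, displacement
`d0`, rescaled resistance and recovery) with fixed effects for the number of
pulse perturbations experienced (a numeric trend — the metrics are functions
of cycle, not calendar time) and the treatment (control as reference), and
random terms for the replicate and the pulse intensity. The full random
structure — a per-replicate random slope on the perturbation count plus a
random intercept per intensity level — is attempted first and simplified
automatically on singular or failed fits, down to a random intercept per
replicate. This mirrors how such designs are actually analysed: with one
intensity per cycle the intensity term is confounded with the trend and is
usually dropped by the singularity check. F statistics use Satterthwaite
denominator degrees of freedom (`lmerTest`); for small designs a
permutation-based p-value (`pvalues = "permutation"`) is available, which
permutes treatment labels across replicates and cycle order within
replicates. Smooth (additive) cycle effects are deliberately not modelled:
with three cycles a linear term exhausts the resolvable structure.

Variance explained is reported as the marginal (fixed effects only) and
conditional (fixed plus random) proportions, computed from the empirical
variances of the fitted components; the marginal value can never exceed the
conditional one.

The headline fold-change — how much eutrophication amplifies the absolute
response — is estimated by `estimate_displacement_ratio()` as the ratio of
mean displacement in the enriched treatments (pooled) to the control mean,
matching the quantity usually quoted ("displacement nearly twice the
control").

`fit_chl_biovolume()` covers the long-term stage: a linear model of total
chlorophyll on total biovolume with a treatment interaction (does enrichment
change the chlorophyll yield per unit biovolume?), with an optional log10
transform applied automatically when a Shapiro–Wilk screen on the residuals
fails. `cycle_average_biovolume()` averages biovolume per replicate over the
baseline period and each perturbation cycle — with 3 treatments × 6
replicates × 4 periods this yields the canonical 72 records —, and
`total_biovolume()` turns particle-counter size-bin counts into a total
(mean over technical counts, then sum over bins).

## Dosing arithmetic

Phosphorus additions follow a three-solution dilution mass balance: vessel
water left after sampling (`cc_prev`, `vc`), refill water (`cr`, `vr`) and
dosing stock (`cs`, `vs`) mix to

```
TP_next = (cc_prev·vc + cr·vr + cs·vs) / (vc + vr + vs)
```

`predict_tp()` evaluates it; `solve_dose_volume()` inverts it for the stock
volume needed to reach a target, with the refill volume absorbing the slack
so the vessel closes at its nominal volume (10 L in the reference layout).
Infeasible targets (above what the stock can reach, or below the no-dose
mixture) raise a dedicated `presspulse_infeasible` condition, distinct from
invariant violations. The inversion round-trips through `predict_tp()` to
1e-9 relative tolerance.

`classify_limitation()` classifies dissolved N:P ratios molarly (atomic
masses N 14.007, P 30.974): above 25:1 phosphorus-limited, below 16:1
nitrogen-limited, co-limited between. The boundaries sit at the Redfield
ratio and the commonly used 25:1 threshold, are configurable, and boundary
ratios fall in the co-limited band (the convention here; sources rarely
specify it). Molar rather than mass ratios are used because the 16:1
Redfield anchor is molar.

## The synthetic-data generator

No deposited dataset ships with the package; instead `simulate_experiment()`
generates experiments with the reference structure — 3 treatments × 6
replicates (N = 18), 105 days sampled every other day (53 sampling days),
pulses at days 4/40/68 killing 50%/15%/30% of the community, stepwise TP
dosing toward 0.41 and 0.82 mg/L in the enriched arms — with every effect
size known, so segmentation, metrics and the mixed-model stage can be
validated against ground truth.

**Mechanistic core.** Each mesocosm carries phosphorus compartments
(biomass-bound, dissolved, dead-organic; nitrogen pools in parallel at a
fixed biomass N:P mass quota of 7.2). Chlorophyll grows logistically toward
the minimum of a light ceiling (`base_K = 12` µg/L, matching the P-derived
capacity of unenriched lake water at ~12 µg P/L) and the P-derived capacity
`chl_yield × accessible P`, drawing stoichiometrically on the dissolved
pools. A pulse instantaneously moves the killed biomass fraction to the
dead pool (`apply_pulse()`); the dead pool remineralizes to the dissolved
pools at `remineralization_rate = 0.5`/day — fast turnover, consistent with
the dissolved-nutrient spikes that follow chemically induced mortality.
Dosing raises dissolved P to the design's per-cycle TP target immediately
after each pulse. Integration is forward Euler with 20 sub-steps per day.
In a closed configuration (no dosing) total P over all compartments is
conserved exactly, which the tests verify; the community starts at
equilibrium (`initial_biomass_frac = 1`), as after an acclimation period.

**Response structure.** A quota-logistic model cannot overshoot its own
capacity, but real communities do: mortality plus nutrient turnover
produces transient chlorophyll peaks well above baseline. The generator
therefore multiplies the mechanistic biomass by a deterministic community
response factor composed, per pulse, of

- a *transient* term with relative amplitude
  `resp_amplitude × kill fraction × hardening_per_cycle^(cycle−1)`
  (defaults 16, 0.8), shaped as a gamma-like curve peaking
  `resp_rise_days = 6` days after the pulse — amplitude proportional to
  kill fraction makes displacement track intensity, and the hardening
  factor makes the community progressively more resistant across cycles;
- a *retained-displacement* term: a fraction
  `min(0.95, recovery_loss_per_cycle × cycle)` (default 0.15/cycle) of the
  transient amplitude is kept permanently, accruing with a 14-day delay so
  peak and new baseline stay separated in time. This drives the rising
  baselines and the per-cycle loss of recovery (ground-truth raw recovery
  ≈ 0.74/0.54/0.38 across cycles);
- for enriched treatments, a *press gain* ramping from 1 to
  `eutro_displacement_multiplier` (default 2) after the first dosing, with
  a 14-day delay and 2-day e-folding. The timing is deliberate: the gain is
  inert at the first cycle's peak and saturated before the second cycle's
  pre-response window, so within every cycle the enriched and control
  trajectories differ by a *constant* factor. Both relative indices are
  scale-invariant, so the generator's ground truth is: absolute
  displacement doubled from cycle 2 onward, resistance and its trend
  unchanged by treatment — the canonical press–pulse contrast. Both
  enriched arms share the same gain (their chlorophyll responses are
  intentionally similar; they differ in their nutrient columns).

Observations carry multiplicative lognormal noise (`noise_cv = 0.12`) plus
a fixed per-replicate lognormal scale (`replicate_cv = 0.08`); group
chlorophyll fractions are fixed shares of the total (so they sum exactly),
biovolume is proportional to chlorophyll (2.5 × 10^5 µm³/ml per µg/L) with
its own noise, and dissolved PO4/DIN report the internal pools with noise.
A pulse of fraction 0 causes no mortality and triggers no response, so the
pulse-free limit is exactly logistic — a property the tests check against
the closed-form solution.

**What the generator does *not* emulate.** Taxon-resolved composition and
succession, grazing, periphyton, residual-oxidant chemistry, and
volume/refill bookkeeping (refill dilution is folded into the dosing step).
The enrichment gain raises enriched baselines between cycles 1 and 2, which
necessarily depresses *measured* cycle-1 recovery in enriched arms (the
chained post-event level doubles); treatment comparisons of recovery in
generated data therefore carry that imprint even though the underlying
retention rule is treatment-neutral. The mid and strong arms produce
identical chlorophyll dynamics by design; analyses that must distinguish
them should look at the nutrient columns. Consequently, passing tests
demonstrate that the pipeline recovers known effects from data with this
covariance structure — not that the mechanistic core is a faithful lake
model.

## Numerical choices and degenerate inputs

- Window ties break deterministically (earliest start, then shortest);
  variances are computed with a numerically stable incremental scheme and
  verified against `stats::var`.
- An undisplaced cycle (`D0 = Dx = 0`) is defined as resistance 1 and
  recovery 1 with a `degenerate` flag (and a warning from `recovery()`),
  so batch processing never aborts on a flat replicate.
- `solve_dose_volume()` distinguishes infeasible targets
  (`presspulse_infeasible`) from invalid inputs (`presspulse_invalid`);
  schema problems in tabular inputs raise `presspulse_schema` errors naming
  the offending column.
- Euler integration at 20 sub-steps/day reproduces the logistic closed form
  to well under 2% over a 60-day horizon; tests assert that tolerance.
- Identical seeds give identical output across the whole pipeline
  (`run_pipeline()` writes byte-identical tables for equal config + seed).

## Problem sizes used by the test suite

Unit tests run on reduced layouts (2 treatments × 2 replicates, 60 days)
plus the full 18-mesocosm layout where record counts matter. The
simulation-based statistical checks use the full layout: 100 seeded
replications for the parameter-recovery property (enriched:control
displacement ratio within [1.5, 2.5] with resistance treatment-neutral at
α = .05) and 200 seeded replications for type-I calibration of the trend
test under a null configuration (equal pulse fractions, no dosing, no
hardening, no retention, no community response — a process with exactly no
trend). These sizes give stable proportions while keeping the suite fast.

## Known limitations

- The rescaling maps honour the published anchors but the original
  supplementary formulas may differ between anchors; swap them in via the
  injectable arguments if exact equivalence is required.
- With three cycles, trend estimates lean on a linear term; the package
  deliberately does not fit additive smooths.
- The permutation p-value refits the mixed model per permutation and is
  correspondingly slow at its default 5000 permutations.
- Mid vs strong enrichment contrasts in *generated* chlorophyll are nil by
  construction (see above).
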