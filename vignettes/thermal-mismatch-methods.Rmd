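---
title: "Methods: thermal performance, energetic balances, and interaction strength"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal performance, energetic balances, and interaction strength}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermomatch)
```

This vignette documents the models, assumptions, default parameters, and
numerical choices implemented in `thermomatch`. The package asks how warming
reshapes a consumer–resource interaction by comparing each organism's
energetic gain-to-loss balance across temperature, and it ships a seeded
synthetic-assay generator so every step can be exercised and tested without
laboratory data.

## 1. The thermal performance curve

All oxygen-based rates (net photosynthesis, respiration) are modelled with a
Sharpe–Schoolfield curve restricted to high-temperature inactivation:

$$
r(T) \;=\; r_{T_{ref}}\,
\exp\!\left[\frac{-E_a}{k}\left(\frac{1}{T} - \frac{1}{T_{ref}}\right)\right]
\Big/
\left(1 + \exp\!\left[\frac{E_h}{k}\left(\frac{1}{t_h} - \frac{1}{T}\right)\right]\right),
$$

with temperatures in kelvin inside the formula (the API always takes °C),
$k = 8.62\times10^{-5}\,$eV K$^{-1}$, activation energy $E_a$ (eV),
deactivation energy $E_h$ (eV, $E_h > E_a$), and $t_h$ (K) the temperature at
which inactivation halves the rate.

Two closed forms connect the raw parameters to the quantities usually
reported — the optimum $T_{opt}$ and the maximal rate (MRP):

$$
T_{opt} \;=\; \frac{E_h\, t_h}{E_h + k\, t_h \ln\!\left(E_h/E_a - 1\right)} .
$$

`topt_of()` implements this map and `th_from_topt()` its inverse, so a curve
can be reconstructed from a published $(E_a, T_{opt}, \mathrm{MRP}, E_h)$
summary: solve $t_h$ from $T_{opt}$, then scale $r_{T_{ref}}$ so the curve's
value at $T_{opt}$ equals MRP (`reconstruct_tpc()`). Both directions are
verified in the test suite against dense-grid argmax oracles on random
parameter sets.

```{r reconstruct, eval = FALSE}
pr <- thermal_preset("chlamydomonas")
photo <- reconstruct_tpc(pr$rate_presets$net_photosynthesis)
photo
predict_grid(photo, 14, 42, 0.1)[1:3, ]
```

## 2. Per-capita rates from assay tables

Raw assays are converted to per-capita rates with control correction:

* **Respirometry** (`oxygen_slope()`, `respiration_rate()`,
  `net_photosynthesis_rate()`): an OLS slope of oxygen concentration over a
  30-minute series, minus the mean slope of the *same-block* blank controls,
  divided by the number of organisms. Respiration is negated so that a
  positive number means oxygen consumed.
* **Grazing** (`ingestion_raw()`): cells removed per consumer per hour,
  corrected by the density change of consumer-free controls over the same
  interval.
* **Energy conversions**: 1 mg O$_2$ = 14.06 J (`oxygen_joule`); ingestion is
  converted with a per-cell energy content and an assimilation efficiency
  (`ingestion_to_energy()`), including a single mL→L factor. Unit tags on
  rate values guard against double conversion.

Table-level wrappers (`compute_oxygen_rates()`, `compute_ingestion_rates()`)
enforce the blocked design: a treatment replicate with no same-block controls
is an error, never silently pooled.

## 3. Fitting

`fit_tpc()` uses bounded Levenberg–Marquardt (`minpack.lm::nlsLM`) with 20
seeded random starts. Rates are internally rescaled to unit magnitude so the
optimizer sees the same problem whatever the unit system; candidates that
violate $E_h > E_a$ are rejected, and the minimal-SSE candidate wins.
Defaults, chosen to bracket all built-in summaries with margin:
$E_a \in [0.2, 3]$, $E_h \in [0.3, 25]$, $t_h \in [280, 330]$ K,
$T_{ref} = 20$ °C. Parameters landing on a bound are flagged rather than
hidden. Confidence intervals come from a case-resampling percentile bootstrap
(`bootstrap_cis()`), refitting each resample from the point estimate plus one
random restart.

Ingestion uses `fit_linear_rate()`: ordinary least squares on temperature,
refit with the slope constrained to zero (intercept = mean) when the slope is
not significant at `alpha`, mirroring how a temperature-independent ingestion
response is treated downstream.

## 4. Energetic balances and mismatch landmarks

`energetic_balance()` forms the pointwise gain/loss ratio on a fine grid
(default step 0.001 °C): net photosynthesis over respiration for an alga,
assimilated ingestion over respiration for the consumer. Points where the
loss is non-positive or the gain negative are masked, and the masked
fraction is recorded.

* **`find_tm()`** returns the *lowest-temperature local maximum* of the
  ratio, not the global grid argmax. Rationale: with a large $E_h$ the
  reconstructed loss curve collapses beyond its optimum, so the ratio can
  blow up at the hot grid edge; that edge spike is an artifact of the
  reconstruction domain, not a balance optimum. A purely monotone ratio has
  no interior peak, so the boundary argmax is returned with
  `boundary = TRUE`.
* **`find_tc()`** is the first downward crossing of ratio = 1, linearly
  interpolated between bracketing grid points; a curve that never reaches 1
  is flagged `always_deficit`.
* **`intra_tm()`** reports the interval(s) where the ratio declines with
  warming; **`inter_tm()`** compares consumer and resource derivatives on a
  common grid — region 1 where they trend in opposite directions, region 2
  where both decline.

Derivatives are taken on a smoothed curve. The smoother (window default
0.5 °C) is a *symmetric* moving average whose window shrinks near grid edges
and masked points: symmetric windows cannot invert a monotone trend, and the
gradual shrinkage avoids the derivative discontinuities a fixed window
creates where it stops fitting.

## 5. CREB and interaction strength

`creb()` is $\ln(I/R_c) - \ln(P/R_r)$, defined where both component ratios
are positive. `classify_trend()` labels the sign pattern of its smoothed
derivative (`declining`, `increasing`, `u_shaped`, `hump_shaped`, `flat`);
derivatives below `eps` count as zero, with `eps` defaulting to 1% of the
CREB range per °C so noise-scale wiggles do not fragment the pattern.
`predict_is_trend()` maps the label to an expected direction of per-capita
interaction strength under warming.

Measured interaction strength uses the Dynamic Index
(`dynamic_index()`): $\ln(N/D)/(y\,t)$ with $N$ the mean same-block
consumer-free density, $D$ the treatment density, $y$ consumers, $t$ hours.
`is_regression()` fits each pair's temperature slope and the
temperature-by-species interaction (Type II ANOVA via `car::Anova`);
`concordance()` compares the predicted direction with the fitted slope.

## 6. The synthetic-assay generator

The generator is first-class, tested code whose defaults *are* the study
conditions bundled in `thermal_preset()`:

* two algal resources assayed at 14–42 °C in 4 °C steps, a consumer pair at
  `c(14, 18, 22, 26, 30, 32, 34, 36)` °C; 3 replicates × 2 blocks per
  temperature; 30-minute oxygen series; 150-minute grazing assays with 5
  consumers per vial.
* rate presets carry the published $E_a$, $T_{opt}$, MRP, $E_h$ summaries
  verbatim; linear ingestion and interaction-strength components carry the
  published slopes with intercepts *pinned* at the published crossover
  temperatures (`pinned_ingestion_line()`), because absolute levels were not
  reported.
* the default noise model is multiplicative lognormal with CV 0.10 on rate
  signals, small additive control noise and per-block drift (2% of the peak
  signal), CV 0.05 on measured cell densities, and Gaussian residuals
  (sd 0.008) on interaction-strength records.

What the generator emulates: blocked vial layouts, control drift, probe
noise, density measurement error, optional consumer mortality. What it does
not: time-autocorrelated probe error, non-linear oxygen depletion at long
durations, resource depletion feedback on ingestion within an assay, or any
behavioural response of the consumer.

Two deliberate placeholders: the per-cell energy contents of the two algae
were not published, so presets carry documented synthetic constants; every
quantity the package reports is a ratio or an anchored line in which that
constant cancels.

## 7. End-to-end runs

`run_all(pipeline_config(...))` chains generation → rates → fits → balances
→ mismatch landmarks → CREB → interaction strength → concordance for both
pairs, derives every stage seed from one master seed, records them in a
manifest, and (optionally) writes CSV tables plus JSON reports.

```{r run, eval = FALSE}
res <- run_all(pipeline_config(seed = 1, grid_step = 0.01))
res$species$chlamydomonas$tm
res$pairs$daphnia_on_chlamydomonas$creb_trend
```

## Limitations

* Reconstruction from rounded summary parameters propagates the rounding:
  landmark temperatures inherit an uncertainty of a few tenths of a degree.
* The bootstrap refits from the point estimate plus one restart; pathological
  resamples can fail (a >20% failure rate triggers a warning).
* Trend classification is a grid heuristic with a tolerance, not an
  inferential test; borderline shapes near `eps` can flip label.
* The generator's noise magnitudes are plausible defaults, not fitted to
  replicate-level data, which were not available.
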