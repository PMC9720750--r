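---
title: "Models and methods behind amphitherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind amphitherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amphitherm)
```

# The scientific problem

Ectotherm metabolic rate rises with temperature and scales allometrically
with body mass.  The metabolic theory of ecology (MTE) treats the two
effects as separable,

$$ SMR = a \; M^{b} \; e^{-E/kT}, $$

with a canonical scaling exponent $b \approx 0.75$ and activation energy
$E \approx 0.65$ eV ($k$ is Boltzmann's constant, $8.617333\times10^{-5}$
eV K$^{-1}$; $T$ in Kelvin).  A growing body of evidence, however, shows
*interactive* mass–temperature effects: small (young) individuals are often
more thermally sensitive than large (old) ones, and populations from
different climates sit at different metabolic levels.  Quantifying that
interaction matters for predicting which individuals of a population are
hit first by warming.

`amphitherm` implements the full analysis chain used in flow-through
respirometry studies of aquatic amphipods that address this question:

1. raw oxygen traces → individual standard metabolic rates (SMR, J day⁻¹);
2. log–log mass-scaling regressions per site × temperature, with ANCOVA
   contrasts of slopes and intercepts against each site's lowest
   temperature;
3. a global ANCOVA $\ln SMR \sim \ln M \times T \times site$ with backward
   stepwise simplification and an LMG variance partition;
4. body-mass classes (mass quantiles 0.33/0.66/0.99) and Boltzmann–Arrhenius
   fits of $\ln(SMR/M)$ on $1/kT$ per class, separately for the *current*
   temperature range (site minimum → site maximum) and a *forecast* range
   (site maximum, +0.6 °C, +1.2 °C — the conservative RCP2.6 increments);
5. Q10 temperature coefficients relative to each site's minimum.

Because raw respirometry data of this kind are rarely deposited, the
package also contains a first-class synthetic-data generator that produces
populations, latent metabolic rates and raw traces with exactly the
statistical structure the estimators assume.  Every estimator is validated
by parameter recovery against that generator.

# Respirometry model

In a flow-through respirometer at steady state, the oxygen consumed by the
animal equals the difference between what flows in and what flows out:

$$ \dot V_{O_2} = (P_{O_2,\mathrm{blank}} - P_{O_2,\mathrm{specimen}})
   \times S_{O_2} \times F $$

with partial pressures in torr, flow $F$ in L h⁻¹ (default 0.006 L h⁻¹ for
a 6 mL chamber) and the solubility coefficient $S_{O_2}$ in
µmol L⁻¹ torr⁻¹.  SMR in J day⁻¹ is $\dot V_{O_2} \times 0.45 \times 24$
(oxyjoule equivalent 0.45 J per µmol O₂).

Two details are deliberate package choices:

* **Steady-state averaging.** Each 15-min phase is averaged over the final
  `window_frac` of the window (default the whole window) and flagged when
  the within-window OLS drift exceeds 0.05 torr min⁻¹.  A mean over a
  configurable late window is robust, reproducible and tunable; nothing is
  interpolated or smoothed by default (smoothing is exposed but off).
* **Solubility.** $S_{O_2}$ is computed from the Garcia–Gordon fit to the
  Benson–Krause saturation data plus a Weiss–Price vapour-pressure
  correction: $S_{O_2} = C_{sat}(T,S) / \left[0.20946\,(760 -
  p_{vap}(T,S))\right]$.  The implementation is checked against the
  published freshwater saturation table (<1 %) and against an independent
  re-implementation (6 significant digits).  Studies that used a
  commercial converter can bypass the fit by supplying an `so2` column.

Negative fluxes (blank below specimen) are physically impossible for a
respiring animal and indicate noise or a failed blank; they are **flagged,
never silently clipped**, and excluded from model fits only on request
(`drop_negative`).

# The generative model

The generator draws masses log-uniformly on 0.4–13.57 mg (the body-mass
span of a full amphipod population; identical distribution in every
site × temperature cell) and sets

$$ \ln SMR = a_{site} + b_0 \ln M
   - E(M)\left(\tfrac{1}{kT} - \tfrac{1}{kT_{ref}}\right) + \varepsilon,
   \qquad E(M) = e_0 + \gamma \ln (M/M_{geo}), $$

with $\varepsilon \sim N(0, \sigma_{\ln}^2)$.  Defaults: $b_0 = 0.75$,
$e_0 = 0.40$ eV at the geometric-mean mass, $\gamma = -0.12$ eV per unit
$\ln M$ (so thermal sensitivity declines continuously with mass — classes
are *estimated afterwards*, never baked into generation), $\sigma_{\ln} =
0.15$, 25 individuals per cell, reference temperature 18 °C (centering
$1/kT$ at the reference decorrelates slope and intercept estimates; it does
not change $E$).  Site intercepts put the high-latitude population highest
($a_{Quarantia} = -0.70$, $a_{Lesina} = -0.95$, $a_{Acquatina} = -1.00$ on
the ln J day⁻¹ scale), giving realistic absolute rates (≈1.4 J day⁻¹ for a
4 mg individual at 18 °C) and chamber depletions of roughly 5–40 torr at
the default flow.

An optional **homeostasis plateau** caps the latent ln SMR of individuals
above 5 mg at the two warm, low-latitude sites at its value at the site's
current maximum temperature, emulating the oxygen- or enzyme-limited
flattening of large individuals' thermal response beyond their locally
experienced range.  It is active in the default scenario and irrelevant to
all current-range fits (it only affects $T > T_{max}$).

Temperature levels per site are {local minimum, 18 °C, local maximum,
maximum + 0.6, maximum + 1.2}.  The preset values that are fixed by the
emulated study design are the 18 °C reference, Quarantia's forecast levels
25.6/26.2 °C (hence a 25 °C maximum), Lesina's 28/28.6/29.2 °C, Acquatina's
12 °C minimum, and salinities 20/22/21 PSU.  The remaining cells —
Quarantia minimum (9 °C), Lesina minimum (11 °C), Acquatina maximum
(27.4 °C) — are *synthetic defaults*, chosen to be climatically plausible
for the latitudinal gradient (colder winters at higher latitude, warmer
summers towards the south) and freely overridable via `site_presets()` or a
scenario YAML.  They are scenario parameters, not climate data.

Raw traces are generated by inverting the flux equation (blank at
air-saturation pressure, specimen depleted by $VO_2/(S_{O_2}F)$), with
optional exponential equilibration transients and AR(1) electrode noise.
Traces are emitted already at steady state by default because the emulated
protocol equilibrates chambers for 3 h before recording.

**What the generator does not emulate:** activity bursts, electrode drift
and calibration error, within-individual repeated measurement, chamber
micro-environment effects, and any curvature of the Arrhenius relationship
within a range (each simulated range has a single within-range $E(M)$).
Passing recovery tests therefore demonstrates estimator correctness under
the assumed model, not robustness to those artefacts.  A corollary: a
single $E(M)$ surface cannot simultaneously reproduce both the shallow
current-range energies and the steep forecast-range energies that real
populations can show; simulations targeting a specific class × range cell
set that cell's energy as their generative truth.

Mass-range presets for single-class simulations (`class_mass_range()`) are
0.8–3.0, 2.7–5.0 and 5.0–11.0 mg; their log-uniform means (≈1.66, 3.73,
7.61 mg) match the class means that quantile-cutting a full population
typically yields.

# Estimators and numerical choices

* **Scaling fits** are OLS on natural logs.  Exponents are base-invariant;
  intercepts are also reported as log10 for comparability with published
  scaling equations.  Cells need ≥3 records and non-degenerate mass
  variance, otherwise they error explicitly.
* **ANCOVA contrasts** across temperature levels come from a single
  interaction model per site with the lowest temperature as baseline, so
  each contrast equals the difference of the separate per-level fits
  exactly (dummy-coding identity, asserted in the tests).
* **The global model** uses temperature as continuous °C (one coefficient),
  while the per-site ANCOVA uses categorical levels (per-level contrasts).
  The mixed-model variant adds a random intercept via `lme4`/`lmerTest`
  when a grouping column is supplied; the default is fixed-effects OLS
  because a random structure should be an explicit, named choice by the
  analyst, not a guess.
* **Stepwise simplification** drops, iteratively, the least significant
  currently-droppable term with $p > 0.05$ by nested-model F-tests
  (`drop1` scope, which enforces marginality: an interaction can never
  orphan its main effects).  The elimination trace is recorded in the fit
  and in the run manifest.
* **Arrhenius fits** regress $\ln(SMR/M)$ on $1/kT$ with site intercepts;
  the site × slope interaction is F-tested and the slope pooled when
  $p \ge 0.05$, matching the usual "pooled E" reporting.  Negative or
  non-significant energies are reported signed, never clamped at zero.
  The Boltzmann constant used is recorded in every fit; fitted energies
  scale exactly proportionally to the constant, and p-values are invariant
  to it, so results computed with the occasionally-printed transposed
  value $8.167\times10^{-5}$ eV K⁻¹ can be reproduced via the
  `boltzmann_k` argument.
* **Mass classes** use type-7 (linear-interpolation) quantiles — R's
  default and a common convention; the algorithm is configurable.
  Individuals above the 0.99 quantile stay in the large class with an
  `above_q99` flag by default, because dropping the heaviest animals
  should be a visible analyst decision.
* **Q10** uses the standard definition
  $Q_{10} = (R_2/R_1)^{10/(T_2-T_1)}$, evaluated on geometric-mean rates
  per cell against the site minimum.  For rates generated with activation
  energy $E$ this equals $\exp(10E/(kT_1T_2))$, which the tests assert.
* **Temperature anomalies** subtract the same-calendar-day mean over the
  climatology window; February 29, present in only about a quarter of
  climatology years, is always referenced to the mean of the February 28
  and March 1 climatologies.
* **LMG variance partition.** The share of a predictor group is its
  average sequential $R^2$ increment over admissible orderings.  With
  marginality (the default) an interaction group may only enter after all
  its parent main effects — otherwise an interaction could be credited
  with variance belonging to its parents.  Two independent routes are
  implemented: explicit enumeration of admissible orderings, and a
  subset-weight formula whose weights are computed by a dynamic program
  counting admissible prefix orderings over downsets of the parenthood
  order.  They agree to 10⁻¹⁰ on random designs (asserted) and shares
  always sum to the full-model $R^2$.  Shares are reported both as percent
  of total response variance (summing to $R^2_{full}$) and as percent of
  explained variance (summing to 100), since published tables use either
  normalisation.
* **Forecast-range fits** include the current maximum as anchor (three
  levels): a two-point range would leave no residual degrees of freedom
  once site terms enter.

# Validation strategy and problem sizes

The test suite validates each stage against an oracle that does not share
its code path: hand-evaluated flux values; the Benson–Krause saturation
table and an independent solubility implementation; closed-form identities
of the generative model; dummy-coding identities; brute-force LMG
enumeration; exact F-test size under the null.

Parameter recovery is the package's standard benchmark
(`activation_energy_recovery()`): generate one body-mass class with a known
activation energy (25 individuals per site × level, $\sigma_{\ln} = 0.15$),
fit the Arrhenius regression, and average over 200 seeded replicates.  Under
these conditions the estimator is unbiased; the Monte-Carlo standard error
of the 200-replicate mean is ≈0.001 eV for current-range fits (temperature
span ≈ 13–16 °C) and ≈0.015–0.02 eV for forecast-range fits, whose span is
only 1.2 °C — recovering a slope over so narrow a lever arm is intrinsically
noisy, which is worth remembering when interpreting real forecast-range
estimates too.  Null-size and power checks for the heterogeneity ANCOVA use
1000 and 200 replicates respectively; sizes were chosen so the whole suite
runs in a few minutes on one core while keeping Monte-Carlo error well
below the asserted margins.

# A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(mode = "synthetic", out_dir = "run1", seed = 1)
res <- run_pipeline(cfg, verbose = TRUE)
res$arrhenius$current_small
res$variance_partition
```

See the README for the numbers a default run prints.

# Known limitations

* The generator's lognormal noise conflates biological scatter and
  measurement error; the two are not separately identifiable from single
  measurements per individual, and no repeated-measures structure is
  simulated.
* Closed-chamber (intermittent) respirometry, electrode-drift calibration
  models and activity correction are out of scope.
* Nonlinear thermal-performance curves (e.g. Sharpe–Schoolfield) are not
  fitted; within each analysed range the model is log-linear in $1/kT$.
* The stepwise procedure tests fixed effects only; random-effect structure
  selection is left to the analyst.
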