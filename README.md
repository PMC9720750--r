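# amphitherm

Joint mass–temperature analysis of standard metabolic rate (SMR) in
aquatic amphipods, from raw flow-through respirometry traces to activation
energies, scaling exponents, Q10 tables and variance partitioning — with a
seeded synthetic-data generator so the whole pipeline can be validated
end to end without laboratory data.

## Who this is for

Ecophysiologists measuring oxygen consumption of small aquatic ectotherms
in flow-through respirometers, and anyone fitting metabolic-theory models
in which the thermal sensitivity of metabolism may depend on body mass and
population of origin.

## The models

SMR is treated as a power law in dry body mass `M` with a
Boltzmann–Arrhenius temperature factor:

```
SMR = a · M^b · exp(−E/kT)
```

* Oxygen flux from a chamber: `VO2 = (PO2_blank − PO2_specimen) · SO2 · F`
  (torr × µmol L⁻¹ torr⁻¹ × L h⁻¹ → µmol O₂ h⁻¹), converted to J day⁻¹ with
  the 0.45 J (µmol O₂)⁻¹ oxyjoule equivalent × 24 h.  `SO2` comes from the
  Garcia–Gordon saturation fit with vapour-pressure correction (or a
  user-supplied column).
* Mass scaling: OLS of `ln SMR` on `ln M` per site × temperature, with
  ANCOVA contrasts of every level against the site's lowest temperature.
* Global model: `ln SMR ~ ln M × T × site`, simplified by backward
  nested-F elimination (α = 0.05), optional random intercept via `lme4`;
  explained variance partitioned among predictor groups by the LMG metric
  (sequential R² averaged over marginality-respecting orderings).
* Thermal response by body-mass class (mass quantiles 0.33/0.66/0.99):
  activation energy `E` = −slope of `ln(SMR/M)` against `1/kT`, fitted
  separately over each site's current annual temperature range and a
  forecast range (current maximum, +0.6 °C, +1.2 °C), with site × slope
  pooling tests; Q10 relative to each site's minimum temperature.

## Worked example

```r
library(amphitherm)

cfg <- pipeline_config(mode = "synthetic", out_dir = "run1", seed = 1)
res <- run_pipeline(cfg, verbose = TRUE)

res$arrhenius$current_small
#> Arrhenius fit (small class, current range): E = 0.612 eV (SE 0.026),
#>   pooled across sites, n = 74
res$arrhenius$current_large
#> Arrhenius fit (large class, current range): E = 0.278 eV (SE 0.023),
#>   pooled across sites, n = 84

res$variance_partition
#> LMG variance partition (exact_permutations), R2 = 0.9619
#>   lnM     T  site lnM:T
#> 72.27 19.47  1.96  2.50

head(res$scaling_equations[, c("site", "temp_level_c", "exponent_b")], 3)
#>   site      temp_level_c exponent_b
#> 1 Acquatina         12        0.940
#> 2 Acquatina         18        0.750
#> 3 Acquatina         27.4      0.612
```

The run simulates 375 individuals (3 sites × 5 temperature levels × 25),
renders and re-reduces their raw traces, and writes
`metabolic_records.csv`, the model tables (`table2_global_model.csv`,
`table3_contrasts.csv`, `table4_equations.csv`,
`table5_current_arrhenius.csv`, `table6_forecast_arrhenius.csv`),
`q10_table.csv`, `variance_partition.csv`, a QC summary and a
`run_manifest.json` recording the seed, constants and the stepwise
elimination trace.  Reading the numbers: small individuals are the most
thermally sensitive (E ≈ 0.6 eV vs ≈ 0.28 eV for large ones), scaling
exponents fall as temperature rises (0.94 → 0.61 at the lowest-latitude
site), and mass dominates the explained SMR variance, with a small but
retained negative mass × temperature interaction (`ln_m:temp_c` survives
elimination).  Identical configuration and seed reproduce every output
byte for byte.

The same pipeline runs on real data with
`pipeline_config(mode = "from_csv", traces_csv = ..., individuals_csv =
...)`; a small demo fixture ships in `inst/extdata/` and a thin CLI
wrapper in `inst/scripts/run_pipeline.R`.

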