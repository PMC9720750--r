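# Regenerates the small synthetic demo fixture shipped in inst/extdata.
# Run from the package root after installing the package.
library(amphitherm)

sites <- site_presets()[1:2, ]
params <- generative_params(n_per_cell = 3, sigma_ln = 0.15, seed = 2024,
                            plateau = NULL)
cfg <- chamber_config(dt_s = 60, noise_sd_torr = 0.2)
ds <- simulate_dataset(params, sites, range = "current",
                       chamber_cfg = cfg, seed = 2024)
ds$traces$po2_torr <- round(ds$traces$po2_torr, 4)
ds$traces$time_s <- as.integer(ds$traces$time_s)

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
readr::write_csv(ds$traces, "inst/extdata/synthetic_demo_traces.csv")
readr::write_csv(ds$individuals, "inst/extdata/synthetic_demo_individuals.csv")
readr::write_csv(
  ds$latent[, c("individual_id", "latent_smr", "smr_j_per_day")],
  "inst/extdata/synthetic_demo_truth.csv"
)
cat("fixture rows:", nrow(ds$traces), "\n")
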