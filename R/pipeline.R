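#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis.  In `"synthetic"` mode
#' the raw data are generated by the synthetic module; in `"from_csv"` mode
#' they are read from `traces_csv` / `individuals_csv`.
#'
#' @param mode `"synthetic"` or `"from_csv"`.
#' @param out_dir Output directory (created if needed).
#' @param traces_csv,individuals_csv Input paths (`from_csv` mode).
#' @param params A [generative_params()] (`synthetic` mode).
#' @param sites A [site_presets()]-shaped table.
#' @param chamber_cfg A [chamber_config()] (`synthetic` mode).
#' @param window_cfg A [steady_state_config()].
#' @param alpha Significance threshold used by every test (default 0.05).
#' @param boltzmann_k Boltzmann constant in eV K^-1.
#' @param quantiles Mass-class quantile cut points.
#' @param random_group Optional random-intercept grouping column for the
#'   global ANCOVA.
#' @param drop_negative Drop records with negative oxygen flux.
#' @param seed Root seed; all stage randomness derives from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "from_csv"),
                            out_dir = tempfile("amphitherm_run_"),
                            traces_csv = NULL, individuals_csv = NULL,
                            params = generative_params(),
                            sites = site_presets(),
                            chamber_cfg = chamber_config(),
                            window_cfg = steady_state_config(),
                            alpha = 0.05,
                            boltzmann_k = boltzmann_k_ev(),
                            quantiles = c(0.33, 0.66, 0.99),
                            random_group = NULL,
                            drop_negative = FALSE,
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1)
  if (mode == "from_csv") {
    if (is.null(traces_csv) || is.null(individuals_csv)) {
      stop("`from_csv` mode needs `traces_csv` and `individuals_csv`",
           call. = FALSE)
    }
    for (f in c(traces_csv, individuals_csv)) {
      if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
    }
  }
  structure(
    list(mode = mode, out_dir = out_dir, traces_csv = traces_csv,
         individuals_csv = individuals_csv, params = params, sites = sites,
         chamber_cfg = chamber_cfg, window_cfg = window_cfg, alpha = alpha,
         boltzmann_k = boltzmann_k, quantiles = quantiles,
         random_group = random_group, drop_negative = drop_negative,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a YAML scenario file
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments;
#' `params` and `sites` sub-maps override individual fields of the default
#' generative parameters and site presets.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  params <- do.call(generative_params, y$params %||% list())
  sites <- site_presets()
  if (!is.null(y$sites)) {
    for (s in y$sites) {
      i <- match(s$site, sites$site)
      if (is.na(i)) {
        sites <- dplyr::bind_rows(sites, tibble::as_tibble(s))
      } else {
        for (f in setdiff(names(s), "site")) sites[[f]][i] <- s[[f]]
      }
    }
  }
  args <- y[setdiff(names(y), c("params", "sites"))]
  do.call(pipeline_config, c(args, list(params = params, sites = sites)))
}

write_csv_out <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (synthetic generation or CSV
#' input), respirometry reduction to metabolic records, the global ANCOVA
#' with stepwise simplification and LMG variance partition, per-site
#' scaling fits and temperature-level ANCOVA contrasts, body-mass classes
#' with current- and forecast-range Arrhenius fits, and Q10 tables.  All
#' result tables are written as CSV to `config$out_dir`, along with a
#' machine-readable `run_manifest.json` recording the seed, constants and
#' elimination traces.  Outputs are byte-identical under identical
#' configuration and seed.
#'
#' @param config A [pipeline_config()] or path to a YAML scenario.
#' @param verbose Log stage progress to stderr.
#' @return (Invisibly) a list with the in-memory results: `records`,
#'   `global_full`, `global_simplified`, `variance_partition`,
#'   `scaling_equations`, `ancova_contrasts`, `arrhenius`, `q10`,
#'   `site_anova`, `manifest`, and the vector of written `files`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  if (is.character(config)) config <- read_scenario(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[amphitherm] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  ## stage 1: acquire raw data -------------------------------------------
  if (config$mode == "synthetic") {
    say("simulating raw dataset (seed ", config$seed, ")")
    ds <- simulate_dataset(config$params, config$sites,
                           chamber_cfg = config$chamber_cfg,
                           seed = config$seed)
    traces <- ds$traces
    individuals <- ds$individuals
    files <- c(files,
               write_csv_out(traces, config$out_dir, "traces.csv"),
               write_csv_out(individuals, config$out_dir,
                             "individuals.csv"))
  } else {
    say("reading raw CSV inputs")
    traces <- read_traces_csv(config$traces_csv)
    individuals <- read_individuals_csv(config$individuals_csv)
  }

  ## stage 2: respirometry reduction -------------------------------------
  say("reducing traces to metabolic records")
  records <- build_metabolic_table(traces, individuals, config$window_cfg,
                                   drop_negative = config$drop_negative)
  qc <- attr(records, "qc")
  files <- c(files,
             write_csv_out(records, config$out_dir,
                           "metabolic_records.csv"))
  jsonlite::write_json(qc, file.path(config$out_dir, "qc_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, file.path(config$out_dir, "qc_summary.json"))

  fit_records <- records
  if (!config$drop_negative) {
    # model fits need positive rates; QC-flagged non-positive records are
    # excluded from fitting but retained in the record table
    fit_records <- records[records$smr_j_per_day > 0, ]
  }

  ## stage 3: global model + variance partition --------------------------
  say("fitting global ANCOVA")
  global_full <- fit_global_ancova(fit_records,
                                   random_group = config$random_group)
  global_simpl <- stepwise_simplify(global_full, alpha = config$alpha)
  files <- c(files,
             write_csv_out(global_simpl$coefficients, config$out_dir,
                           "table2_global_model.csv"))
  vp <- smr_variance_partition(fit_records)
  vp_tab <- tibble::tibble(
    predictor_group = names(vp$shares),
    share_pct_total_variance = vp$shares_pct_total,
    share_pct_explained_variance = vp$shares_pct_explained,
    r2_full_pct = 100 * vp$r2_full
  )
  files <- c(files,
             write_csv_out(vp_tab, config$out_dir,
                           "variance_partition.csv"))

  ## stage 4: per-site scaling and temperature contrasts -----------------
  say("fitting per-cell scaling relationships")
  equations <- scaling_equation_table(fit_records)
  contrasts <- purrr::map_dfr(unique(fit_records$site),
                              function(s)
                                compare_across_temperatures(fit_records, s))
  files <- c(files,
             write_csv_out(contrasts, config$out_dir,
                           "table3_contrasts.csv"),
             write_csv_out(equations, config$out_dir,
                           "table4_equations.csv"))

  ## stage 5: mass classes, Arrhenius fits, Q10 --------------------------
  say("fitting Arrhenius models by mass class")
  classed <- assign_mass_classes(fit_records, config$quantiles)
  arr <- list()
  for (rng in c("current", "forecast")) {
    for (cl in levels(classed$mass_class)) {
      key <- paste(rng, cl, sep = "_")
      arr[[key]] <- tryCatch(
        fit_arrhenius(classed, mass_class = cl, temp_range = rng,
                      sites = config$sites,
                      boltzmann_k = config$boltzmann_k,
                      alpha = config$alpha),
        error = function(e) NULL
      )
    }
  }
  arr_tab <- purrr::imap_dfr(arr, function(f, key) {
    if (is.null(f)) return(NULL)
    tibble::tibble(
      temp_range = strsplit(key, "_")[[1]][1],
      mass_class = strsplit(key, "_")[[1]][2],
      activation_energy_ev = f$activation_energy_ev, se_e = f$se_e,
      pooled = f$pooled,
      site_slope_f = f$site_slope_test$f %||% NA_real_,
      site_slope_p = f$site_slope_test$p %||% NA_real_,
      n = f$n, r2 = f$r2,
      boltzmann_k_ev_per_k = f$boltzmann_k_ev_per_k
    )
  })
  files <- c(files,
             write_csv_out(arr_tab[arr_tab$temp_range == "current", ],
                           config$out_dir, "table5_current_arrhenius.csv"),
             write_csv_out(arr_tab[arr_tab$temp_range == "forecast", ],
                           config$out_dir,
                           "table6_forecast_arrhenius.csv"))
  q10 <- q10_table(classed)
  files <- c(files, write_csv_out(q10, config$out_dir, "q10_table.csv"))

  ## trivial site comparisons --------------------------------------------
  site_anova <- list(
    mass = anova_oneway(fit_records$dry_mass_mg, fit_records$site),
    smr = anova_oneway(fit_records$smr_j_per_day, fit_records$site)
  )

  ## manifest -------------------------------------------------------------
  manifest <- list(
    package = "amphitherm",
    version = as.character(utils::packageVersion("amphitherm")),
    mode = config$mode,
    seed = config$seed,
    alpha = config$alpha,
    boltzmann_k_ev_per_k = config$boltzmann_k,
    oxyjoule_j_per_umol = oxyjoule_equivalent(),
    quantiles = config$quantiles,
    n_records = nrow(records),
    qc = qc,
    elimination_trace = as.list(global_simpl$elimination_trace),
    retained_terms = global_simpl$terms,
    r2_global = global_simpl$r2_total,
    site_anova = list(mass_f = site_anova$mass$f, mass_p = site_anova$mass$p,
                      smr_f = site_anova$smr$f, smr_p = site_anova$smr$p)
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, file.path(config$out_dir, "run_manifest.json"))
  say("done: ", length(files), " files in ", config$out_dir)

  invisible(list(records = records, global_full = global_full,
                 global_simplified = global_simpl,
                 variance_partition = vp,
                 scaling_equations = equations,
                 ancova_contrasts = contrasts,
                 arrhenius = arr, q10 = q10, site_anova = site_anova,
                 manifest = manifest, files = files))
}
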