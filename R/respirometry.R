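#' Configuration of the steady-state averaging window
#'
#' Controls how the final analysis window of each 15-minute respirometry
#' phase is averaged, and the linear-drift threshold beyond which a trace is
#' flagged as not having reached steady state.
#'
#' @param window_s Nominal phase duration in seconds (default 900 s = 15 min).
#' @param window_frac Fraction of the window, counted from its end, over
#'   which the mean partial pressure is taken (default 1, i.e. the whole
#'   window).
#' @param min_points Minimum number of samples required inside the analysis
#'   window.
#' @param max_drift_torr_per_min Absolute OLS slope of PO2 against time
#'   (torr min^-1) above which the window is flagged as drifting.
#' @return A list of class `steady_state_config`.
#' @export
steady_state_config <- function(window_s = 900, window_frac = 1,
                                min_points = 10,
                                max_drift_torr_per_min = 0.05) {
  stopifnot(window_s > 0, window_frac > 0, window_frac <= 1,
            min_points >= 2, max_drift_torr_per_min > 0)
  structure(
    list(window_s = window_s, window_frac = window_frac,
         min_points = min_points,
         max_drift_torr_per_min = max_drift_torr_per_min),
    class = "steady_state_config"
  )
}

#' Mean steady-state oxygen partial pressure of a trace
#'
#' Averages the oxygen partial pressure over the final portion of a
#' respirometry phase and checks that the signal is not drifting.  The
#' estimate is the arithmetic mean of `po2_torr` over the last
#' `window_frac` of the window; a within-window OLS slope larger in absolute
#' value than `max_drift_torr_per_min` raises a QC flag (the value is still
#' returned).
#'
#' @param trace A data frame with numeric columns `time_s` (strictly
#'   increasing) and `po2_torr` (non-negative) for a single chamber/phase.
#' @param window_cfg A [steady_state_config()].
#' @return A list of class `steady_state` with elements `mean_po2_torr`,
#'   `drift_torr_per_min`, `drift_flag`, `n_points`.
#' @examples
#' tr <- data.frame(time_s = seq(0, 900, by = 10), po2_torr = 150)
#' average_steady_state(tr)$mean_po2_torr
#' @export
average_steady_state <- function(trace, window_cfg = steady_state_config()) {
  stopifnot(inherits(window_cfg, "steady_state_config"))
  if (!all(c("time_s", "po2_torr") %in% names(trace))) {
    stop("`trace` must contain `time_s` and `po2_torr` columns",
         call. = FALSE)
  }
  t <- trace$time_s
  p <- trace$po2_torr
  if (any(diff(t) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  if (any(p < 0)) stop("`po2_torr` must be non-negative", call. = FALSE)
  t_end <- max(t)
  t_start <- t_end - window_cfg$window_frac * window_cfg$window_s
  keep <- t >= t_start
  if (sum(keep) < window_cfg$min_points) {
    stop(sprintf("analysis window holds %d samples; at least %d required",
                 sum(keep), window_cfg$min_points), call. = FALSE)
  }
  tw <- t[keep]
  pw <- p[keep]
  slope_s <- coef(lm(pw ~ tw))[["tw"]]       # torr per second
  drift <- slope_s * 60
  structure(
    list(mean_po2_torr = mean(pw),
         drift_torr_per_min = drift,
         drift_flag = abs(drift) > window_cfg$max_drift_torr_per_min,
         n_points = sum(keep)),
    class = "steady_state"
  )
}

#' Oxygen consumption rate from a blank/specimen pair
#'
#' The oxygen flux out of a flow-through chamber is the partial-pressure
#' difference between the blank outflow and the specimen outflow, scaled by
#' the oxygen solubility coefficient and the water flow rate:
#'
#' \deqn{\dot{V}_{O_2} = (P_{O_2,blank} - P_{O_2,specimen}) \times
#'   S_{O_2} \times F}
#'
#' in umol O2 h^-1, with pressures in torr, `so2` in umol L^-1 torr^-1 and
#' `F` in L h^-1.  A negative result (specimen apparently releasing oxygen)
#' is returned as is; callers flag rather than clip it.
#'
#' @param po2_blank_torr Mean PO2 of the blank phase (torr).
#' @param po2_specimen_torr Mean PO2 of the specimen phase (torr).
#' @param so2 Oxygen solubility coefficient (umol L^-1 torr^-1), positive.
#' @param flow_l_per_h Water flow rate through the chamber (L h^-1), positive.
#' @return Oxygen consumption in umol O2 h^-1.
#' @examples
#' compute_vo2(150, 140, 1.5, 0.006)  # 0.09 umol / h
#' @export
compute_vo2 <- function(po2_blank_torr, po2_specimen_torr, so2,
                        flow_l_per_h) {
  if (any(!is.finite(po2_blank_torr)) || any(!is.finite(po2_specimen_torr)) ||
      any(!is.finite(so2)) || any(!is.finite(flow_l_per_h))) {
    stop("all inputs must be finite", call. = FALSE)
  }
  if (any(so2 <= 0)) stop("`so2` must be positive", call. = FALSE)
  if (any(flow_l_per_h <= 0)) {
    stop("`flow_l_per_h` must be positive", call. = FALSE)
  }
  (po2_blank_torr - po2_specimen_torr) * so2 * flow_l_per_h
}

#' Convert an oxygen consumption rate to a daily metabolic rate
#'
#' Applies the oxyjoule equivalent (0.45 J per umol O2) and scales from an
#' hourly to a daily rate, i.e. `SMR = vo2 * 0.45 * 24` J day^-1.
#'
#' @param vo2_umol_per_h Oxygen consumption in umol O2 h^-1.
#' @return Standard metabolic rate in J day^-1.
#' @examples
#' vo2_to_smr(1)     # 10.8 J / day
#' @export
vo2_to_smr <- function(vo2_umol_per_h) {
  if (any(!is.finite(vo2_umol_per_h))) {
    stop("`vo2_umol_per_h` must be finite", call. = FALSE)
  }
  vo2_umol_per_h * oxyjoule_equivalent() * 24
}

#' Build the analysis-ready metabolic table from traces and individuals
#'
#' Pairs each specimen trace with the blank recorded for the same chamber
#' and run, averages both phases over the configured steady-state window,
#' applies the flux equation and unit conversions, and joins the result to
#' the individual metadata.  Quality-control flags (negative oxygen flux,
#' drifting windows) are carried as columns; nothing is silently dropped
#' unless `drop_negative = TRUE`.
#'
#' @param traces Long-format trace table with columns `chamber_id`,
#'   `run_id`, `phase` (`"specimen"`/`"blank"`), `time_s`, `po2_torr`,
#'   `flow_l_per_h`, `temp_c`, `salinity_psu`, and optionally `so2` to
#'   bypass [compute_solubility()].
#' @param individuals Individual metadata with columns `individual_id`,
#'   `site`, `chamber_id`, `run_id`, `temp_level_c`, `dry_mass_mg` and
#'   optionally `length_mm`.
#' @param window_cfg A [steady_state_config()].
#' @param drop_negative Drop records whose oxygen flux is negative instead
#'   of keeping them flagged.
#' @return A tibble of metabolic records: one row per individual with
#'   `vo2_umol_per_h`, `smr_j_per_day`, `mass_specific_smr` and QC columns
#'   `qc_negative_vo2`, `qc_drift_specimen`, `qc_drift_blank`.  A `qc`
#'   attribute summarises flag counts.
#' @export
build_metabolic_table <- function(traces, individuals,
                                  window_cfg = steady_state_config(),
                                  drop_negative = FALSE) {
  needed <- c("chamber_id", "run_id", "phase", "time_s", "po2_torr",
              "flow_l_per_h", "temp_c", "salinity_psu")
  miss <- setdiff(needed, names(traces))
  if (length(miss)) {
    stop("`traces` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  needed_ind <- c("individual_id", "site", "chamber_id", "run_id",
                  "temp_level_c", "dry_mass_mg")
  miss <- setdiff(needed_ind, names(individuals))
  if (length(miss)) {
    stop("`individuals` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(individuals$dry_mass_mg) |
            individuals$dry_mass_mg <= 0)) {
    stop("every individual needs a positive `dry_mass_mg`", call. = FALSE)
  }

  summarise_phase <- function(df) {
    ss <- average_steady_state(df[order(df$time_s), ], window_cfg)
    tibble::tibble(
      po2_torr = ss$mean_po2_torr,
      drift_flag = ss$drift_flag,
      flow_l_per_h = df$flow_l_per_h[1],
      temp_c = df$temp_c[1],
      salinity_psu = df$salinity_psu[1],
      so2_given = if ("so2" %in% names(df)) df$so2[1] else NA_real_
    )
  }
  phase_means <- traces |>
    dplyr::group_by(.data$chamber_id, .data$run_id, .data$phase) |>
    dplyr::group_modify(~ summarise_phase(.x)) |>
    dplyr::ungroup()

  spec <- dplyr::filter(phase_means, .data$phase == "specimen")
  blank <- dplyr::filter(phase_means, .data$phase == "blank") |>
    dplyr::select("chamber_id", "run_id",
                  po2_blank_torr = "po2_torr", qc_drift_blank = "drift_flag")

  paired <- dplyr::left_join(spec, blank, by = c("chamber_id", "run_id"))
  orphans <- paired[is.na(paired$po2_blank_torr), ]
  if (nrow(orphans)) {
    stop("specimen traces without a matching blank: ",
         paste(sprintf("%s/%s", orphans$chamber_id, orphans$run_id),
               collapse = ", "), call. = FALSE)
  }

  so2 <- ifelse(is.na(paired$so2_given),
                compute_solubility(paired$temp_c, paired$salinity_psu)$so2,
                paired$so2_given)
  vo2 <- compute_vo2(paired$po2_blank_torr, paired$po2_torr, so2,
                     paired$flow_l_per_h)

  measured <- paired |>
    dplyr::transmute(
      chamber_id = .data$chamber_id, run_id = .data$run_id,
      po2_specimen_torr = .data$po2_torr,
      po2_blank_torr = .data$po2_blank_torr,
      so2 = so2, flow_l_per_h = .data$flow_l_per_h,
      vo2_umol_per_h = vo2,
      smr_j_per_day = vo2_to_smr(vo2),
      qc_drift_specimen = .data$drift_flag,
      qc_drift_blank = .data$qc_drift_blank,
      qc_negative_vo2 = vo2 < 0
    )

  unmatched_ind <- dplyr::anti_join(individuals, measured,
                                    by = c("chamber_id", "run_id"))
  if (nrow(unmatched_ind)) {
    stop("individuals without traces: ",
         paste(unmatched_ind$individual_id, collapse = ", "), call. = FALSE)
  }

  records <- individuals |>
    dplyr::inner_join(measured, by = c("chamber_id", "run_id")) |>
    dplyr::mutate(mass_specific_smr = .data$smr_j_per_day / .data$dry_mass_mg)

  if (drop_negative) {
    records <- dplyr::filter(records, !.data$qc_negative_vo2)
  }
  qc <- list(
    n_records = nrow(records),
    n_negative_vo2 = sum(records$qc_negative_vo2),
    n_drift_specimen = sum(records$qc_drift_specimen),
    n_drift_blank = sum(records$qc_drift_blank),
    dropped_negative = drop_negative
  )
  attr(records, "qc") <- qc
  records
}

#' Read trace and individual tables from CSV
#'
#' Thin readers for the two input schemas consumed by
#' [build_metabolic_table()]: UTF-8 CSV with a header row.
#'
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_traces_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_traces_csv
#' @export
read_individuals_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
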