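#' Inverse thermal energy 1/kT
#'
#' Converts a Celsius temperature to the Boltzmann-Arrhenius predictor
#' `1/(k * T_Kelvin)` in eV^-1.  The slope of ln(rate) against this
#' quantity is minus the activation energy in eV.
#'
#' @param temp_c Temperature in degrees C, above absolute zero.
#' @param boltzmann_k Boltzmann constant in eV K^-1 (default the physical
#'   constant; see [boltzmann_k_ev()]).
#' @return 1/kT in eV^-1 (vectorised).
#' @examples
#' inverse_thermal_energy(18)
#' @export
inverse_thermal_energy <- function(temp_c, boltzmann_k = boltzmann_k_ev()) {
  if (any(!is.finite(temp_c)) || any(temp_c <= -.ZERO_C_K)) {
    stop("`temp_c` must be finite and above absolute zero", call. = FALSE)
  }
  stopifnot(boltzmann_k > 0)
  1 / (boltzmann_k * (temp_c + .ZERO_C_K))
}

#' Assign individuals to body-mass classes by mass quantiles
#'
#' Cuts the pooled mass distribution at its 0.33 and 0.66 quantiles into
#' small / medium / large classes; the 0.99 quantile marks the nominal upper
#' bound of the large class.  Individuals above it are by default kept in
#' the large class with a QC flag (`above_q99`), or dropped if
#' `drop_above_top = TRUE`.
#'
#' @param records A data frame with a `dry_mass_mg` column.
#' @param quantiles The three probabilities (lower cut, upper cut, top
#'   bound), default `c(0.33, 0.66, 0.99)`.
#' @param type Quantile algorithm passed to [stats::quantile()] (default 7,
#'   linear interpolation).
#' @param drop_above_top Drop individuals above the top-bound quantile
#'   instead of flagging them.
#' @return `records` with added columns `mass_class` (ordered factor
#'   small < medium < large) and `above_q99`, plus attributes
#'   `class_bounds_mg` and `class_summary` (per-class n, mean and sd mass).
#' @examples
#' df <- data.frame(dry_mass_mg = 1:9)
#' table(assign_mass_classes(df)$mass_class)
#' @export
assign_mass_classes <- function(records, quantiles = c(0.33, 0.66, 0.99),
                                type = 7, drop_above_top = FALSE) {
  stopifnot("dry_mass_mg" %in% names(records), length(quantiles) == 3,
            all(diff(quantiles) > 0))
  m <- records$dry_mass_mg
  if (length(unique(m)) < 3) {
    stop("mass distribution is degenerate: need >= 3 distinct masses",
         call. = FALSE)
  }
  q <- quantile(m, quantiles, type = type, names = FALSE)
  cls <- cut(m, breaks = c(-Inf, q[1], q[2], Inf),
             labels = c("small", "medium", "large"), right = TRUE)
  out <- records
  out$mass_class <- factor(cls, levels = c("small", "medium", "large"),
                           ordered = TRUE)
  out$above_q99 <- m > q[3]
  if (drop_above_top) out <- out[!out$above_q99, ]
  summ <- out |>
    dplyr::group_by(.data$mass_class) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_mass_mg = mean(.data$dry_mass_mg),
                     sd_mass_mg = sd(.data$dry_mass_mg),
                     .groups = "drop")
  attr(out, "class_bounds_mg") <- setNames(q, paste0("q", quantiles))
  attr(out, "class_summary") <- summ
  out
}

#' Boltzmann-Arrhenius fit of mass-specific SMR
#'
#' Regresses `ln(mass-specific SMR)` on inverse thermal energy `1/kT`, with
#' collection-site intercepts when more than one site is present.  The
#' site x slope interaction is tested by a nested-model F-test; when it is
#' not significant at `alpha` the slope is pooled across sites (the usual
#' reporting convention) and the interaction dropped, otherwise per-site
#' slopes are kept and reported.  The activation energy is minus the
#' (pooled) slope.
#'
#' @param records Metabolic records with columns `mass_specific_smr`,
#'   `temp_level_c`, `site`.  Subset to one body-mass class and one
#'   temperature range before calling, or use the `mass_class` /
#'   `temp_range` filters below.
#' @param mass_class Optional: keep only this `mass_class` value (requires a
#'   `mass_class` column, see [assign_mass_classes()]).
#' @param temp_range Optional: `"current"` or `"forecast"`; keeps only the
#'   temperature levels in that range per site (requires `sites`).
#' @param sites Site table used to resolve `temp_range` (default
#'   [site_presets()]).
#' @param boltzmann_k Boltzmann constant in eV K^-1.
#' @param alpha Significance level of the site x slope test (default 0.05).
#' @return A list of class `arrhenius_fit`: `activation_energy_ev`, `se_e`,
#'   `site_intercepts_ln`, `site_slopes_ev` (per-site energies when not
#'   pooled), `site_slope_test` (F, df, p or `NULL` for a single site),
#'   `pooled`, `n`, `r2`, `boltzmann_k_ev_per_k`, `mass_class`,
#'   `temp_range`, and the underlying `model`.
#' @examples
#' p <- generative_params(sigma_ln = 0, e_mass_slope = 0, e0 = 0.65)
#' r <- simulate_records(p, seed = 1)
#' fit_arrhenius(r)$activation_energy_ev
#' @export
fit_arrhenius <- function(records, mass_class = NULL, temp_range = NULL,
                          sites = site_presets(),
                          boltzmann_k = boltzmann_k_ev(), alpha = 0.05) {
  df <- as.data.frame(records)
  if (!is.null(mass_class)) {
    stopifnot("mass_class" %in% names(df))
    df <- df[df$mass_class == mass_class, ]
  }
  if (!is.null(temp_range)) {
    temp_range <- match.arg(temp_range, c("current", "forecast"))
    keep <- rep(FALSE, nrow(df))
    for (i in seq_len(nrow(sites))) {
      lv <- temp_levels(sites[i, ], temp_range)
      keep <- keep | (df$site == sites$site[i] &
                        sapply(df$temp_level_c,
                               function(t) any(abs(t - lv) < 1e-8)))
    }
    df <- df[keep, ]
  }
  stopifnot(all(c("mass_specific_smr", "temp_level_c", "site") %in%
                  names(df)))
  if (any(df$mass_specific_smr <= 0)) {
    stop("`mass_specific_smr` must be positive for the log transform",
         call. = FALSE)
  }
  df$inv_kt <- inverse_thermal_energy(df$temp_level_c, boltzmann_k)
  df$ln_msmr <- log(df$mass_specific_smr)
  for (s in unique(df$site)) {
    if (length(unique(df$temp_level_c[df$site == s])) < 2) {
      stop("site ", s, " has fewer than 2 temperature levels in range",
           call. = FALSE)
    }
  }
  multi_site <- length(unique(df$site)) > 1
  if (multi_site) {
    df$site <- factor(df$site)
    full <- lm(ln_msmr ~ inv_kt * site, data = df)
    add <- lm(ln_msmr ~ inv_kt + site, data = df)
    cmp <- anova(add, full)
    test <- list(f = cmp$F[2], df1 = cmp$Df[2], df2 = cmp$Res.Df[2],
                 p = cmp$`Pr(>F)`[2])
    pooled <- test$p >= alpha
    model <- if (pooled) add else full
  } else {
    model <- lm(ln_msmr ~ inv_kt, data = df)
    test <- NULL
    pooled <- TRUE
  }
  co <- summary(model)$coefficients
  site_slopes <- NULL
  if (pooled) {
    e <- -co["inv_kt", "Estimate"]
    se <- co["inv_kt", "Std. Error"]
  } else {
    # per-site slopes from the interaction model
    lev <- levels(df$site)
    base_slope <- co["inv_kt", "Estimate"]
    slopes <- setNames(rep(base_slope, length(lev)), lev)
    for (l in lev[-1]) {
      nm <- paste0("inv_kt:site", l)
      if (nm %in% rownames(co)) slopes[l] <- base_slope + co[nm, "Estimate"]
    }
    site_slopes <- -slopes
    e <- -base_slope
    se <- co["inv_kt", "Std. Error"]
  }
  intercepts <- NULL
  if (multi_site) {
    lev <- levels(df$site)
    b0 <- co["(Intercept)", "Estimate"]
    intercepts <- setNames(rep(b0, length(lev)), lev)
    for (l in lev[-1]) {
      nm <- paste0("site", l)
      if (nm %in% rownames(co)) intercepts[l] <- b0 + co[nm, "Estimate"]
    }
  } else {
    intercepts <- setNames(co["(Intercept)", "Estimate"],
                           unique(as.character(df$site)))
  }
  structure(
    list(activation_energy_ev = unname(e), se_e = unname(se),
         site_intercepts_ln = intercepts, site_slopes_ev = site_slopes,
         site_slope_test = test, pooled = pooled, n = nrow(df),
         r2 = summary(model)$r.squared,
         boltzmann_k_ev_per_k = boltzmann_k,
         mass_class = mass_class %||% NA_character_,
         temp_range = temp_range %||% NA_character_,
         model = model),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit (%s class, %s range): E = %.3f eV (SE %.3f), %s, n = %d\n",
              x$mass_class, x$temp_range, x$activation_energy_ev, x$se_e,
              if (x$pooled) "pooled across sites" else "site-specific slopes",
              x$n))
  invisible(x)
}

#' Test heterogeneity of Arrhenius slopes across a factor
#'
#' F-test of the `factor x (1/kT)` interaction in a joint linear model of
#' `ln(mass-specific SMR)`, e.g. whether thermal sensitivity differs among
#' body-mass classes.
#'
#' @param records Metabolic records with `mass_specific_smr`,
#'   `temp_level_c` and the grouping column.
#' @param factor Name of the grouping column (default `"mass_class"`).
#' @param boltzmann_k Boltzmann constant in eV K^-1.
#' @return A list with `f`, `df1`, `df2`, `p` and the two nested models.
#' @export
slope_heterogeneity_test <- function(records, factor = "mass_class",
                                     boltzmann_k = boltzmann_k_ev()) {
  df <- as.data.frame(records)
  stopifnot(all(c("mass_specific_smr", "temp_level_c", factor) %in%
                  names(df)))
  df$grp <- base::factor(df[[factor]])
  if (nlevels(df$grp) < 2) {
    stop("need at least 2 levels of `", factor, "`", call. = FALSE)
  }
  df$inv_kt <- inverse_thermal_energy(df$temp_level_c, boltzmann_k)
  df$ln_msmr <- log(df$mass_specific_smr)
  full <- lm(ln_msmr ~ inv_kt * grp, data = df)
  reduced <- lm(ln_msmr ~ inv_kt + grp, data = df)
  cmp <- anova(reduced, full)
  list(f = cmp$F[2], df1 = cmp$Df[2], df2 = cmp$Res.Df[2],
       p = cmp$`Pr(>F)`[2], full = full, reduced = reduced)
}

#' Temperature coefficient Q10 between two rates
#'
#' \deqn{Q_{10} = (R / R_{ref})^{10 / (T - T_{ref})}}
#'
#' the factor by which the rate would change over a 10 degree rise at the
#' observed per-degree sensitivity.
#'
#' @param rate_ref,temp_ref_c Reference rate (positive) and its temperature.
#' @param rate,temp_c Comparison rate (positive) and its temperature
#'   (different from the reference temperature).
#' @return A tibble with `ref_temp_c`, `temp_c` and `q10` (vectorised).
#' @examples
#' compute_q10(1, 10, 2, 20)$q10  # doubling over 10 degrees -> 2
#' @export
compute_q10 <- function(rate_ref, temp_ref_c, rate, temp_c) {
  n <- max(length(rate_ref), length(temp_ref_c), length(rate),
           length(temp_c))
  rate_ref <- rep_len(rate_ref, n); rate <- rep_len(rate, n)
  temp_ref_c <- rep_len(temp_ref_c, n); temp_c <- rep_len(temp_c, n)
  if (any(rate_ref <= 0) || any(rate <= 0)) {
    stop("rates must be positive", call. = FALSE)
  }
  if (any(temp_c == temp_ref_c)) {
    stop("`temp_c` must differ from `temp_ref_c`", call. = FALSE)
  }
  tibble::tibble(
    ref_temp_c = temp_ref_c, temp_c = temp_c,
    q10 = (rate / rate_ref)^(10 / (temp_c - temp_ref_c))
  )
}

#' Q10 table across sites, classes and temperature levels
#'
#' For every site x mass-class cell, compares each temperature level with
#' the site's minimum level, using the geometric mean mass-specific SMR per
#' cell as the rate.
#'
#' @param records Metabolic records carrying `mass_class` (see
#'   [assign_mass_classes()]).
#' @return A tibble `site`, `mass_class`, `ref_temp_c`, `temp_c`, `q10`.
#' @export
q10_table <- function(records) {
  df <- as.data.frame(records)
  stopifnot(all(c("site", "mass_class", "temp_level_c",
                  "mass_specific_smr") %in% names(df)))
  cell <- df |>
    dplyr::group_by(.data$site, .data$mass_class, .data$temp_level_c) |>
    dplyr::summarise(rate = exp(mean(log(.data$mass_specific_smr))),
                     .groups = "drop")
  purrr::map_dfr(split(cell, list(cell$site, cell$mass_class),
                       drop = TRUE), function(g) {
    g <- g[order(g$temp_level_c), ]
    if (nrow(g) < 2) return(NULL)
    ref <- g[1, ]
    rest <- g[-1, ]
    dplyr::bind_cols(
      tibble::tibble(site = rest$site, mass_class = rest$mass_class),
      compute_q10(ref$rate, ref$temp_level_c, rest$rate,
                  rest$temp_level_c)
    )
  })
}

#' Daily temperature anomaly relative to a day-of-year climatology
#'
#' For each observation, subtracts the mean value observed on the same
#' calendar day (month-day) across the climatology window.  February 29 has
#' no climatology of its own in most windows; it is compared against the
#' mean of the February 28 and March 1 climatologies.
#'
#' @param dates A `Date` vector.
#' @param values Numeric series aligned with `dates`.
#' @param climatology_window Optional `Date` length-2 vector delimiting the
#'   climatology period (inclusive); default the whole series.
#' @return A tibble `date`, `value`, `climatology`, `anomaly`.
#' @export
compute_temperature_anomaly <- function(dates, values,
                                        climatology_window = NULL) {
  stopifnot(inherits(dates, "Date"), length(dates) == length(values))
  in_window <- rep(TRUE, length(dates))
  if (!is.null(climatology_window)) {
    stopifnot(length(climatology_window) == 2)
    in_window <- dates >= climatology_window[1] &
      dates <= climatology_window[2]
  }
  if (!any(in_window)) stop("empty climatology window", call. = FALSE)
  md <- format(dates, "%m-%d")
  clim <- tapply(values[in_window], md[in_window], mean)
  clim_of <- function(key) {
    # Feb 29 appears in only ~1/4 of climatology years, so it is always
    # referenced to the mean of the Feb 28 and Mar 1 climatologies.
    if (key == "02-29") {
      neighbours <- c(clim["02-28"], clim["03-01"])
      neighbours <- neighbours[!is.na(neighbours)]
      if (length(neighbours)) return(mean(neighbours))
    }
    if (key %in% names(clim)) return(clim[[key]])
    NA_real_
  }
  clim_vec <- unname(vapply(md, clim_of, numeric(1)))
  tibble::tibble(date = dates, value = values, climatology = clim_vec,
                 anomaly = values - clim_vec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
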