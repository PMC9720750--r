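#' Allometric mass scaling of SMR at one site and temperature
#'
#' OLS regression of `ln SMR` on `ln M` (natural logs; the exponent is
#' base-invariant, the intercept is reported both in ln units and converted
#' to log10 for comparability with published scaling equations).
#'
#' @param records Metabolic records with `dry_mass_mg` and `smr_j_per_day`.
#' @param site,temp_level Optional filters on the `site` and `temp_level_c`
#'   columns.
#' @return A one-row tibble of class `scaling_fit`: `site`, `temp_level_c`,
#'   `exponent_b`, `se_b`, `intercept_ln`, `se_intercept`,
#'   `intercept_log10`, `n`, `r2`.
#' @examples
#' rec <- data.frame(dry_mass_mg = c(1, 2, 4, 8),
#'                   smr_j_per_day = 0.5 * c(1, 2, 4, 8)^0.75)
#' fit_mass_scaling(rec)$exponent_b  # 0.75
#' @export
fit_mass_scaling <- function(records, site = NULL, temp_level = NULL) {
  df <- as.data.frame(records)
  if (!is.null(site)) df <- df[df$site == site, ]
  if (!is.null(temp_level)) {
    df <- df[abs(df$temp_level_c - temp_level) < 1e-8, ]
  }
  stopifnot(all(c("dry_mass_mg", "smr_j_per_day") %in% names(df)))
  if (nrow(df) < 3) {
    stop("need at least 3 records to fit a scaling relationship",
         call. = FALSE)
  }
  if (any(df$dry_mass_mg <= 0) || any(df$smr_j_per_day <= 0)) {
    stop("mass and SMR must be positive for the log transform",
         call. = FALSE)
  }
  if (var(log(df$dry_mass_mg)) == 0) {
    stop("zero variance in ln mass; exponent is unidentifiable",
         call. = FALSE)
  }
  m <- lm(log(smr_j_per_day) ~ log(dry_mass_mg), data = df)
  co <- summary(m)$coefficients
  out <- tibble::tibble(
    site = site %||% NA_character_,
    temp_level_c = temp_level %||% NA_real_,
    exponent_b = co[2, "Estimate"], se_b = co[2, "Std. Error"],
    intercept_ln = co[1, "Estimate"], se_intercept = co[1, "Std. Error"],
    intercept_log10 = co[1, "Estimate"] / log(10),
    n = nrow(df), r2 = summary(m)$r.squared
  )
  class(out) <- c("scaling_fit", class(out))
  out
}

#' Scaling equations for every site x temperature cell
#'
#' @param records Metabolic records.
#' @return A tibble with one [fit_mass_scaling()] row per cell.
#' @export
scaling_equation_table <- function(records) {
  cells <- unique(records[, c("site", "temp_level_c")])
  cells <- cells[order(cells$site, cells$temp_level_c), ]
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    fit_mass_scaling(records, cells$site[i], cells$temp_level_c[i])
  })
}

#' ANCOVA comparison of scaling lines across temperature levels
#'
#' Fits, per site, a single interaction model
#' `ln SMR ~ ln M * factor(temperature)` with the site's lowest temperature
#' as the baseline level, and reports each level's intercept and slope
#' contrast against that baseline with t-tests.  By dummy-coding algebra the
#' contrasts equal the differences of the separate per-level OLS fits.
#'
#' @param records Metabolic records for (at least) one site.
#' @param site Site to analyse.
#' @return A tibble of class `ancova_contrasts` with one row per
#'   temperature level: `d_intercept`, `se_d_intercept`, `t_intercept`,
#'   `p_intercept`, `d_slope`, `se_d_slope`, `t_slope`, `p_slope`, `df`.
#'   The baseline row carries zero contrasts and `NA` tests.
#' @export
compare_across_temperatures <- function(records, site) {
  df <- as.data.frame(records)
  df <- df[df$site == site, ]
  stopifnot(all(c("dry_mass_mg", "smr_j_per_day", "temp_level_c") %in%
                  names(df)))
  levels_c <- sort(unique(df$temp_level_c))
  if (length(levels_c) < 2) {
    stop("site ", site, " has fewer than 2 temperature levels",
         call. = FALSE)
  }
  baseline <- levels_c[1]
  df$t_lvl <- factor(df$temp_level_c, levels = levels_c)
  df$ln_m <- log(df$dry_mass_mg)
  df$ln_smr <- log(df$smr_j_per_day)
  m <- lm(ln_smr ~ ln_m * t_lvl, data = df)
  co <- summary(m)$coefficients
  res_df <- m$df.residual
  rows <- purrr::map_dfr(levels_c, function(lv) {
    if (lv == baseline) {
      return(tibble::tibble(
        site = site, temp_level_c = lv, baseline_level_c = baseline,
        d_intercept = 0, se_d_intercept = NA_real_,
        t_intercept = NA_real_, p_intercept = NA_real_,
        d_slope = 0, se_d_slope = NA_real_,
        t_slope = NA_real_, p_slope = NA_real_, df = res_df
      ))
    }
    # factor labels are as.character() of the numeric levels
    nm_i <- rownames(co)[match(paste0("t_lvl", lv), rownames(co))]
    nm_s <- rownames(co)[match(paste0("ln_m:t_lvl", lv), rownames(co))]
    tibble::tibble(
      site = site, temp_level_c = lv, baseline_level_c = baseline,
      d_intercept = co[nm_i, "Estimate"],
      se_d_intercept = co[nm_i, "Std. Error"],
      t_intercept = co[nm_i, "t value"],
      p_intercept = co[nm_i, "Pr(>|t|)"],
      d_slope = co[nm_s, "Estimate"],
      se_d_slope = co[nm_s, "Std. Error"],
      t_slope = co[nm_s, "t value"],
      p_slope = co[nm_s, "Pr(>|t|)"],
      df = res_df
    )
  })
  class(rows) <- c("ancova_contrasts", class(rows))
  attr(rows, "model") <- m
  rows
}

#' Global ANCOVA of SMR on mass, temperature and site
#'
#' Fits the full-interaction model
#' `ln SMR ~ ln M * T * site` with temperature as a continuous covariate in
#' degrees C.  When `random_group` names a column, a random intercept for
#' that grouping is added via \pkg{lme4}/\pkg{lmerTest} (the fixed-effects
#' structure is unchanged); otherwise ordinary least squares is used.
#'
#' @param records Metabolic records with `dry_mass_mg`, `smr_j_per_day`,
#'   `temp_level_c` and `site`.
#' @param random_group Optional name of a grouping column (e.g. `"run_id"`)
#'   for a random intercept.
#' @return A list of class `global_model_fit` with `model`, `terms`,
#'   `coefficients` (tibble), `r2_total`, `random_group`,
#'   `elimination_trace` (empty until [stepwise_simplify()]), and `data`.
#' @export
fit_global_ancova <- function(records, random_group = NULL) {
  df <- as.data.frame(records)
  stopifnot(all(c("dry_mass_mg", "smr_j_per_day", "temp_level_c", "site")
                %in% names(df)))
  df$ln_m <- log(df$dry_mass_mg)
  df$ln_smr <- log(df$smr_j_per_day)
  df$temp_c <- df$temp_level_c
  df$site <- factor(df$site)
  fixed <- ln_smr ~ ln_m * temp_c * site
  if (nlevels(df$site) < 2) fixed <- ln_smr ~ ln_m * temp_c
  if (is.null(random_group)) {
    model <- lm(fixed, data = df)
    if (any(is.na(coef(model)))) {
      stop("rank-deficient design; aliased terms: ",
           paste(names(coef(model))[is.na(coef(model))], collapse = ", "),
           call. = FALSE)
    }
  } else {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      stop("the mixed-model path needs the `lmerTest` package",
           call. = FALSE)
    }
    stopifnot(random_group %in% names(df))
    df$.grp <- factor(df[[random_group]])
    fml <- update(fixed, . ~ . + (1 | .grp))
    model <- lmerTest::lmer(fml, data = df)
  }
  new_global_fit(model, df, random_group)
}

new_global_fit <- function(model, data, random_group,
                           elimination_trace = NULL) {
  is_lmm <- inherits(model, "merMod")
  co <- if (is_lmm) summary(model)$coefficients else
    summary(model)$coefficients
  fitted_vals <- fitted(model)
  y <- data$ln_smr
  r2 <- 1 - sum((y - fitted_vals)^2) / sum((y - mean(y))^2)
  structure(
    list(model = model,
         terms = attr(terms(if (is_lmm) formula(model, fixed.only = TRUE)
                            else formula(model)), "term.labels"),
         coefficients = tibble::as_tibble(co, rownames = "term"),
         r2_total = r2,
         random_group = random_group,
         elimination_trace = elimination_trace %||%
           tibble::tibble(step = integer(), dropped = character(),
                          f = numeric(), p = numeric()),
         data = data),
    class = "global_model_fit"
  )
}

#' @export
print.global_model_fit <- function(x, ...) {
  cat("Global ANCOVA of ln SMR (", if (is.null(x$random_group)) "OLS"
      else paste0("random intercept: ", x$random_group),
      "), R2 = ", round(x$r2_total, 3), "\n", sep = "")
  cat("terms:", paste(x$terms, collapse = ", "), "\n")
  if (nrow(x$elimination_trace)) {
    cat("dropped:", paste(x$elimination_trace$dropped, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Backward stepwise simplification by nested-model F-tests
#'
#' Starting from the fitted full-interaction model, repeatedly removes the
#' least significant currently-droppable term (highest p-value above
#' `alpha`), where droppable terms are those whose removal respects
#' marginality (no interaction is orphaned of its main effects —
#' [stats::drop1()] scope).  Stops when every droppable term is significant
#' at `alpha`.  The eliminated terms and their test statistics are recorded
#' in `elimination_trace`.
#'
#' @param fit A [fit_global_ancova()] result.
#' @param alpha Retention threshold (default 0.05).
#' @return A `global_model_fit` for the simplified model.
#' @export
stepwise_simplify <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "global_model_fit"))
  model <- fit$model
  df <- fit$data
  is_lmm <- inherits(model, "merMod")
  trace <- list()
  step <- 0L
  repeat {
    d1 <- if (is_lmm) {
      drop1(model, test = "F")   # lmerTest: Satterthwaite F-tests
    } else {
      drop1(model, test = "F")
    }
    tab <- as.data.frame(d1)
    tab <- tab[rownames(tab) != "<none>", , drop = FALSE]
    pcol <- grep("^Pr\\(", names(tab), value = TRUE)[1]
    fcol <- grep("^F", names(tab), value = TRUE)[1]
    if (!nrow(tab) || all(is.na(tab[[pcol]]))) break
    worst <- which.max(tab[[pcol]])
    if (tab[[pcol]][worst] <= alpha) break
    drop_term <- rownames(tab)[worst]
    step <- step + 1L
    trace[[step]] <- tibble::tibble(step = step, dropped = drop_term,
                                    f = tab[[fcol]][worst],
                                    p = tab[[pcol]][worst])
    model <- update(model, as.formula(paste(". ~ . -", drop_term)))
  }
  new_global_fit(model, df, fit$random_group,
                 elimination_trace = dplyr::bind_rows(
                   fit$elimination_trace, dplyr::bind_rows(trace)))
}
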