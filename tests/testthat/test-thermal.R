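test_that("mass classes follow the distribution quantiles", {
  df <- data.frame(dry_mass_mg = 1:9)
  cls <- assign_mass_classes(df)
  expect_equal(as.character(cls$mass_class),
               rep(c("small", "medium", "large"), each = 3))
  b <- attr(cls, "class_bounds_mg")
  expect_equal(unname(b), unname(quantile(1:9, c(0.33, 0.66, 0.99))))
  # heaviest individual above q99 is kept in `large` but flagged
  expect_true(cls$above_q99[9])
  dropped <- assign_mass_classes(df, drop_above_top = TRUE)
  expect_equal(nrow(dropped), 8)
  expect_error(assign_mass_classes(data.frame(dry_mass_mg = rep(2, 10))),
               "degenerate")
})

test_that("inverse thermal energy matches its formula and is monotone", {
  k <- boltzmann_k_ev()
  expect_equal(inverse_thermal_energy(18), 1 / (k * 291.15))
  expect_equal(inverse_thermal_energy(26.2), 1 / (k * 299.35))
  grid <- inverse_thermal_energy(seq(-2, 40, by = 2))
  expect_true(all(diff(grid) < 0))
  expect_error(inverse_thermal_energy(-300), "absolute zero")
})

test_that("noiseless Arrhenius data are inverted to machine precision", {
  recs <- direct_arrhenius_records(c(11, 15, 19, 24, 28), e_ev = 0.65)
  fit <- suppressWarnings(fit_arrhenius(recs))
  expect_equal(fit$activation_energy_ev, 0.65, tolerance = 1e-12)
  # multiplying all rates by a constant shifts only the intercept
  recs10 <- recs
  recs10$mass_specific_smr <- recs10$mass_specific_smr * 17
  fit10 <- suppressWarnings(fit_arrhenius(recs10))
  expect_equal(fit10$activation_energy_ev, 0.65, tolerance = 1e-12)
})

test_that("site structure is pooled or split according to the interaction", {
  set.seed(8)
  # common slope, offset sites -> pooled, offsets recovered
  base <- direct_arrhenius_records(c(12, 18, 25), 0.5, n_per_temp = 40,
                                   sigma = 0.1)
  shifted <- base
  shifted$site <- "S2"
  shifted$mass_specific_smr <- shifted$mass_specific_smr * exp(0.3)
  both <- rbind(base, shifted)
  fit <- fit_arrhenius(both)
  expect_true(fit$pooled)
  expect_equal(unname(diff(fit$site_intercepts_ln)), 0.3, tolerance = 0.05)
  expect_equal(fit$activation_energy_ev, 0.5, tolerance = 0.05)

  # genuinely different slopes -> interaction kept, per-site energies
  other <- direct_arrhenius_records(c(12, 18, 25), 1.1, n_per_temp = 40,
                                    sigma = 0.1)
  other$site <- "S2"
  mix <- rbind(base, other)
  fit2 <- fit_arrhenius(mix)
  expect_false(fit2$pooled)
  expect_equal(unname(fit2$site_slopes_ev["S1"]), 0.5, tolerance = 0.06)
  expect_equal(unname(fit2$site_slopes_ev["S2"]), 1.1, tolerance = 0.06)

  expect_error(fit_arrhenius(direct_arrhenius_records(18, 0.5)),
               "fewer than 2 temperature levels")
})

test_that("activation energies rescale proportionally to the constant used", {
  set.seed(12)
  recs <- direct_arrhenius_records(c(12, 18, 25), 0.6, n_per_temp = 30,
                                   sigma = 0.1)
  k_default <- boltzmann_k_ev()
  k_printed <- 8.167e-5
  f1 <- fit_arrhenius(recs, boltzmann_k = k_default)
  f2 <- fit_arrhenius(recs, boltzmann_k = k_printed)
  expect_equal(f2$activation_energy_ev,
               f1$activation_energy_ev * k_printed / k_default,
               tolerance = 1e-12)
  # inference is untouched by the choice of constant
  expect_equal(summary(f2$model)$coefficients[2, "t value"],
               summary(f1$model)$coefficients[2, "t value"],
               tolerance = 1e-9)
})

test_that("slope heterogeneity across classes is detected with correct df", {
  set.seed(14)
  mk <- function(e, cls) {
    r <- direct_arrhenius_records(c(12, 18, 25), e, n_per_temp = 30,
                                  sigma = 0.15)
    r$mass_class <- cls
    r
  }
  recs <- rbind(mk(0.3, "large"), mk(0.3, "medium"), mk(0.5, "small"))
  het <- slope_heterogeneity_test(recs)
  expect_equal(het$df1, 2)                     # levels - 1
  expect_equal(het$df2, nrow(recs) - 6)        # n - params of full model
  expect_lt(het$p, 0.05)
  expect_error(slope_heterogeneity_test(mk(0.3, "only")), "2 levels")
})

test_that("Q10 follows its defining identities", {
  expect_equal(compute_q10(2, 10, 2, 17)$q10, 1)
  expect_equal(compute_q10(1, 10, 2, 20)$q10, 2)
  expect_equal(compute_q10(1, 10, 1.5, 15)$q10, 2.25)
  expect_error(compute_q10(1, 10, 1, 10), "differ")
  expect_error(compute_q10(-1, 10, 1, 20), "positive")
})

test_that("Q10 of Arrhenius-generated rates equals the closed form", {
  k <- boltzmann_k_ev()
  for (e in c(0.29, 0.48, 0.65)) {
    t1 <- 12; t2 <- 25
    r <- direct_arrhenius_records(c(t1, t2), e, n_per_temp = 1)
    q10 <- compute_q10(r$mass_specific_smr[r$temp_level_c == t1], t1,
                       r$mass_specific_smr[r$temp_level_c == t2],
                       t2)$q10
    closed <- exp(10 * e / (k * (t1 + 273.15) * (t2 + 273.15)))
    expect_lt(abs(q10 - closed) / closed, 0.005)
  }
})

test_that("temperature anomalies subtract the day-of-year climatology", {
  d <- seq(as.Date("2015-01-01"), as.Date("2016-12-31"), by = "day")
  a0 <- compute_temperature_anomaly(d, rep(15, length(d)))
  expect_true(all(a0$anomaly == 0))

  # 2015 is the climatology; 2016 runs one degree warmer day for day
  clim <- 15 + 5 * sin(2 * pi * as.integer(format(d, "%j")) / 365)
  vals1 <- clim + (format(d, "%Y") == "2016")
  a1 <- compute_temperature_anomaly(d, vals1,
                                    climatology_window =
                                      c(d[1], as.Date("2015-12-31")))
  jan_feb_2016 <- format(a1$date, "%Y") == "2016" &
    as.integer(format(a1$date, "%j")) <= 59
  expect_equal(a1$anomaly[jan_feb_2016], rep(1, sum(jan_feb_2016)),
               tolerance = 1e-12)

  # leap day is referenced to the mean of its neighbours' climatology
  vals <- seq_along(d)  # strictly increasing daily values
  a2 <- compute_temperature_anomaly(d, vals)
  feb29 <- a2[format(a2$date, "%m-%d") == "02-29", ]
  exp_clim <- mean(c(
    mean(vals[format(d, "%m-%d") == "02-28"]),
    mean(vals[format(d, "%m-%d") == "03-01"])
  ))
  expect_equal(feb29$climatology, exp_clim)
  expect_error(compute_temperature_anomaly(d, vals,
                                           climatology_window =
                                             as.Date(c("2020-01-01",
                                                       "2020-12-31"))),
               "empty")
})
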