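test_that("noiseless power laws are inverted exactly", {
  m <- exp(seq(log(0.5), log(12), length.out = 40))
  rec <- data.frame(dry_mass_mg = m, smr_j_per_day = 0.4 * m^0.75)
  fit <- suppressWarnings(fit_mass_scaling(rec))
  expect_equal(fit$exponent_b, 0.75, tolerance = 1e-12)
  expect_equal(fit$intercept_ln, log(0.4), tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("degenerate scaling inputs are rejected", {
  expect_error(fit_mass_scaling(data.frame(dry_mass_mg = c(1, 2),
                                           smr_j_per_day = c(1, 2))),
               "at least 3")
  expect_error(fit_mass_scaling(data.frame(dry_mass_mg = rep(2, 5),
                                           smr_j_per_day = 1:5)),
               "variance")
  expect_error(fit_mass_scaling(data.frame(dry_mass_mg = c(1, 2, -3),
                                           smr_j_per_day = c(1, 2, 3))),
               "positive")
})

test_that("the exponent is invariant to the logarithm base", {
  set.seed(4)
  m <- exp(runif(60, log(0.4), log(13)))
  smr <- 0.5 * m^0.8 * exp(rnorm(60, 0, 0.2))
  b_ln <- fit_mass_scaling(data.frame(dry_mass_mg = m,
                                      smr_j_per_day = smr))$exponent_b
  b_log10 <- unname(coef(lm(log10(smr) ~ log10(m)))[2])
  expect_equal(b_ln, b_log10, tolerance = 1e-12)
})

test_that("confidence intervals for b have nominal coverage", {
  set.seed(7)
  covered <- 0
  n_rep <- 300
  for (i in seq_len(n_rep)) {
    m <- exp(runif(40, log(0.4), log(13.57)))
    smr <- 0.3 * m^0.75 * exp(rnorm(40, 0, 0.15))
    f <- fit_mass_scaling(data.frame(dry_mass_mg = m, smr_j_per_day = smr))
    half <- qt(0.975, f$n - 2) * f$se_b
    covered <- covered + (abs(f$exponent_b - 0.75) <= half)
  }
  expect_gte(covered / n_rep, 0.91)
  expect_lte(covered / n_rep, 0.985)
})

test_that("temperature-level contrasts equal differences of separate fits", {
  p <- generative_params(seed = 21)
  recs <- simulate_records(p)
  con <- compare_across_temperatures(recs, "Lesina")
  base_lv <- con$baseline_level_c[1]
  sep_base <- fit_mass_scaling(recs, "Lesina", base_lv)
  for (i in which(con$temp_level_c != base_lv)) {
    sep <- fit_mass_scaling(recs, "Lesina", con$temp_level_c[i])
    expect_equal(con$d_slope[i], sep$exponent_b - sep_base$exponent_b,
                 tolerance = 1e-10)
    expect_equal(con$d_intercept[i],
                 sep$intercept_ln - sep_base$intercept_ln,
                 tolerance = 1e-10)
  }
  # the baseline contrasts with itself are exactly zero
  base_row <- con[con$temp_level_c == base_lv, ]
  expect_equal(base_row$d_slope, 0)
  expect_equal(base_row$d_intercept, 0)
})

test_that("slope-contrast type-I error is near nominal", {
  set.seed(31)
  rej <- 0
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    m <- exp(runif(120, log(0.4), log(13.57)))
    t_lvl <- rep(c(12, 18, 27), each = 40)
    smr <- 0.3 * m^0.75 * exp(0.05 * (t_lvl - 18)) * exp(rnorm(120, 0, 0.15))
    recs <- data.frame(site = "X", dry_mass_mg = m, smr_j_per_day = smr,
                       temp_level_c = t_lvl)
    con <- compare_across_temperatures(recs, "X")
    p_top <- con$p_slope[con$temp_level_c == 27]
    rej <- rej + (p_top < 0.05)
  }
  expect_gte(rej / n_rep, 0.02)
  expect_lte(rej / n_rep, 0.09)
})

test_that("the global ANCOVA reduces to OLS and flags aliasing", {
  # single site, additive truth: the simplified model equals plain OLS
  set.seed(5)
  m <- exp(runif(150, log(0.4), log(13)))
  t_lvl <- sample(c(12, 18, 24), 150, replace = TRUE)
  smr <- exp(-1 + 0.75 * log(m) + 0.06 * (t_lvl - 18) +
               rnorm(150, 0, 0.15))
  recs <- data.frame(site = "only", dry_mass_mg = m, smr_j_per_day = smr,
                     temp_level_c = t_lvl)
  simp <- stepwise_simplify(fit_global_ancova(recs))
  expect_false("ln_m:temp_c" %in% simp$terms)
  direct <- lm(log(smr) ~ log(m) + t_lvl)
  expect_equal(sort(unname(coef(simp$model))),
               sort(unname(coef(direct))), tolerance = 1e-10)

  # constant temperature aliases the temperature terms
  recs$temp_level_c <- 18
  expect_error(fit_global_ancova(recs), "rank-deficient")
})

test_that("stepwise elimination respects marginality and stops correctly", {
  p <- generative_params(seed = 9, e_mass_slope = -0.12)
  recs <- simulate_records(p)
  full <- fit_global_ancova(recs)
  simp <- stepwise_simplify(full)
  # no interaction survives without its main effects
  for (tm in simp$terms) {
    parts <- strsplit(tm, ":")[[1]]
    if (length(parts) > 1) {
      for (sub in parts) expect_true(sub %in% simp$terms)
    }
  }
  # a strong mass x temperature interaction is retained
  expect_true("ln_m:temp_c" %in% simp$terms)
  # an already-minimal model comes back unchanged
  again <- stepwise_simplify(simp)
  expect_identical(sort(again$terms), sort(simp$terms))
  expect_equal(nrow(again$elimination_trace),
               nrow(simp$elimination_trace))
})

test_that("the mixed-model path fits a random intercept", {
  skip_if_not_installed("lmerTest")
  p <- generative_params(seed = 13, n_per_cell = 10)
  ds <- simulate_records(p)
  ds$batch <- sample(letters[1:5], nrow(ds), replace = TRUE)
  fit <- fit_global_ancova(ds, random_group = "batch")
  expect_s4_class(fit$model, "lmerMod")
  expect_true(all(is.finite(fit$coefficients$Estimate)))
  simp <- stepwise_simplify(fit)
  expect_true("ln_m" %in% simp$terms)
})
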