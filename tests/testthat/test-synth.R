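test_that("population generation honours cell counts, range and seed", {
  p <- generative_params(seed = 11)
  pop <- generate_population(p)
  expect_equal(nrow(pop), 3 * 5 * 25)   # 375 individuals
  expect_true(all(pop$dry_mass_mg >= 0.4 & pop$dry_mass_mg <= 13.57))
  pop2 <- generate_population(p)
  expect_identical(pop, pop2)
  expect_error(generative_params(n_per_cell = 1), "n_per_cell")
})

test_that("the generative model obeys its closed-form identities", {
  p <- generative_params(sigma_ln = 0, e_mass_slope = 0, e0 = 0.5,
                         plateau = NULL)
  # ln-rate difference across temperatures is -e0 * d(1/kT), exactly
  s1 <- generate_true_smr(3, 12, "Lesina", p)
  s2 <- generate_true_smr(3, 24, "Lesina", p)
  dx <- inverse_thermal_energy(24) - inverse_thermal_energy(12)
  expect_equal(log(s2) - log(s1), -0.5 * dx)

  # at the reference temperature the model is a pure power law
  m <- c(0.5, 2, 9)
  s <- generate_true_smr(m, 18, "Quarantia", p)
  expect_equal(log(s), unname(p$site_offsets["Quarantia"]) + 0.75 * log(m))
})

test_that("the homeostasis plateau caps latent rates at the site maximum", {
  p <- generative_params(sigma_ln = 0,
                         plateau = list(sites = "Acquatina",
                                        min_mass_mg = 5))
  sites <- site_presets()
  t_max <- sites$t_max_c[sites$site == "Acquatina"]
  at_max <- generate_true_smr(8, t_max, "Acquatina", p, sites)
  above <- generate_true_smr(8, t_max + 1.2, "Acquatina", p, sites)
  expect_equal(above, at_max)
  # light individuals and other sites are unaffected
  expect_gt(generate_true_smr(2, t_max + 1.2, "Acquatina", p, sites),
            generate_true_smr(2, t_max, "Acquatina", p, sites))
  expect_gt(generate_true_smr(8, 26.2, "Quarantia", p, sites),
            generate_true_smr(8, 25, "Quarantia", p, sites))
})

test_that("trace generation inverts the flux equation", {
  cfg <- chamber_config(dt_s = 30)
  tr0 <- generate_trace(0, 18, 20, cfg)
  ms <- tapply(tr0$po2_torr, tr0$phase, mean)
  expect_equal(unname(ms["specimen"]), unname(ms["blank"]))

  tr <- generate_trace(1.5, 18, 20, cfg, seed = 3)
  tr_again <- generate_trace(1.5, 18, 20, cfg, seed = 3)
  expect_identical(tr, tr_again)

  # a chamber flow far too low for the metabolic rate is impossible
  expect_error(generate_trace(50, 18, 20, chamber_config(flow_l_per_h =
                                                           0.0005)),
               "deplete")
})

test_that("mass distributions are homogeneous across temperature cells", {
  p <- generative_params(n_per_cell = 25)
  passes <- 0
  for (i in 1:20) {
    pop <- generate_population(p, seed = 100 + i)
    cells <- split(pop$dry_mass_mg, pop$temp_level_c)
    ks <- suppressWarnings(ks.test(cells[[1]], cells[[length(cells)]]))
    passes <- passes + (ks$p.value > 0.05)
  }
  expect_gte(passes, 17)
})

test_that("the full pipeline identifies the generative structure", {
  p <- generative_params(sigma_ln = 0.15, n_per_cell = 25, plateau = NULL)
  ok_sign <- 0
  ok_order <- 0
  n_rep <- 30
  for (i in seq_len(n_rep)) {
    recs <- simulate_records(p, seed = 500 + i)
    fit <- fit_global_ancova(recs)
    co <- fit$coefficients
    b_lnm_t <- co$Estimate[co$term == "ln_m:temp_c"]
    ok_sign <- ok_sign + (b_lnm_t < 0)
    inter <- fit_arrhenius(recs)
    off <- inter$site_intercepts_ln
    ok_order <- ok_order + (off["Quarantia"] == max(off))
  }
  expect_gte(ok_sign, round(0.9 * n_rep))
  expect_gte(ok_order, round(0.9 * n_rep))
})
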