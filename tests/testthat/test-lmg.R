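test_that("single-group and orthogonal designs have closed-form shares", {
  set.seed(2)
  x <- rnorm(60)
  y <- 2 * x + rnorm(60)
  vp <- lmg_shares(y, list(x = x))
  expect_equal(unname(vp$shares["x"]), summary(lm(y ~ x))$r.squared,
               tolerance = 1e-12)
  expect_equal(sum(vp$shares), vp$r2_full, tolerance = 1e-12)

  # exactly orthogonal, centred predictors: shares are the marginal R2s
  x1 <- scale(rnorm(80), scale = FALSE)[, 1]
  x2 <- residuals(lm(rnorm(80) ~ x1))
  y2 <- x1 + 0.5 * x2 + rnorm(80)
  vp2 <- lmg_shares(y2, list(a = x1, b = x2))
  expect_equal(unname(vp2$shares["a"]),
               summary(lm(y2 ~ x1))$r.squared, tolerance = 1e-10)
  expect_equal(unname(vp2$shares["b"]),
               summary(lm(y2 ~ x2))$r.squared, tolerance = 1e-10)
})

test_that("both routes agree with brute force on random designs", {
  set.seed(3)
  for (rep in 1:8) {
    d <- random_lmg_design(sample(3:5, 1))
    perm <- lmg_shares(d$y, d$groups, method = "exact_permutations")
    shap <- lmg_shares(d$y, d$groups, method = "shapley_subsets")
    oracle <- oracle_lmg(d$y, d$groups)
    expect_equal(perm$shares, shap$shares, tolerance = 1e-10)
    expect_equal(perm$shares, oracle, tolerance = 1e-10)
    expect_equal(sum(perm$shares), perm$r2_full, tolerance = 1e-10)
    expect_equal(sum(shap$shares), shap$r2_full, tolerance = 1e-10)
  }
})

test_that("shares are invariant to group labelling order", {
  set.seed(6)
  d <- random_lmg_design(4)
  vp <- lmg_shares(d$y, d$groups)
  vp_rev <- lmg_shares(d$y, rev(d$groups))
  expect_equal(vp$shares[names(vp_rev$shares)], vp_rev$shares,
               tolerance = 1e-12)
})

test_that("marginality keeps interactions behind their parents", {
  set.seed(9)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n)
  inter <- (x1 - mean(x1)) * (x2 - mean(x2))
  y <- x1 + x2 + 0.8 * inter + rnorm(n)
  groups <- list(a = x1, b = x2, ab = inter)
  parents <- list(ab = c("a", "b"))
  perm <- lmg_shares(y, groups, parents = parents,
                     method = "exact_permutations")
  shap <- lmg_shares(y, groups, parents = parents,
                     method = "shapley_subsets")
  oracle <- oracle_lmg(y, groups, parents = parents)
  expect_equal(perm$shares, shap$shares, tolerance = 1e-10)
  expect_equal(perm$shares, oracle, tolerance = 1e-10)
  expect_equal(sum(perm$shares), perm$r2_full, tolerance = 1e-10)
  # the restriction matters: unrestricted shares credit `ab` differently
  free <- lmg_shares(y, groups, marginality = FALSE)
  expect_false(isTRUE(all.equal(free$shares["ab"], perm$shares["ab"],
                                tolerance = 1e-6)))
})

test_that("the SMR wrapper partitions ln SMR variance coherently", {
  p <- generative_params(seed = 17)
  recs <- simulate_records(p)
  vp <- smr_variance_partition(recs)
  expect_setequal(names(vp$shares), c("lnM", "T", "site", "lnM:T"))
  expect_true(all(vp$shares > -1e-8))
  expect_equal(sum(vp$shares), vp$r2_full, tolerance = 1e-8)
  expect_equal(sum(vp$shares_pct_explained), 100, tolerance = 1e-6)
  # mass and temperature dominate; the interaction share is modest
  expect_gt(vp$shares["lnM"], vp$shares["lnM:T"])
})

test_that("one-way ANOVA matches the pooled t-test and a hand example", {
  set.seed(10)
  a <- rnorm(12); b <- rnorm(12, 0.8)
  res <- anova_oneway(c(a, b), rep(c("a", "b"), each = 12))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  # 3 groups x 5 values against the hand-computed sums of squares
  g1 <- c(10, 12, 9, 11, 8)
  g2 <- c(14, 15, 13, 16, 12)
  g3 <- c(9, 8, 11, 5, 7)
  hand <- anova_oneway(c(g1, g2, g3), rep(1:3, each = 5))
  ss_b <- 5 * sum((c(mean(g1), mean(g2), mean(g3)) -
                     mean(c(g1, g2, g3)))^2)
  ss_w <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) +
    sum((g3 - mean(g3))^2)
  expect_equal(hand$f, (ss_b / 2) / (ss_w / 12), tolerance = 1e-12)
  expect_equal(hand$df1, 2)
  expect_equal(hand$df2, 12)

  expect_error(anova_oneway(1:5, rep("a", 5)), "2 groups")
  expect_error(anova_oneway(1:3, c("a", "a", "b")), "at least 2 values")
})
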