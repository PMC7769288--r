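test_that("covariate screening applies the joint p and |r| rule strictly", {
  set.seed(1)
  g <- rnorm(10)
  s <- screen_covariate(g, g, "Age")
  expect_equal(s$r, 1)
  expect_true(s$passes)

  # |r| just below the threshold fails no matter how small p is
  set.seed(2)
  n <- 500
  u <- as.numeric(scale(rnorm(n)))
  v <- as.numeric(scale(resid(lm(rnorm(n) ~ u))))
  r0 <- 0.4 - 1e-9
  cov <- r0 * u + sqrt(1 - r0^2) * v
  s2 <- screen_covariate(u, cov)
  expect_lt(s2$p, 1e-10)
  expect_false(s2$passes)

  # negative correlations are admitted on magnitude
  s3 <- screen_covariate(u, -(0.6 * u + 0.8 * v))
  expect_lt(s3$r, -0.4)
  expect_true(s3$passes)

  # zero variance fails with a flag rather than erroring the pipeline
  s4 <- screen_covariate(rep(1, 10), rnorm(10))
  expect_false(s4$passes)
  expect_equal(s4$flag, "zero-variance")
})

test_that("screening decisions agree with an independent cor.test oracle", {
  set.seed(7)
  n <- 46
  for (rep in 1:400) {
    g <- rnorm(n)
    cov <- 0.3 * g + rnorm(n)
    s <- screen_covariate(g, cov)
    ct <- cor.test(g, cov)
    expect_equal(s$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(s$p, ct$p.value, tolerance = 1e-12)
    expect_identical(s$passes,
                     ct$p.value < 0.05 && abs(ct$estimate) > 0.4)
  }
})

test_that("interaction screening keeps null interactions out and strong ones in", {
  set.seed(11)
  n <- 46
  med <- rep(0:1, each = n / 2)
  # null interaction: inclusion rate should sit near the 5% nominal level
  hits <- 0
  reps <- 400
  for (i in 1:reps) {
    cov <- rnorm(n)
    g <- 2 * cov + rnorm(n)
    hits <- hits + screen_interaction(g, cov, med)$include
  }
  expect_lt(hits / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))

  # slope differing by 5 residual SDs between groups is always caught
  cov <- rnorm(n)
  g <- 2 * cov + 5 * med * cov + rnorm(n)
  expect_true(screen_interaction(g, cov, med)$include)

  # constant covariate makes the design singular: excluded with a flag
  s <- screen_interaction(g, rep(1, n), med)
  expect_false(s$include)
  expect_equal(s$flag, "singular-design")
})

test_that("zone classification covers the nine-cell decision table", {
  expect_equal(classify_zone(FALSE, FALSE)$zone_code, "1")
  expect_equal(classify_zone(FALSE, TRUE)$zone_code, "2A")
  expect_equal(classify_zone(TRUE, FALSE)$zone_code, "2B")
  expect_equal(classify_zone(FALSE, TRUE, int_tiv = TRUE)$zone_code, "2C")
  expect_equal(classify_zone(TRUE, FALSE, int_age = TRUE)$zone_code, "2D")
  expect_equal(classify_zone(TRUE, TRUE)$zone_code, "3A")
  expect_equal(classify_zone(TRUE, TRUE, FALSE, TRUE)$zone_code, "3B")
  expect_equal(classify_zone(TRUE, TRUE, TRUE, FALSE)$zone_code, "3C")
  expect_equal(classify_zone(TRUE, TRUE, TRUE, TRUE)$zone_code, "3D")

  # interaction without its covariate is a contract violation
  expect_error(classify_zone(FALSE, FALSE, int_age = TRUE), "inconsistent")
  expect_error(classify_zone(TRUE, FALSE, int_tiv = TRUE), "inconsistent")

  # zone_from_code is the exact inverse of the table
  for (code in c("1", "2A", "2B", "2C", "2D", "3A", "3B", "3C", "3D"))
    expect_equal(zone_from_code(code)$zone_code, code)
  expect_error(zone_from_code("4Z"), "unknown zone")
})

test_that("Zone 1 group F equals the squared pooled-variance t statistic", {
  for (seed in 1:10) {
    tab <- make_toy_table(n_per_group = 12, seed = seed, effect_ml = 2,
                          noise_sd = 3)
    fit <- fit_region(tab, "region", "1")
    tt <- t.test(tab$volumes[tab$subjects$med == 1, 1],
                 tab$volumes[tab$subjects$med == 0, 1], var.equal = TRUE)
    expect_equal(fit$F_med, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(fit$p_nominal, tt$p.value, tolerance = 1e-9)
  }
})

test_that("OLS coefficients match the normal-equations oracle in every zone", {
  codes <- c("1", "2A", "2B", "2C", "2D", "3A", "3B", "3C", "3D")
  for (seed in seq_along(codes)) {
    tab <- make_toy_table(n_per_group = 10, seed = seed, effect_ml = 1,
                          age_slope = -0.2, tiv_slope = 0.05, noise_sd = 2)
    zone <- zone_from_code(codes[seed])
    fit <- fit_region(tab, "region", zone)
    oracle <- normal_equations_beta(fit$design, fit$response)
    expect_equal(unname(fit$beta), as.numeric(oracle), tolerance = 1e-8)
    # partial eta-squared identity holds on every fit
    expect_equal(fit$eta2_partial,
                 fit$F_med / (fit$F_med + fit$df_error), tolerance = 1e-12)
  }
})

test_that("error df track the zone's parameter count (n = 46)", {
  tab <- make_toy_table(n_per_group = 23, seed = 5, effect_ml = 3,
                        age_slope = -0.5, tiv_slope = 0.1, noise_sd = 4)
  expect_equal(fit_region(tab, "region", "1")$df_error, 44L)
  expect_equal(fit_region(tab, "region", "3A")$df_error, 42L)
  expect_equal(fit_region(tab, "region", "3D")$df_error, 40L)
})

test_that("model nesting: each added column removes 1 df and never raises SSE", {
  tab <- make_toy_table(n_per_group = 15, seed = 9, effect_ml = 1,
                        age_slope = -0.3, tiv_slope = 0.04, noise_sd = 2)
  sse <- function(fit) sum(fit$residuals^2)
  ladder <- c("1", "2A", "3A", "3B", "3D")
  fits <- lapply(ladder, function(z) fit_region(tab, "region", z))
  for (i in 2:length(fits)) {
    expect_lte(sse(fits[[i]]), sse(fits[[i - 1]]) + 1e-10)
    expect_equal(fits[[i - 1]]$df_error - fits[[i]]$df_error, 1L)
  }
})

test_that("degenerate designs fail with informative errors", {
  tab <- make_toy_table(n_per_group = 10, seed = 3)
  tab$subjects$tiv_ml <- tab$subjects$age  # TIV collinear with age
  expect_error(fit_region(tab, "region", "3A"), "collinear")

  small <- make_toy_table(n_per_group = 2, seed = 4)
  expect_error(fit_region(small, "region", "1"), "at least 3 subjects")
})

test_that("fitted group coefficient is unbiased at the study design", {
  # generative effect 6.93% of 611 mL; mean fitted Med coefficient over
  # replicates should sit within 5% of the true 42.34 mL
  true_eff <- 611 * 6.93 / 100
  est <- numeric(300)
  for (i in seq_len(300)) {
    co <- generate_cohort(seed = 1000 + i)
    tab <- generate_volumes(co, whole_brain_spec(), seed = 2000 + i)
    est[i] <- fit_region(tab, "whole_brain", "3A")$beta[["Med"]]
  }
  expect_lt(abs(mean(est) - true_eff), 0.05 * true_eff)
})

test_that("diagnostics report assumption checks without touching the fit", {
  tab <- make_toy_table(n_per_group = 12, seed = 21, effect_ml = 2,
                        age_slope = -0.3, tiv_slope = 0.05, noise_sd = 2)
  fit <- fit_region(tab, "region", "3A")
  d <- run_diagnostics(fit)
  expect_true(d$shapiro_p >= 0 && d$shapiro_p <= 1)
  expect_true(d$levene_p >= 0 && d$levene_p <= 1)
  expect_true(all(is.finite(d$slope_homogeneity_p[c("Age", "TIV")])))

  # one datum moved far out must be counted as an outlier
  tab2 <- tab
  tab2$volumes[3, 1] <- tab2$volumes[3, 1] + 30  # ~15 residual SDs
  fit2 <- fit_region(tab2, "region", "3A")
  d2 <- run_diagnostics(fit2)
  expect_gte(d2$n_outliers, 1)
  expect_true("outliers" %in% d2$flags)
})

test_that("diagnostic p-values behave under their null hypotheses", {
  # Gaussian residuals: Shapiro p approximately uniform over replications;
  # equal group variances: Levene rejects at about its nominal rate
  reps <- 200
  sw <- lev <- numeric(reps)
  for (i in seq_len(reps)) {
    tab <- make_toy_table(n_per_group = 12, seed = 3000 + i, noise_sd = 2)
    fit <- fit_region(tab, "region", "1")
    d <- run_diagnostics(fit)
    sw[i] <- d$shapiro_p
    lev[i] <- d$levene_p
  }
  expect_gt(ks.test(sw, "punif")$p.value, 0.01)
  expect_gte(mean(lev > 0.05), 0.95 - 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("screen_region + classify + fit recovers planted zone structure", {
  # strong covariate structure with no interactions: Zone 3A
  co <- generate_cohort(seed = 31)
  tab <- generate_volumes(co, whole_brain_spec(), seed = 32)
  zone <- screen_region(tab, "whole_brain")
  expect_true(zone$include_tiv)  # r(GMV,TIV) ~ 0.65 by calibration
  expect_false(zone$include_med_x_age && !zone$include_age)

  # pure-noise region with no covariate structure: Zone 1
  stem <- region_spec("stem", baseline_ml = 1.67, noise_sd_ml = 0.28)
  tab2 <- generate_volumes(co, stem, seed = 33)
  expect_equal(screen_region(tab2, "stem")$zone_code, "1")
})
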