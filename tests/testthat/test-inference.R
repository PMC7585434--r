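test_that("standardized single-predictor coefficients equal Pearson r", {
  set.seed(1)
  x <- rnorm(10); df <- data.frame(richness = x, species_stability = 2 * x)
  fit <- standardized_path_fit(df, list(species_stability ~ richness))
  expect_equal(fit$coef, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  for (i in 1:20) {
    df <- data.frame(richness = rnorm(15), species_stability = rnorm(15))
    fit <- standardized_path_fit(df, list(species_stability ~ richness))
    expect_equal(fit$coef, cor(df$richness, df$species_stability),
                 tolerance = 1e-12)
  }
})

test_that("two-predictor coefficients match the normal-equation oracle", {
  toy <- data.frame(
    alpha_stability    = c(1.2, 0.8, 1.9, 2.4, 1.1, 0.5, 1.7, 2.0),
    species_stability  = c(0.9, 0.7, 1.5, 2.1, 1.2, 0.4, 1.1, 1.8),
    species_asynchrony = c(0.3, 0.1, 0.6, 0.5, 0.2, 0.1, 0.8, 0.4)
  )
  fit <- standardized_path_fit(
    toy, list(alpha_stability ~ species_stability + species_asynchrony))
  oracle <- zscore_lm_oracle(toy$alpha_stability, toy[, 2:3])
  expect_equal(fit$coef, unname(oracle), tolerance = 1e-10)
  expect_equal(fit$n, rep(8, 2))
})

test_that("degenerate path inputs fail loudly", {
  df <- data.frame(richness = rep(3, 8), species_stability = rnorm(8))
  expect_error(standardized_path_fit(df, list(species_stability ~ richness)),
               "zero-variance.*richness")
  cyc <- list(a ~ b, b ~ a)
  expect_error(standardized_path_fit(data.frame(a = rnorm(9), b = rnorm(9)),
                                     cyc), "cycle")
  expect_error(standardized_path_fit(data.frame(richness = rnorm(3),
                                                species_stability = rnorm(3)),
                                     list(species_stability ~ richness)),
               "too few rows")
})

test_that("fixed-effect pooling matches the closed form and metafor", {
  mc <- meta_combine(c(0.2, 0.4), c(0.1, 0.1))
  expect_equal(mc$pooled, 0.3, tolerance = 1e-12)
  expect_equal(mc$se, 0.070711, tolerance = 1e-5)

  same <- meta_combine(c(0.25, 0.25, 0.25), c(0.05, 0.07, 0.1))
  expect_equal(same$pooled, 0.25, tolerance = 1e-12)
  expect_equal(same$Q_het, 0, tolerance = 1e-12)

  eq <- meta_combine(1:6 / 10, rep(0.2, 6))
  expect_equal(eq$pooled, mean(1:6 / 10), tolerance = 1e-12)
  expect_equal(eq$se, 0.2 / sqrt(6), tolerance = 1e-12)

  expect_error(meta_combine(c(0.1, 0.2), c(0.1, 0)), "SEs")
  expect_error(meta_combine(0.1, 0.1), ">= 2")

  set.seed(8)
  coefs <- rnorm(5, 0.3, 0.2); ses <- runif(5, 0.05, 0.2)
  mc <- meta_combine(coefs, ses)
  rf <- metafor::rma(yi = coefs, sei = ses, method = "FE")
  expect_equal(mc$pooled, as.numeric(rf$beta), tolerance = 1e-8)
  expect_equal(mc$se, rf$se, tolerance = 1e-8)
  rd <- metafor::rma(yi = coefs, sei = ses, method = "DL")
  expect_equal(mc$pooled_re, as.numeric(rd$beta), tolerance = 1e-8)
  expect_equal(mc$tau2, rd$tau2, tolerance = 1e-8)
})

test_that("treatment Q follows the two-group subgroup closed form", {
  q <- treatment_difference_q(c(0.4, 0.1), c(0.1, 0.1))
  expect_equal(q$Q, 4.5, tolerance = 1e-12)
  expect_equal(q$df, 1L)
  expect_equal(q$p, pchisq(4.5, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(q$p, 0.0339, tolerance = 1e-3)

  expect_equal(treatment_difference_q(c(0.3, 0.2), c(0.3, 0.1))$Q, 0)
  expect_equal(treatment_difference_q(c(0.3, 0.2), c(0.3, 0.1))$p, 1)

  q2 <- treatment_difference_q(c(0.39, 0.05), c(0.20, 0.05))
  expect_equal(q2$Q, 7.22, tolerance = 1e-10)

  # invariant to swapping group labels and shifting both coefficients
  a <- c(0.42, 0.08); b <- c(0.11, 0.12)
  expect_equal(treatment_difference_q(a, b)$Q,
               treatment_difference_q(b, a)$Q, tolerance = 1e-12)
  expect_equal(treatment_difference_q(a + c(5, 0), b + c(5, 0))$Q,
               treatment_difference_q(a, b)$Q, tolerance = 1e-10)
  expect_error(treatment_difference_q(c(0.1, 0), c(0.2, 0.1)), "SEs")
})

test_that("AR(1) slope reduces to OLS at rho 0 and recovers a known slope", {
  set.seed(12)
  x <- rnorm(40); y <- 1 + 0.5 * x + rnorm(40, 0, 0.3)
  ols <- lm(y ~ x)
  sl <- slope_with_ar1(y, x, fix_rho = 0)
  expect_equal(sl$slope, unname(coef(ols)["x"]), tolerance = 1e-10)
  expect_equal(sl$ci, unname(confint(ols)["x", ]), tolerance = 1e-10)

  # AR(1) noise with rho 0.6: slope CI covers the truth, rho is recovered
  set.seed(99)
  n <- 200
  e <- as.numeric(arima.sim(list(ar = 0.6), n, sd = 0.5))
  x <- rnorm(n); y <- 2 * x + e
  sl <- slope_with_ar1(y, x)
  expect_true(sl$converged)
  expect_true(sl$ci[1] < 2 && 2 < sl$ci[2])
  expect_equal(sl$rho, 0.6, tolerance = 0.15)

  const <- slope_with_ar1(rep(3, 10), rnorm(10))
  expect_equal(const$slope, 0)
  expect_true(is.na(const$rho))
})

test_that("AR(1) slope agrees with gls with corAR1 on a shared fit", {
  set.seed(5)
  n <- 120
  x <- rnorm(n)
  y <- 1.5 * x + as.numeric(arima.sim(list(ar = 0.5), n, sd = 0.4))
  sl <- slope_with_ar1(y, x)
  g <- nlme::gls(y ~ x, correlation = nlme::corAR1(form = ~1))
  expect_equal(sl$slope, unname(coef(g)["x"]), tolerance = 0.05)
})

test_that("log response ratios behave antisymmetrically", {
  expect_equal(log_response_ratio(10, 5), log(2), tolerance = 1e-12)
  expect_equal(log_response_ratio(7, 7), 0)
  expect_equal(log_response_ratio(5, 10), -log(2), tolerance = 1e-12)
  expect_error(log_response_ratio(-1, 2), "positive")
})

test_that("climate residualization matches the normal-equation oracle", {
  set.seed(42)
  clim <- data.frame(MAP_VAR = runif(42, 0.1, 0.8),
                     MAT_VAR = runif(42, 0.05, 0.6))
  y <- rnorm(42)
  res <- climate_residualize(y, clim)
  X <- cbind(1, clim$MAP_VAR, clim$MAT_VAR)
  oracle <- y - X %*% solve(crossprod(X), crossprod(X, y))
  expect_equal(res, as.numeric(oracle), tolerance = 1e-10)
  expect_equal(mean(res), 0, tolerance = 1e-12)

  y_lin <- 2 + 3 * clim$MAP_VAR
  expect_equal(max(abs(climate_residualize(y_lin, clim))), 0,
               tolerance = 1e-10)

  coll <- data.frame(MAP_VAR = clim$MAP_VAR, MAT_VAR = clim$MAP_VAR * 2)
  expect_warning(climate_residualize(y, coll), "collinear")
})

test_that("two-way ANOVA detects planted effects and rejects degenerate input", {
  set.seed(6)
  df <- expand.grid(site = 1:20, treatment = c("Control", "NPK"),
                    duration = 4:9)
  df$value <- rnorm(nrow(df)) + 5 * (df$treatment == "NPK")
  a <- anova_effects(df)
  expect_lt(a$p[a$term == "treatment"], 0.001)
  expect_gt(a$p[a$term == "duration"], 0.05)

  df$value <- rep(1, nrow(df)) + rnorm(nrow(df), 0, 1e-8)
  a0 <- anova_effects(df)
  expect_lt(a0$F[a0$term == "treatment"], 10)

  df1 <- df[df$treatment == "Control", ]
  expect_error(anova_effects(df1), "single level")
})

test_that("overlapping four-year windows enumerate correctly", {
  expect_length(overlapping_windows(9), 6)
  expect_equal(overlapping_windows(9)[[1]], c(1L, 4L))
  expect_equal(overlapping_windows(9)[[6]], c(6L, 9L))
  expect_length(overlapping_windows(4), 1)
  expect_warning(w <- overlapping_windows(3), "fewer than 4")
  expect_length(w, 0)
})

test_that("treatment Q has power against a planted interaction", {
  # site-level metric responds to richness in one arm only; Q per replicate
  set.seed(77)
  sig <- 0
  for (i in 1:100) {
    n <- 42
    rich <- runif(n, 4, 30)
    ctl <- data.frame(richness = rich,
                      species_stability = rnorm(n, 0, 1))
    frt <- data.frame(richness = rich,
                      species_stability = -0.15 * rich + rnorm(n, 0, 1))
    fc <- standardized_path_fit(ctl, list(species_stability ~ richness))
    ff <- standardized_path_fit(frt, list(species_stability ~ richness))
    q <- treatment_difference_q(c(fc$coef, fc$se), c(ff$coef, ff$se))
    sig <- sig + (q$p < 0.05)
  }
  expect_gte(sig / 100, 0.9)
})
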