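# noiseless generator whose group intercepts are log10 of integers, so the
# rounded richness is exact and the fit must reproduce the intercepts
noiseless_config <- function() {
  tiny_config(n_native_nonwoody = 30, n_native_woody = 30,
              n_nonnative_nonwoody = 30, n_nonnative_woody = 30,
              n_families = 6, sd_family = 0, sd_resid = 0,
              beta_range_nonwoody = 0, beta_range_woody = 0,
              beta_year_nonwoody = 0, beta_year_woody = 0,
              beta_dist_nonwoody = 0, beta_dist_woody = 0,
              intercept_native_nonwoody = log10(8),
              intercept_native_woody = log10(12),
              intercept_nonnative_nonwoody = log10(2),
              intercept_nonnative_woody = log10(5),
              missing_woodiness_fraction = 0)
}

noiseless_data <- function() {
  cfg <- noiseless_config()
  fl <- generate_flora(cfg)
  gi <- quiet(generate_interactions(fl, cfg))
  fl$richness <- gi$truth$plants$richness[
    match(fl$accepted_name, gi$truth$plants$accepted_name)]
  fl
}

test_that("noiseless origin model recovers the generating cell means", {
  d <- noiseless_data()
  fit <- quiet(fit_origin_model(d))
  b <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(b["(Intercept)"]), log10(8), tolerance = 1e-6)
  expect_equal(unname(b["originnon-native"]), log10(2) - log10(8),
               tolerance = 1e-6)
  expect_equal(unname(b["woodinesswoody"]), log10(12) - log10(8),
               tolerance = 1e-6)
  expect_equal(unname(b["originnon-native:woodinesswoody"]),
               log10(5) - log10(2) - (log10(12) - log10(8)),
               tolerance = 1e-6)
  expect_equal(fit$sigma2_resid, 0, tolerance = 1e-12)
})

test_that("constant response gives zero slopes and zero residual variance", {
  d <- noiseless_data()
  d$richness <- 7
  fit <- quiet(fit_origin_model(d))
  expect_true(all(abs(fit$coefficients$estimate[-1]) < 1e-10))
  expect_equal(fit$sigma2_resid, 0, tolerance = 1e-12)
})

test_that("origin-model contrasts recover generating effects within 2 SE", {
  cfg <- synthetic_config(seed = 31, recovery = TRUE)
  fl <- generate_flora(cfg)
  gi <- quiet(generate_interactions(fl, cfg))
  fl$richness <- gi$truth$plants$richness
  fit <- quiet(fit_origin_model(fl))
  b <- fit$coefficients
  est <- setNames(b$estimate, b$term)
  se <- setNames(b$se, b$term)
  true_origin <- cfg$intercept_nonnative_nonwoody -
    cfg$intercept_native_nonwoody
  true_wood <- cfg$intercept_native_woody - cfg$intercept_native_nonwoody
  expect_lt(abs(est["originnon-native"] - true_origin),
            2 * se["originnon-native"])
  expect_lt(abs(est["woodinesswoody"] - true_wood),
            2 * se["woodinesswoody"])
})

test_that("drivers model recovers generating slopes within 2 SE", {
  cfg <- synthetic_config(seed = 12, recovery = TRUE)
  fl <- generate_flora(cfg)
  gi <- quiet(generate_interactions(fl, cfg))
  fl$richness <- gi$truth$plants$richness
  non <- fl[fl$origin == "non-native", ]
  non$relatedness <- non$relatedness_true
  fit <- quiet(fit_drivers_model(non))
  sl <- woodiness_slopes(fit)
  truth <- tibble::tibble(
    predictor = rep(c("log10_aoo", "intro_year", "centroid_dist_km"),
                    each = 2),
    woodiness = rep(c("non-woody", "woody"), 3),
    beta = c(cfg$beta_range_nonwoody, cfg$beta_range_woody,
             cfg$beta_year_nonwoody, cfg$beta_year_woody,
             cfg$beta_dist_nonwoody, cfg$beta_dist_woody))
  m <- dplyr::left_join(sl, truth, by = c("predictor", "woodiness"))
  expect_true(all(abs(m$estimate - m$beta) < 2 * m$se))
})

test_that("satterthwaite mode reports degrees of freedom", {
  skip_if_not_installed("lmerTest")
  d <- noiseless_data()
  d$richness <- d$richness + rep_len(0:1, nrow(d)) # break degeneracy
  fit <- quiet(fit_origin_model(d, p_values = "satterthwaite"))
  expect_true("df" %in% names(fit$coefficients))
  expect_true(all(fit$coefficients$df > 0))
})

test_that("marginal R2 equals conditional when family variance is zero", {
  cfg <- tiny_config(n_native_nonwoody = 60, n_native_woody = 60,
                     n_nonnative_nonwoody = 60, n_nonnative_woody = 60,
                     sd_family = 0, missing_woodiness_fraction = 0)
  fl <- generate_flora(cfg)
  gi <- quiet(generate_interactions(fl, cfg))
  fl$richness <- gi$truth$plants$richness
  fit <- quiet(fit_origin_model(fl))
  r2 <- quiet(r2_decomposition(fit))
  expect_equal(r2$estimate[r2$component == "marginal"],
               r2$estimate[r2$component == "conditional"],
               tolerance = 1e-6)
})

test_that("null-effect predictor has near-zero semi-partial R2", {
  cfg <- synthetic_config(seed = 4, recovery = TRUE,
                          n_nonnative_nonwoody = 1000,
                          n_nonnative_woody = 1000)
  fl <- generate_flora(cfg)
  gi <- quiet(generate_interactions(fl, cfg))
  fl$richness <- gi$truth$plants$richness
  non <- fl[fl$origin == "non-native", ]
  non$relatedness <- non$relatedness_true
  fit <- quiet(fit_drivers_model(non))
  r2 <- quiet(r2_decomposition(fit))
  # relatedness has no generating effect
  expect_lt(r2$estimate[r2$component == "relatedness"], 0.01)
})

test_that("dropping every fixed effect returns the full marginal R2", {
  s <- synth_small()
  fl <- s$flora
  fl$richness <- s$truth$plants$richness
  non <- fl[fl$origin == "non-native", ]
  non$relatedness <- non$relatedness_true
  fit <- quiet(fit_drivers_model(non))
  r2 <- quiet(r2_decomposition(fit, predictor_groups = list(everything = "")))
  expect_equal(r2$estimate[r2$component == "everything"],
               r2$estimate[r2$component == "marginal"], tolerance = 1e-6)
})

test_that("marginal R2 is invariant to affine covariate rescaling", {
  s <- synth_small()
  fl <- s$flora
  fl$richness <- s$truth$plants$richness
  non <- fl[fl$origin == "non-native", ]
  non$relatedness <- non$relatedness_true
  fit1 <- quiet(fit_drivers_model(non))
  non2 <- non
  non2$centroid_dist_km <- non2$centroid_dist_km * 3 + 100
  fit2 <- quiet(fit_drivers_model(non2))
  expect_equal(trophinet:::troph_r2_point(fit1)[["marginal"]],
               trophinet:::troph_r2_point(fit2)[["marginal"]], tolerance = 1e-6)
})

test_that("semi-partials do not depend on predictor-group ordering", {
  s <- synth_small()
  fl <- s$flora
  fl$richness <- s$truth$plants$richness
  non <- fl[fl$origin == "non-native", ]
  non$relatedness <- non$relatedness_true
  fit <- quiet(fit_drivers_model(non))
  g1 <- list(range_size = "log10_aoo", relatedness = "relatedness")
  g2 <- rev(g1)
  r1 <- quiet(r2_decomposition(fit, predictor_groups = g1))
  r2 <- quiet(r2_decomposition(fit, predictor_groups = g2))
  expect_equal(
    r1$estimate[r1$component == "range_size"],
    r2$estimate[r2$component == "range_size"], tolerance = 1e-12)
})

test_that("bootstrap CIs bracket the point estimates", {
  s <- synth_small()
  fl <- s$flora
  fl$richness <- s$truth$plants$richness
  non <- fl[fl$origin == "non-native", ]
  non$relatedness <- non$relatedness_true
  fit <- quiet(fit_drivers_model(non))
  r2 <- quiet(r2_decomposition(
    fit, predictor_groups = list(range_size = "log10_aoo"), n_boot = 20,
    seed = 2))
  expect_true(all(is.finite(r2$lower)))
  expect_true(all(r2$lower <= r2$upper))
  m <- r2$estimate[r2$component == "marginal"]
  expect_true(r2$lower[r2$component == "marginal"] < m + 0.1)
})

test_that("back-transformations reproduce their closed forms", {
  expect_equal(round(backtransform_per_decade(0.218), 2), 1.65)
  expect_equal(round(backtransform_per_decade(0.308), 2), 2.03)
  expect_equal(backtransform_per_decade(0), 1)
  expect_equal(round(backtransform_per_century(-0.00097)), 25)
  expect_equal(round(backtransform_per_century(-0.0014)), 38)
  expect_equal(backtransform_per_century(0), 0)
  expect_equal(distance_effect_percent(0, -14868), 0)
  expect_equal(distance_effect_percent(-2.31e-5, -14868),
               (exp(-2.31e-5 * -14868) - 1) * 100)
  # multiplicative symmetry: flipping the contrast inverts the ratio
  up <- distance_effect_percent(-2.31e-5, -14868) / 100 + 1
  dn <- distance_effect_percent(-2.31e-5, 14868) / 100 + 1
  expect_equal(up * dn, 1, tolerance = 1e-12)
})

test_that("residence arithmetic", {
  expect_equal(residence_years(1719, 2025), 306)
  expect_equal(residence_years(1845, 2025), 180)
  expect_equal(residence_years(2000, 2000), 0)
  expect_error(residence_years(2030, 2025), "precede")
})

test_that("group summary reports means, SEs and fold contrasts", {
  plants <- tibble::tibble(
    origin = rep(c("native", "non-native"), each = 4),
    woodiness = rep(c("woody", "woody", "non-woody", "non-woody"), 2),
    richness = c(6, 6.34, 4, 4.26, 2.2, 2.28, 1.8, 1.88))
  gs <- group_summary(plants)
  expect_equal(nrow(gs$groups), 4)
  f <- setNames(gs$contrasts$fold, gs$contrasts$contrast)
  expect_equal(unname(f["native vs non-native (woody)"]), 6.17 / 2.24,
               tolerance = 1e-9)
  expect_equal(unname(f["native vs non-native (non-woody)"]), 4.13 / 1.84,
               tolerance = 1e-9)
  expect_equal(fold_ratio(6.17, 4.13), 1.4939, tolerance = 1e-4)
  expect_equal(fold_ratio(5, 5), 1)
  pc <- setNames(gs$contrasts$percent, gs$contrasts$contrast)
  expect_equal(unname(pc["native vs non-native (woody)"]),
               (6.17 / 2.24 - 1) * 100, tolerance = 1e-9)
})

test_that("crossover threshold inverts the fitted prediction exactly", {
  cfg <- synthetic_config(seed = 6, recovery = TRUE)
  fl <- generate_flora(cfg)
  gi <- quiet(generate_interactions(fl, cfg))
  fl$richness <- gi$truth$plants$richness
  non <- fl[fl$origin == "non-native", ]
  non$relatedness <- non$relatedness_true
  fit <- quiet(fit_drivers_model(non))
  for (w in c("non-woody", "woody")) {
    target <- 12
    km2 <- crossover_threshold(fit, target, "range_size", w)
    # closed-form check: predict at the returned value
    ref <- list(log10_aoo = log10(km2))
    d <- fit$data
    newdata <- tibble::tibble(
      woodiness = factor(w, levels = levels(d$woodiness)),
      relatedness = factor(names(which.max(table(d$relatedness))),
                           levels = levels(d$relatedness)),
      log10_aoo = log10(km2) - fit$centers[["log10_aoo"]],
      intro_year_s = mean(d$intro_year_s),
      centroid_dist_s = mean(d$centroid_dist_s))
    pred <- predict(fit$model, newdata = newdata, re.form = NA)
    expect_equal(unname(pred), log10(target), tolerance = 1e-6)
    yr <- crossover_threshold(fit, target, "intro_year", w)
    expect_true(is.finite(yr))
  }
})

test_that("crossover at the reference point returns the reference value", {
  cfg <- synthetic_config(seed = 6, recovery = TRUE)
  fl <- generate_flora(cfg)
  gi <- quiet(generate_interactions(fl, cfg))
  fl$richness <- gi$truth$plants$richness
  non <- fl[fl$origin == "non-native", ]
  non$relatedness <- non$relatedness_true
  fit <- quiet(fit_drivers_model(non))
  d <- fit$data
  ref_aoo <- fit$centers[["log10_aoo"]] + mean(d$log10_aoo)
  newdata <- tibble::tibble(
    woodiness = factor("woody", levels = levels(d$woodiness)),
    relatedness = factor(names(which.max(table(d$relatedness))),
                         levels = levels(d$relatedness)),
    log10_aoo = mean(d$log10_aoo),
    intro_year_s = mean(d$intro_year_s),
    centroid_dist_s = mean(d$centroid_dist_s))
  target <- 10^predict(fit$model, newdata = newdata, re.form = NA)
  km2 <- crossover_threshold(fit, target, "range_size", "woody")
  expect_equal(log10(km2), ref_aoo, tolerance = 1e-6)
})

test_that("zero slope yields a no-crossover error", {
  d <- noiseless_data()
  non <- d[d$origin == "non-native", ]
  non$relatedness <- non$relatedness_true
  non$richness <- non$richness + rep_len(0:1, nrow(non))
  fit <- quiet(fit_drivers_model(non))
  # manually zero the range-size slope
  fit$model@beta[which(names(lme4::fixef(fit$model)) == "log10_aoo")] <- 0
  fit$model@beta[grep("woodinesswoody:log10_aoo",
                      names(lme4::fixef(fit$model)))] <- 0
  expect_error(crossover_threshold(fit, 5, "range_size", "non-woody"),
               "no crossover")
})

test_that("residual diagnostics flag skew and degeneracy", {
  # continuous lognormal response: conditional residuals exactly normal
  set.seed(9)
  n <- 5000
  d <- tibble::tibble(
    origin = sample(c("native", "non-native"), n, replace = TRUE),
    woodiness = sample(c("woody", "non-woody"), n, replace = TRUE),
    family = sample(sprintf("fam%02d", 1:40), n, replace = TRUE))
  d$richness <- 10^(0.5 + 0.3 * (d$origin == "native") + rnorm(n, 0, 0.4))
  fit <- quiet(fit_origin_model(d))
  norm <- residual_normality_summary(fit)
  expect_lt(abs(norm$skewness), 0.1)
  expect_lt(norm$ks_distance, 0.05)
  # exponential noise: strong positive skew
  d <- noiseless_data()
  set.seed(1)
  d$richness <- pmax(1, round(d$richness * 10^stats::rexp(nrow(d), 2)))
  fit2 <- quiet(fit_origin_model(d))
  skewed <- residual_normality_summary(fit2)
  expect_gt(skewed$skewness, 0.5)
  expect_gt(skewed$ks_distance, norm$ks_distance)
  # constant residuals
  d$richness <- 7
  fit3 <- quiet(fit_origin_model(d))
  expect_warning(residual_normality_summary(fit3), "degenerate")
})
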