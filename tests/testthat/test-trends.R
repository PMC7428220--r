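test_that("no-signal data give a zero slope with an interval covering 0", {
  met <- simulate_metrics(10, 10, beta0 = 1.5, beta1 = 0, sd_int = 0,
                          sd_slope = 0, family = "gaussian", sigma = 0)
  met$richness_S <- 32L  # constant
  f <- suppressWarnings(fit_trend(met, "log10_richness"))
  expect_lt(abs(f$beta1), 1e-6)
  met$n_rare <- 5L
  fnb <- suppressWarnings(fit_trend(met, "n_rare"))
  expect_lt(abs(fnb$beta1), 1e-6)
  expect_true(fnb$interval95[["lower"]] <= 0 && fnb$interval95[["upper"]] >= 0)
})

test_that("with no random effects the NB slope matches a pooled GLM", {
  skip_if_not_installed("MASS")
  met <- simulate_metrics(40, 10, beta0 = 3, beta1 = 0.02, sd_int = 0,
                          sd_slope = 0, family = "nb", theta = 5, seed = 4)
  f <- fit_trend(met, "n_rare", random_effects = "none")
  gm <- MASS::glm.nb(n_rare ~ centered_year, data = met)
  expect_equal(signif(f$beta1, 3), signif(unname(coef(gm)[2]), 3))
})

test_that("per-assemblage slopes are beta1 plus shrunken BLUP deviations", {
  met <- simulate_metrics(25, 12, beta0 = 1.5, beta1 = 0.005, sd_int = 0.3,
                          sd_slope = 0.01, family = "gaussian", sigma = 0.05,
                          seed = 3)
  f <- suppressWarnings(fit_trend(met, "log10_richness"))
  sl <- extract_assemblage_slopes(f)
  expect_length(sl, 25)
  # zero-mean random effect: predicted deviations average to ~0
  expect_lt(abs(mean(sl - f$beta1)), 1e-6)
  # shrinkage: BLUP slopes sit closer to beta1 than per-assemblage OLS slopes
  ols <- vapply(split(met, met$assemblage_id), function(d) {
    unname(coef(lm(log10(richness_S) ~ centered_year, data = d))[2])
  }, numeric(1))[names(sl)]
  expect_lt(mean(abs(sl - f$beta1)), mean(abs(ols - f$beta1)))
})

test_that("an assemblage with a strong true slope tops the slope ranking", {
  met <- simulate_metrics(15, 15, beta0 = 1.5, beta1 = 0, sd_int = 0.1,
                          sd_slope = 0, family = "gaussian", sigma = 0.03,
                          seed = 7)
  hot <- met$assemblage_id == "A001"
  met$richness_S[hot] <- pmax(1, round(
    10^(log10(met$richness_S[hot]) + 0.03 * met$centered_year[hot])))
  f <- suppressWarnings(fit_trend(met, "log10_richness"))
  sl <- extract_assemblage_slopes(f)
  expect_equal(names(which.max(sl)), "A001")
})

test_that("shifting calendar years leaves the fitted slope unchanged", {
  scn <- generate_scenario(scenario_preset("immigration", n_assemblages = 8,
                                           n_years = 10, seed = 12))
  met <- summarize_years(rarefy(filter_years(scn$records), seed = 2))
  rec2 <- dplyr::mutate(scn$records, year = year + 1000L)
  met2 <- summarize_years(rarefy(filter_years(rec2), seed = 2))
  f1 <- suppressWarnings(fit_trend(met, "log10_size"))
  f2 <- suppressWarnings(fit_trend(met2, "log10_size"))
  expect_equal(f1$beta1, f2$beta1, tolerance = 1e-8)
})

test_that("assemblage trends classify by whether the interval crosses zero", {
  fake <- structure(list(
    response = "n_rare", family = "negative_binomial",
    beta1 = 0.004, se_beta1 = 0,
    assemblage_slopes = c(A = 0.0055, B = -0.0005, C = -0.0055),
    assemblage_slope_sd = c(A = 0.0055 / 1.96 / 2.2,
                            B = 0.0035 / 1.96,
                            C = 0.0045 / 1.96 / 2.2)
  ), class = "trend_fit")
  cl <- classify_assemblage_trends(fake)
  expect_equal(as.character(cl$trend),
               c("positive", "indeterminate", "negative"))
  expect_true(all(cl$lower <= cl$slope & cl$slope <= cl$upper))
})

test_that("the NB mixed model recovers slopes simulated from its own form", {
  reps <- 25
  res <- purrr::map(seq_len(reps), function(k) {
    met <- simulate_metrics(30, 10, beta0 = 3, beta1 = 0.01, sd_int = 0.3,
                            sd_slope = 0.005, family = "nb", theta = 5,
                            seed = 1000 + k)
    f <- suppressWarnings(fit_trend(met, "n_rare"))
    c(covered = f$interval95[["lower"]] <= 0.01 &&
        0.01 <= f$interval95[["upper"]],
      beta1 = f$beta1)
  })
  cover <- mean(vapply(res, `[[`, numeric(1), "covered"))
  expect_gte(cover, 0.8)
  expect_equal(mean(vapply(res, `[[`, numeric(1), "beta1")), 0.01,
               tolerance = 0.25)
})

test_that("the Gaussian mixed model recovers log10 slopes", {
  reps <- 25
  cover <- mean(vapply(seq_len(reps), function(k) {
    met <- simulate_metrics(30, 10, beta0 = 1.5, beta1 = 0.003,
                            sd_int = 0.2, sd_slope = 0.002,
                            family = "gaussian", sigma = 0.04,
                            seed = 2000 + k)
    f <- suppressWarnings(fit_trend(met, "log10_richness"))
    f$interval95[["lower"]] <= 0.003 && 0.003 <= f$interval95[["upper"]]
  }, logical(1)))
  expect_gte(cover, 0.8)
})

test_that("the power-variance model fits heteroscedastic alpha trends", {
  met <- withr::with_seed(31, {
    m <- simulate_metrics(30, 15, beta0 = 0, beta1 = 0, sd_int = 0,
                          sd_slope = 0, family = "gaussian")
    ids <- unique(m$assemblage_id)
    b0 <- stats::runif(length(ids), 5, 40)
    b1 <- rnorm(length(ids), 0.05, 0.03)
    i <- match(m$assemblage_id, ids)
    mu <- b0[i] + b1[i] * m$centered_year
    delta <- 0.8
    m$fisher_alpha <- mu + rnorm(nrow(m), 0, 0.2 * abs(mu)^delta)
    m
  })
  f <- suppressWarnings(fit_trend(met, "fisher_alpha"))
  expect_equal(f$family, "gaussian_power_variance")
  expect_equal(f$beta1, 0.05, tolerance = 0.3)
  expect_gt(f$dispersion$delta, 0.3)  # heteroscedasticity picked up
  expect_length(extract_assemblage_slopes(f), 30)
  expect_true(all(is.finite(f$assemblage_slope_sd)))
})

test_that("slope_to_ratio converts log10 slopes to yearly ratios", {
  expect_equal(slope_to_ratio(0), 1)
  expect_equal(slope_to_ratio(1, digits = 6), 10)
  expect_equal(slope_to_ratio(c(0.0007, 0.0043)), c(1.002, 1.010))
})
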