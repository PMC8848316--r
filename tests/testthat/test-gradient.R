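# Gradient regression, effect size, significance categories and the
# effect time course.

test_that("a noiseless log-linear relation is fitted exactly", {
  r <- c(0.1, 0.5, 1, 2, 10)
  y <- 2 * log(r) + 5
  fit <- fit_descriptor_gradient(y, r)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("degenerate inputs follow the documented conventions", {
  r <- c(0.5, 1, 2, 4)
  fit <- fit_descriptor_gradient(rep(7, 4), r)
  expect_equal(fit$slope, 0)
  expect_equal(fit$p_value, 1)
  es <- effect_size(fit, 0.5, 4)
  expect_equal(es$effect_percent, 0)
  expect_error(fit_descriptor_gradient(1:4, rep(2, 4)), "identical")
  expect_error(fit_descriptor_gradient(1:2, c(1, 2)), "at least 3")
  expect_error(fit_descriptor_gradient(1:4, c(-1, 1, 2, 3)), "positive")
})

test_that("slope, intercept, R2 and p match the closed-form OLS oracle", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    r <- exp(stats::runif(n, -2, 2))
    y <- stats::rnorm(n, 3 + 0.7 * log(r), 0.5)
    fit <- fit_descriptor_gradient(y, r)
    or <- oracle_ols(log(r), y)
    expect_equal(fit$slope, or$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, or$intercept, tolerance = 1e-9)
    expect_equal(fit$pearson_r, or$r, tolerance = 1e-9)
    expect_equal(fit$r_squared, or$r2, tolerance = 1e-9)
    expect_equal(fit$p_value, or$p, tolerance = 1e-9)
  }
})

test_that("effect size matches its closed form and baseline conventions", {
  r <- exp(seq(log(0.1), log(10), length.out = 12))
  y <- 10 + 1 * log(r)
  fit <- fit_descriptor_gradient(y, r)
  es <- effect_size(fit, 0.1, 10)
  want <- 100 * (2 * log(10)) / (10 - log(10))
  expect_equal(es$effect_percent, want, tolerance = 1e-9)
  expect_equal(es$y_at_min, 10 + log(0.1), tolerance = 1e-9)
  expect_equal(es$y_at_max, 10 + log(10), tolerance = 1e-9)
  # alternative baselines
  es_max <- effect_size(fit, 0.1, 10, baseline = "max")
  expect_equal(es_max$effect_percent,
               100 * (2 * log(10)) / (10 + log(10)), tolerance = 1e-9)
  # negative baseline prediction invalidates a percent reading
  y2 <- 1 + 2 * log(r)
  fit2 <- fit_descriptor_gradient(y2, r)
  es2 <- effect_size(fit2, 0.1, 10)
  expect_true(es2$undefined)
  expect_true(is.na(es2$effect_percent))
})

test_that("effect size and p-value are invariant to the log base", {
  set.seed(3)
  r <- exp(stats::runif(20, log(0.1), log(10)))
  y <- stats::rnorm(20, 40 + 4 * log(r), 2)
  f_e <- fit_descriptor_gradient(y, r, log_base = exp(1))
  f_10 <- fit_descriptor_gradient(y, r, log_base = 10)
  expect_equal(f_e$p_value, f_10$p_value, tolerance = 1e-12)
  es_e <- effect_size(f_e, 0.1, 10)
  es_10 <- effect_size(f_10, 0.1, 10)
  expect_equal(es_e$effect_percent, es_10$effect_percent, tolerance = 1e-9)
  expect_equal(es_e$conf_low, es_10$conf_low, tolerance = 1e-9)
})

test_that("significance categories use strict thresholds", {
  got <- classify_significance(c(0.005, 0.2, 0.05, 0.01, 0.049))
  expect_equal(as.character(got),
               c("p<0.01", "NS", "NS", "p<0.05", "p<0.05"))
  expect_true(is.ordered(got))
  expect_lt(which(levels(got) == "NS"), which(levels(got) == "p<0.01"))
})

test_that("time course recovers flat and transient programmed effects", {
  lay <- single_species_layout(seed = 2)
  lmap <- build_light_map(lay, gradient_config(noise_sd = 0), seed = 2)
  sch <- imaging_schedule(31)
  # constant-in-time effect: estimates flat across days, CIs cover E
  E <- 25
  m_flat <- morphotype("lycop", effects = list(
    height = effect_fun(slope_for_effect(E, 0.1, 10), onset_day = 0,
                        peak_day = 14, shape = 0)))
  tt <- simulate_descriptor_truth(lay, lmap, list(lycop = m_flat),
                                  schedule = sch, seed = 9)
  ec <- effect_time_course(tt, "side_HeightMax", treatment_days = 31)
  late <- ec[ec$day >= 7, ]
  # per-day CIs cover at the nominal rate; the day-averaged estimate is flat
  expect_gte(mean(late$conf_low <= E & E <= late$conf_high), 0.75)
  expect_lt(abs(mean(late$effect_percent) - E), 3)
  # rise-peak-decay: estimated effect peaks at the configured day
  m_tr <- morphotype("lycop", effects = list(
    height = effect_fun(slope_for_effect(40, 0.1, 10), onset_day = 2,
                        peak_day = 14, shape = 2)))
  tt2 <- simulate_descriptor_truth(lay, lmap, list(lycop = m_tr),
                                   schedule = sch, seed = 10)
  ec2 <- effect_time_course(tt2, "side_HeightMax", treatment_days = 31)
  peak_day <- ec2$day[which.max(abs(ec2$effect_percent))]
  expect_lte(abs(peak_day - 14), 4)  # one imaging session
})

test_that("time course table is complete and flags post-treatment days", {
  lay <- two_species_layout(seed = 1)
  lmap <- build_light_map(lay, gradient_config(), seed = 1)
  morphs <- list(a = morphotype("a"), b = morphotype("b", habit = "grass"))
  tt <- simulate_descriptor_truth(lay, lmap, morphs,
                                  schedule = c(7L, 21L, 35L), seed = 3,
                                  treatment_days = 30)
  ec <- effect_time_course(tt, c("side_HeightMax", "top_Area"),
                           treatment_days = 30)
  expect_equal(nrow(ec), 2 * 3 * 2)  # species x days x descriptors
  expect_identical(unique(ec$post_treatment[ec$day == 35]), TRUE)
  expect_identical(unique(ec$post_treatment[ec$day <= 30]), FALSE)
  expect_error(effect_time_course(tt[tt$day == 7, ], "top_Area"),
               "2 timepoints")
})

test_that("sparse cells are omitted with a message rather than fitted", {
  lay <- two_species_layout(seed = 4)
  lmap <- build_light_map(lay, gradient_config(), seed = 4)
  morphs <- list(a = morphotype("a"), b = morphotype("b"))
  tt <- simulate_descriptor_truth(lay, lmap, morphs,
                                  schedule = c(7L, 14L), seed = 4)
  tt$side_HeightMax[tt$species == "b" & tt$day == 14] <- NA_real_
  expect_message(
    ec <- effect_time_course(tt, "side_HeightMax"),
    "omitted"
  )
  expect_equal(nrow(ec), 3)
})
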