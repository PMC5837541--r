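test_that("swap model specs validate their keys and adjustment sets", {
  expect_error(swap_model_spec("state_transfer", "S", "S"),
               class = "actibigram_invalid_input")
  expect_error(swap_model_spec("state_transfer", "S", "XX"),
               class = "actibigram_invalid_input")
  expect_error(swap_model_spec("ubigram_swap", "[SS]", "MV"),
               class = "actibigram_invalid_input")
  expect_error(swap_model_spec("state_transfer", "S", "M",
                               adjustment = "model3"),
               class = "actibigram_invalid_input")
  spec <- swap_model_spec("ubigram_swap", "[SS]", "[MV]",
                          adjustment = "model3")
  expect_s3_class(spec, "swap_model_spec")
})

test_that("state-transfer coefficients match a closed-form two-predictor OLS", {
  set.seed(31)
  n <- 300
  Md <- runif(n, 20, 120)
  Sd <- runif(n, 300, 600)
  r <- 1440 - (Md + Sd)
  y <- 20 - 0.04 * Md + 0.01 * r + rnorm(n, 0, 1.5)
  tab <- data.frame(Sd = Sd, Ld = 0, Md = Md, Vd = 0, BMI = y)
  spec <- swap_model_spec("state_transfer", baseline = "S",
                          comparison = "M")
  res <- fit_state_transfer(tab, spec)
  beta_oracle <- normal_equation_ols(cbind(1, Md, r), y)
  expect_equal(res$raw_beta, beta_oracle[2], tolerance = 1e-10)
  expect_equal(res$beta_scaled, 10 * beta_oracle[2], tolerance = 1e-10)
  expect_equal(res$n_used, n)
  # t-based CI from the residual degrees of freedom
  fit <- lm(y ~ Md + r)
  se <- summary(fit)$coefficients["Md", "Std. Error"]
  expect_equal(res$ci_low,
               10 * (beta_oracle[2] - qt(0.975, n - 3) * se),
               tolerance = 1e-10)
})

test_that("exchanging baseline and comparison negates the estimate and keeps the CI width", {
  sim <- simulate_cohort(quick_cohort_config(n = 250, seed = 12),
                         rules = one_day_rules())
  tab <- sim$cohort
  # state-transfer family
  for (pair in list(c("S", "M"), c("L", "V"), c("S", "L"))) {
    a <- fit_state_transfer(tab, swap_model_spec("state_transfer",
                                                 pair[1], pair[2]))
    b <- fit_state_transfer(tab, swap_model_spec("state_transfer",
                                                 pair[2], pair[1]))
    expect_equal(a$raw_beta, -b$raw_beta, tolerance = 1e-10)
    expect_equal(a$ci_high - a$ci_low, b$ci_high - b$ci_low,
                 tolerance = 1e-10)
  }
  # u-bigram swap family
  for (pair in list(c("[SS]", "[MV]"), c("[SL]", "[LM]"),
                    c("[LL]", "[MM]"))) {
    a <- fit_bigram_swap(tab, swap_model_spec("ubigram_swap",
                                              pair[1], pair[2]))
    b <- fit_bigram_swap(tab, swap_model_spec("ubigram_swap",
                                              pair[2], pair[1]))
    expect_equal(a$raw_beta, -b$raw_beta, tolerance = 1e-10)
    expect_equal(a$ci_high - a$ci_low, b$ci_high - b$ci_low,
                 tolerance = 1e-10)
  }
})

test_that("a single simulated cohort recovers a known u-bigram swap effect", {
  cfg <- quick_cohort_config(
    n = 1000, seed = 77,
    outcome_coefficients = c(intercept = 21, u_MV = -0.5),
    confounders = list(), noise_sd = 1)
  sim <- simulate_cohort(cfg, rules = one_day_rules())
  spec <- swap_model_spec("ubigram_swap", baseline = "[SS]",
                          comparison = "[MV]")
  res <- fit_bigram_swap(sim$cohort, spec)
  expect_lt(res$ci_low, -5)  # per-10 scale: truth is -5
  expect_gt(res$ci_high, -5)
  expect_equal(res$raw_beta, -0.5, tolerance = 0.15)
})

test_that("per-SD scaling multiplies the coefficient by the baseline SD", {
  sim <- simulate_cohort(quick_cohort_config(n = 300, seed = 4),
                         rules = one_day_rules())
  spec10 <- swap_model_spec("ubigram_swap", "[SS]", "[MV]",
                            scale = "per_10")
  specsd <- swap_model_spec("ubigram_swap", "[SS]", "[MV]",
                            scale = "per_sd")
  r10 <- fit_bigram_swap(sim$cohort, spec10)
  rsd <- fit_bigram_swap(sim$cohort, specsd)
  expect_equal(rsd$sd_of_baseline, sd(sim$cohort$u_SS))
  expect_equal(rsd$beta_scaled, r10$raw_beta * sd(sim$cohort$u_SS))
  expect_true(is.na(r10$sd_of_baseline))
})

test_that("model3 agrees with model1 on a confounder-free cohort", {
  # durations are correlated with the contrast but carry no independent
  # outcome information here, so adjusting for them only adds noise
  cfg <- quick_cohort_config(
    n = 800, seed = 21, nonwear_on = TRUE,
    outcome_coefficients = c(intercept = 21, u_MV = -0.5),
    confounders = list(), noise_sd = 1)
  sim <- simulate_cohort(cfg, rules = one_day_rules())
  m1 <- fit_bigram_swap(sim$cohort,
                        swap_model_spec("ubigram_swap", "[SS]", "[MV]",
                                        adjustment = "model1"))
  m3 <- fit_bigram_swap(sim$cohort,
                        swap_model_spec("ubigram_swap", "[SS]", "[MV]",
                                        adjustment = "model3"))
  expect_lt(abs(m1$raw_beta - m3$raw_beta),
            3 * (m1$raw_se + m3$raw_se))
})

test_that("constant outcomes give a zero estimate with a CI containing zero", {
  sim <- simulate_cohort(quick_cohort_config(n = 100, seed = 3),
                         rules = one_day_rules())
  tab <- sim$cohort
  tab$BMI <- 22
  # summary.lm warns about the (intentionally) perfect fit
  res <- suppressWarnings(
    fit_state_transfer(tab, swap_model_spec("state_transfer", "S", "M")))
  expect_equal(res$beta_scaled, 0, tolerance = 1e-10)
  expect_lte(res$ci_low, 0)
  expect_gte(res$ci_high, 0)
})

test_that("degenerate designs raise informative errors", {
  sim <- simulate_cohort(quick_cohort_config(n = 150, seed = 8),
                         rules = one_day_rules())
  tab <- sim$cohort
  # zero-variance comparison feature
  tab$u_SV <- 0
  expect_error(
    fit_bigram_swap(tab, swap_model_spec("ubigram_swap", "[SS]", "[SV]")),
    class = "actibigram_degenerate_feature")
  # collinear covariate duplicating the comparison column
  tab2 <- sim$cohort
  tab2$dup <- tab2$u_MV
  expect_error(
    fit_bigram_swap(tab2, swap_model_spec("ubigram_swap", "[SS]", "[MV]",
                                          adjustment = "model2",
                                          covariates = "dup")),
    class = "actibigram_collinearity_error")
  # too few rows for the number of terms
  expect_error(
    fit_state_transfer(tab[1:4, ],
                       swap_model_spec("state_transfer", "S", "M")),
    class = "actibigram_invalid_input")
})

test_that("cpm models use per-100-count and per-SD scaling and support mutual adjustment", {
  set.seed(19)
  n <- 500
  mcpm <- runif(n, 300, 1200)
  sdcpm <- 0.8 * mcpm + rnorm(n, 0, 120)
  a <- -0.004
  tab <- data.frame(mCPM = mcpm, sdCPM = sdcpm,
                    BMI = 22 + a * mcpm + rnorm(n, 0, 0.5))
  res <- fit_cpm_models(tab)
  expect_equal(res$mCPM$beta_scaled, a * 100, tolerance = 0.1)
  expect_equal(res$mCPM$scale_unit, "per 100 counts/min")
  expect_equal(res$sdCPM$beta_scaled, res$sdCPM$raw_beta * sd(sdcpm))

  # outcome independent of both -> CIs contain 0
  tab0 <- tab
  set.seed(20)
  tab0$BMI <- rnorm(n, 22, 2)
  res0 <- fit_cpm_models(tab0, mutual = TRUE)
  expect_lt(res0$mCPM$ci_low, 0); expect_gt(res0$mCPM$ci_high, 0)
  expect_lt(res0$sdCPM$ci_low, 0); expect_gt(res0$sdCPM$ci_high, 0)

  # perfect collinearity under mutual adjustment
  tab2 <- tab
  tab2$sdCPM <- tab2$mCPM
  expect_error(fit_cpm_models(tab2, mutual = TRUE),
               class = "actibigram_collinearity_error")
})

test_that("the full grid emits one row per unordered pair and model", {
  sim <- simulate_cohort(quick_cohort_config(n = 200, seed = 15),
                         rules = one_day_rules())
  grid <- run_full_grid(sim$cohort,
                        families = c("state_transfer", "ubigram_swap"),
                        models = "model1")
  expect_equal(sum(grid$kind == "state_transfer"), choose(4, 2))
  expect_equal(sum(grid$kind == "ubigram_swap"), choose(10, 2))
  # each unordered pair appears exactly once
  key <- paste(pmin(grid$baseline, grid$comparison),
               pmax(grid$baseline, grid$comparison))
  expect_false(any(duplicated(paste(grid$kind, grid$model, key))))
  # per-fit failures are flagged rows, not aborts
  tab <- sim$cohort
  tab$u_SV <- 0
  grid2 <- run_full_grid(tab, families = "ubigram_swap", models = "model1")
  # a constant feature breaks fits on both sides: as comparison it has
  # zero variance, as baseline it makes the remainder collinear
  failed <- grid2[!is.na(grid2$error), ]
  expect_gt(nrow(failed), 0)
  expect_true(all(failed$comparison == "[SV]" | failed$baseline == "[SV]"))
  expect_true(all(!is.na(grid2$beta[grid2$baseline != "[SV]" &
                                      grid2$comparison != "[SV]"])))
  # determinism: identical inputs give identical results
  grid3 <- run_full_grid(sim$cohort,
                         families = c("state_transfer", "ubigram_swap"),
                         models = "model1")
  expect_identical(grid, grid3)
})
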