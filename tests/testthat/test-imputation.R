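test_that("stepwise selection recovers an exact single-predictor signal", {
  set.seed(42)
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- 2 * X[, "x1"]
  m <- stepwise_fit(X, y)
  expect_identical(m$predictors, "x1")
  expect_lt(abs(m$coef[["x1"]] - 2) / 2, 1e-8)
  expect_lt(abs(m$intercept), 1e-8)
})

test_that("stepwise on pure noise selects the empty model in the large majority", {
  # with 2 independent noise predictors the analytic empty-model rate is
  # (1 - p_in)^2 = 0.9025 per replicate
  empty <- vapply(1:50, function(r) {
    set.seed(1000 + r)
    X <- matrix(rnorm(200 * 2), 200, 2, dimnames = list(NULL, c("x1", "x2")))
    y <- rnorm(200)
    length(stepwise_fit(X, y)$predictors) == 0L
  }, logical(1))
  expect_gte(mean(empty), 0.8)
})

test_that("single-predictor stepwise degenerates to ordinary least squares", {
  set.seed(3)
  x <- rnorm(100)
  y <- 1.5 + 3 * x + rnorm(100, 0, 0.1)
  m <- stepwise_fit(matrix(x, dimnames = list(NULL, "x")), y)
  ref <- lm(y ~ x)
  expect_equal(m$coef[["x"]], unname(coef(ref)["x"]))
  expect_equal(m$intercept, unname(coef(ref)["(Intercept)"]))
})

test_that("stepwise guards its preconditions", {
  X <- matrix(rnorm(10 * 3), 10, 3)
  expect_error(stepwise_fit(matrix(rnorm(8), 4, 2), rnorm(4)),
               class = "obty_error_size")
  expect_error(stepwise_fit(X, rnorm(10), p_in = 0.2, p_out = 0.1),
               class = "obty_error_validation")
  X[1, 1] <- NA
  expect_error(stepwise_fit(X, rnorm(10)), class = "obty_error_validation")
})

test_that("the full-pattern model reproduces the analytic trapezoid weights", {
  g <- generate_cohort(default_config(n = 300), seed = 12)
  suite <- train_imputation_suite(
    g$cohort, patterns = list(availability_pattern()), seed = 13)
  m <- suite$models[["glucose_auc|0,30,60,120"]]
  expect_equal(unname(m$coef[paste0("glu_", c(0, 30, 60, 120))]),
               c(15, 30, 45, 30), tolerance = 1e-6)
  expect_lt(abs(m$intercept), 1e-6)
  expect_gt(m$r2_test, 1 - 1e-10)
})

test_that("template-generated curves give high held-out adjusted R-squared", {
  g <- generate_cohort(default_config(), seed = 14)
  suite <- train_imputation_suite(g$cohort, seed = 15)
  r2 <- vapply(suite$models, `[[`, numeric(1), "adjusted_r2_test")
  expect_gt(mean(r2), 0.95)
  # higher insulin curve noise orders imputation quality glucose > insulin
  expect_gt(mean(r2[grep("^glucose", names(r2))]),
            mean(r2[grep("^insulin", names(r2))]))
})

test_that("split membership depends on the seed but noiseless coefficients do not", {
  cfg <- default_config(n = 300)
  cfg$curve_noise <- c(glucose = 0, insulin = 0)
  g <- generate_cohort(cfg, seed = 16)
  pats <- list(availability_pattern(glucose = c(0, 60), insulin = c(0, 60)))
  s1 <- train_imputation_suite(g$cohort, patterns = pats, seed = 1)
  s2 <- train_imputation_suite(g$cohort, patterns = pats, seed = 2)
  m1 <- s1$models[["glucose_auc|0,60"]]
  m2 <- s2$models[["glucose_auc|0,60"]]
  expect_equal(m1$coef, m2$coef, tolerance = 1e-8)
  expect_equal(m1$intercept, m2$intercept, tolerance = 1e-6)
})

test_that("imputed features match direct computation for complete records", {
  g <- generate_cohort(default_config(n = 200), seed = 17)
  suite <- train_imputation_suite(g$cohort, seed = 18)
  f_direct <- compute_features(g$cohort)
  f_imp <- impute_features(g$cohort, suite)
  expect_equal(f_imp$glucose_auc, f_direct$glucose_auc)
  expect_equal(f_imp$insulin_auc, f_direct$insulin_auc)
  expect_false(any(f_imp$glucose_imputed) || any(f_imp$insulin_imputed))
})

test_that("records missing the 30-min point are imputed within 2% (glucose)", {
  g <- generate_cohort(default_config(), seed = 19)
  suite <- train_imputation_suite(g$cohort, seed = 20)
  holdout <- generate_cohort(default_config(n = 250), seed = 21)
  miss <- apply_missingness(holdout$cohort,
                            availability_pattern(glucose = c(0, 60, 120),
                                                 insulin = c(0, 60, 120)),
                            fraction = 1, seed = 22)
  f <- impute_features(miss, suite)
  tr <- holdout$truth[match(f$patient_id, holdout$truth$patient_id), ]
  expect_true(all(f$glucose_imputed))
  rel <- abs(f$glucose_auc - tr$glucose_auc) / tr$glucose_auc
  expect_lt(mean(rel), 0.02)
})

test_that("fasting-only estimates are flagged as the lowest-confidence pattern", {
  g <- generate_cohort(default_config(), seed = 23)
  suite <- train_imputation_suite(g$cohort, seed = 24)
  r2 <- vapply(suite$models, `[[`, numeric(1), "adjusted_r2_test")
  expect_lt(r2[["glucose_auc|0"]], r2[["glucose_auc|0,30,60"]])

  one <- apply_missingness(g$cohort[1:5, ] |> as.data.frame() |>
                             as_cohort(comorbidities = comorbidity_names(g$cohort)),
                           availability_pattern(glucose = 0, insulin = 0),
                           fraction = 1, seed = 25)
  f <- impute_features(one, suite)
  expect_true(all(f$glucose_imputed))
  expect_equal(f$glucose_r2, rep(r2[["glucose_auc|0"]], 5))
})

test_that("an unseen availability pattern raises a no-model error listing patterns", {
  g <- generate_cohort(default_config(n = 200), seed = 26)
  suite <- train_imputation_suite(
    g$cohort, patterns = list(availability_pattern(glucose = c(0, 60), insulin = c(0, 60))),
    seed = 27)
  miss <- apply_missingness(g$cohort, availability_pattern(glucose = c(0, 30),
                                                           insulin = c(0, 30)),
                            fraction = 1, seed = 28)
  err <- expect_error(impute_features(miss, suite), class = "obty_error_pattern")
  expect_match(conditionMessage(err), "glucose_auc\\|0,60")
})
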