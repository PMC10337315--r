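test_that("the linear predictor applies cT grouping and named coefficients", {
  tbl <- tibble::tibble(cT = c("2", "3", "4a", "4b", "1"),
                        glcm_sum_entropy = c(1.5, 2, 0, 3, -1))
  m0 <- logistic_model_spec("null", 0, 0, "glcm_sum_entropy", 0)
  expect_equal(linear_predictor(m0, tbl), rep(0, 5))

  m1 <- logistic_model_spec("ct", 2.73, -2.8, "glcm_sum_entropy", 0)
  expect_equal(linear_predictor(m1, tbl[2, ]), -0.07)
  expect_equal(linear_predictor(m1, tbl[5, ]), 2.73)
  # 4b grouped with 3-4a
  expect_equal(linear_predictor(m1, tbl[4, ]), -0.07)

  m2 <- logistic_model_spec("f", 0, 0, "glcm_sum_entropy", 2)
  expect_equal(linear_predictor(m2, tbl[1, ]), 3.0)
  m3 <- logistic_model_spec("missing", 0, 0, "not_a_feature", 1)
  expect_error(linear_predictor(m3, tbl), "not_a_feature")
})

test_that("the probability transform is the logistic function", {
  expect_equal(predict_probability(0), 0.5)
  x <- c(-3, -0.5, 0.2, 4)
  expect_equal(predict_probability(x) + predict_probability(-x), rep(1, 4))
  expect_equal(predict_probability(-0.07), 0.4825, tolerance = 1e-4)
  expect_error(predict_probability(c(1, Inf)), "finite")
})

test_that("AUC equals Mann-Whitney pair counting, including ties", {
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(auc(rep(0.3, 8), rep(c(0, 1), 4)), 0.5)
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc(1:4, rep(1, 4)), "classes")
  for (seed in 1:6) {
    n <- c(10, 30, 200, 50, 120, 200)[seed]
    withr::with_seed(seed, {
      scores <- sample(seq(0, 1, 0.05), n, replace = TRUE) # force ties
      labels <- rbinom(n, 1, 0.4)
    })
    if (length(unique(labels)) < 2) next
    expect_identical(auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("bootstrap intervals are deterministic, degenerate-safe and calibrated", {
  const <- tibble::tibble(x = rep(2.5, 40))
  ci <- bootstrap_ci(const, function(d) mean(d$x), n_replicates = 100, seed = 1)
  expect_equal(ci$lo, ci$hi)
  expect_equal(ci$lo, 2.5)

  dat <- tibble::tibble(x = withr::with_seed(2, rnorm(60)))
  a <- bootstrap_ci(dat, function(d) mean(d$x), n_replicates = 200, seed = 7)
  b <- bootstrap_ci(dat, function(d) mean(d$x), n_replicates = 200, seed = 7)
  expect_identical(a[c("lo", "hi")], b[c("lo", "hi")])

  covered <- 0
  for (s in 1:100) {
    d <- tibble::tibble(x = withr::with_seed(1000 + s, rnorm(500)))
    ci <- bootstrap_ci(d, function(dd) mean(dd$x), n_replicates = 200,
                       seed = s)
    covered <- covered + (ci$lo <= 0 && 0 <= ci$hi)
  }
  expect_gte(covered, 90)

  # statistic that is never defined: the failure budget must trip
  expect_error(
    bootstrap_ci(tibble::tibble(y = rnorm(20)),
                 function(d) stop("undefined"),
                 n_replicates = 50, seed = 1),
    "replicate|undefined")
})

test_that("calibration recovers slope and intercept of the generating model", {
  withr::with_seed(11, {
    logo <- rnorm(5000, 0, 1.5)
    y <- rbinom(5000, 1, plogis(logo))
  })
  cal <- calibration(logo, y)
  expect_gt(cal$slope, 0.9); expect_lt(cal$slope, 1.1)
  expect_gt(cal$intercept, -0.1); expect_lt(cal$intercept, 0.1)

  # shifted predictors: offset intercept estimates -shift
  cal_shift <- calibration(logo + 0.8, y)
  expect_equal(cal_shift$intercept, -0.8, tolerance = 0.1)
})

test_that("calibration matches a Newton MLE oracle and detects separation", {
  logo <- c(-2, -1, 0, 1, 2)
  y <- c(0, 1, 0, 1, 1)
  cal <- calibration(logo, y)
  o <- oracle_logistic_mle(logo, y)
  expect_equal(cal$slope, o$slope, tolerance = 1e-6)
  expect_equal(cal$intercept, o$offset_intercept, tolerance = 1e-6)
  cal_j <- calibration(logo, y, intercept_method = "joint")
  expect_equal(cal_j$intercept, o$intercept, tolerance = 1e-6)

  expect_error(calibration(c(-2, -1, 1, 2), c(0, 0, 1, 1)), "separation")
})

test_that("recalibrated predictions are a calibration fixed point", {
  withr::with_seed(3, {
    logo <- rnorm(400, 0, 2)
    y <- rbinom(400, 1, plogis(0.7 * logo - 0.5))
  })
  cal <- calibration(logo, y, intercept_method = "joint")
  logo2 <- cal$intercept + cal$slope * logo
  cal2 <- calibration(logo2, y, intercept_method = "joint")
  expect_equal(cal2$slope, 1, tolerance = 1e-6)
  expect_equal(cal2$intercept, 0, tolerance = 1e-6)
  expect_equal(calibration(logo2, y)$intercept, 0, tolerance = 1e-6)
})

test_that("the sensitivity-constrained threshold maximises specificity", {
  op <- threshold_at_sensitivity(c(.9, .8, .7, .2, .1), c(1, 1, 1, 0, 0), 0.9)
  expect_equal(op$threshold, 0.7)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)

  perfect <- threshold_at_sensitivity(c(.9, .8, .2, .1), c(1, 1, 0, 0), 0.9)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  # target 0: the constraint is vacuous at the largest threshold
  op0 <- threshold_at_sensitivity(c(.9, .8, .2), c(1, 0, 0), 0)
  expect_equal(op0$threshold, 0.9)
  expect_equal(op0$specificity, 1)
  expect_error(threshold_at_sensitivity(c(.5), c(1), 1.2), "target")
})

test_that("validating the true generative model gives near-ideal calibration", {
  cfg <- tiny_sim_config(n_patients = 800, seed = 17)
  clin <- generate_clinical_cohort(cfg)
  om <- cfg$outcome_model
  # the model's native orientation predicts TRG 1: negate the latent model
  truth <- logistic_model_spec("truth", -om$intercept, -om$ct_effect,
                               "heterogeneity", -om$heterogeneity_effect)
  rep <- validate_model(truth, clin, n_boot = 200, seed = 5)
  expect_gt(rep$calibration_slope, 0.85)
  expect_lt(rep$calibration_slope, 1.15)
  expect_lt(abs(rep$calibration_intercept), 0.15)
  expect_gt(rep$auc, 0.6)
  expect_gte(rep$sensitivity, 0.9)
  expect_true(all(c(rep$auc, rep$specificity, rep$ppv, rep$npv,
                    rep$accuracy) >= 0))
  expect_true(all(c(rep$auc, rep$specificity, rep$ppv, rep$npv,
                    rep$accuracy) <= 1))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$auc, rep$auc)
})

test_that("a noise-only model has an AUC interval covering 0.5", {
  cfg <- tiny_sim_config(n_patients = 300, seed = 23)
  clin <- generate_clinical_cohort(cfg)
  clin$noise_feature <- withr::with_seed(99, rnorm(nrow(clin)))
  noise <- logistic_model_spec("noise", 0, 0, "noise_feature", 1)
  rep <- validate_model(noise, clin, n_boot = 400, seed = 8)
  expect_lte(rep$auc_ci[1], 0.5)
  expect_gte(rep$auc_ci[2], 0.5)
})
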