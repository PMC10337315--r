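test_that("TRG dichotomisation follows the endpoint definitions", {
  expect_identical(dichotomise_trg(1, "trg234"), 0L)
  expect_identical(dichotomise_trg(2, "trg34"), 0L)
  expect_identical(dichotomise_trg(4, "trg234"), 1L)
  expect_identical(dichotomise_trg(4, "trg34"), 1L)
  expect_identical(dichotomise_trg(1:5, "trg234"), c(0L, 1L, 1L, 1L, 1L))
  expect_identical(dichotomise_trg(1:5, "trg34"), c(0L, 0L, 1L, 1L, 1L))
  expect_error(dichotomise_trg(0), "1..5")
  expect_error(dichotomise_trg(c(2, 6)), "1..5")
})

test_that("per-scanner standardisation removes location and scale per group", {
  tbl <- noise_feature_table(80, 4, seed = 1)
  out <- standardise_per_scanner(tbl)
  for (sc in unique(out$scanner)) {
    for (f in feature_columns(out)) {
      x <- out[[f]][out$scanner == sc]
      expect_lt(abs(mean(x)), 1e-9)
      expect_lt(abs(sd(x) - 1), 1e-9)
    }
  }
  expect_s3_class(attr(out, "scaling"), "tbl_df")

  # single scanner equals global z-scoring
  tbl1 <- noise_feature_table(40, 3, seed = 2, scanners = "only")
  out1 <- standardise_per_scanner(tbl1)
  f <- feature_columns(tbl1)[1]
  expect_equal(out1[[f]], as.vector(scale(tbl1[[f]])), tolerance = 1e-12)

  # idempotence
  out2 <- standardise_per_scanner(out)
  expect_equal(out2[feature_columns(out2)], out[feature_columns(out)],
               tolerance = 1e-9, ignore_attr = TRUE)

  # gain-shifted copies become identically distributed across scanners
  base <- withr::with_seed(3, rnorm(50))
  tbl3 <- tibble::tibble(stat_f = c(base, 1.7 * base),
                         scanner = rep(c("a", "b"), each = 50))
  out3 <- standardise_per_scanner(tbl3, features = "stat_f")
  expect_equal(sort(out3$stat_f[out3$scanner == "a"]),
               sort(out3$stat_f[out3$scanner == "b"]), tolerance = 1e-12)

  tbl4 <- tibble::tibble(stat_f = c(rep(1, 5), withr::with_seed(4, rnorm(5))),
                         scanner = rep(c("a", "b"), each = 5))
  expect_warning(out4 <- standardise_per_scanner(tbl4, features = "stat_f"),
                 "zero variance")
  expect_true(all(out4$stat_f[out4$scanner == "a"] == 0))
})

test_that("an injected multiplicative scanner effect is undetectable after standardisation", {
  n <- 200
  withr::with_seed(5, {
    tbl <- tibble::tibble(
      scanner = rep(c("a", "b"), each = n),
      stat_a = rnorm(2 * n, 2, 0.5) * rep(c(1, 1.4), each = n),
      stat_b = rnorm(2 * n, 5, 1.0) * rep(c(1, 0.7), each = n),
      glcm_c = rnorm(2 * n, 0, 1.0) + rep(c(0, 0.8), each = n)
    )
  })
  feats <- c("stat_a", "stat_b", "glcm_c")
  before <- vapply(feats, function(f) {
    t.test(tbl[[f]][tbl$scanner == "a"], tbl[[f]][tbl$scanner == "b"])$p.value
  }, numeric(1))
  expect_true(any(before < 0.01))
  out <- standardise_per_scanner(tbl, features = feats)
  after <- vapply(feats, function(f) {
    t.test(out[[f]][out$scanner == "a"], out[[f]][out$scanner == "b"])$p.value
  }, numeric(1))
  expect_true(all(after > 0.1))
})

test_that("the correlation filter removes exactly the redundant columns", {
  withr::with_seed(7, {
    a <- rnorm(100)
    tbl <- tibble::tibble(stat_a = a, stat_b = a, stat_c = rnorm(100))
  })
  kept <- correlation_filter(tbl, cutoff = 0.9)
  expect_length(kept, 2)
  expect_true("stat_c" %in% kept)
  expect_length(intersect(c("stat_a", "stat_b"), kept), 1)

  # cutoff 1 with no perfect collinearity keeps everything
  tbl2 <- noise_feature_table(50, 5, seed = 8)
  expect_length(correlation_filter(tbl2, cutoff = 1), 5)

  # postcondition: surviving pairwise |r| <= cutoff, by direct recomputation
  withr::with_seed(9, {
    z <- matrix(rnorm(80 * 3), 80, 3)
    x <- cbind(z, z %*% matrix(rnorm(9), 3) + 0.1 * matrix(rnorm(80 * 3), 80))
    colnames(x) <- sprintf("stat_x%d", 1:6)
  })
  tbl3 <- tibble::as_tibble(as.data.frame(x))
  kept3 <- correlation_filter(tbl3, cutoff = 0.7)
  r <- abs(cor(tbl3[, as.character(kept3)]))
  diag(r) <- 0
  expect_lte(max(r), 0.7)
})

test_that("the LASSO recovers true effects and stays sparse under pure noise", {
  n <- 300; p <- 30
  withr::with_seed(21, {
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- sprintf("stat_v%02d", 1:p)
    eta <- 1.5 * x[, 3] - 1.5 * x[, 17]
    y <- rbinom(n, 1, plogis(eta))
  })
  tbl <- tibble::as_tibble(as.data.frame(x))
  fit <- fit_lasso(tbl, y, seed = 2)
  expect_true(all(c("stat_v03", "stat_v17") %in% fit$selected$variable))
  expect_gt(fit$selected$coefficient[fit$selected$variable == "stat_v03"], 0)
  expect_lt(fit$selected$coefficient[fit$selected$variable == "stat_v17"], 0)
  expect_error(fit_lasso(tbl, rep(1, n)), "single class")

  # null simulation: under the sparser 1-SE penalty rule, pure noise gives
  # at most a couple of spurious selections in the large majority of runs
  hits <- 0
  for (s in 1:50) {
    tbl0 <- noise_feature_table(300, 30, seed = 400 + s)
    y0 <- withr::with_seed(500 + s, rbinom(300, 1, 0.4))
    f0 <- fit_lasso(tbl0, y0, lambda_rule = "1se", seed = s)
    hits <- hits + (nrow(f0$selected) <= 2)
  }
  expect_gte(hits, 40)
})

test_that("optimism correction behaves at its degenerate and typical limits", {
  tbl <- noise_feature_table(120, 8, seed = 31)
  y <- withr::with_seed(32, rbinom(120, 1, plogis(1.2 * tbl$stat_f01)))
  oc0 <- optimism_corrected_auc(tbl, y, n_bootstrap = 1, refilter = FALSE,
                                identity_resample = TRUE, seed = 3)
  expect_equal(oc0$optimism, 0)
  expect_equal(oc0$corrected, oc0$apparent)

  oc <- optimism_corrected_auc(tbl, y, n_bootstrap = 25, refilter = FALSE,
                               seed = 4)
  expect_lte(oc$corrected, oc$apparent + 0.02)
  oc2 <- optimism_corrected_auc(tbl, y, n_bootstrap = 25, refilter = FALSE,
                                seed = 4)
  expect_identical(oc$corrected, oc2$corrected)
})

test_that("the extension pipeline prefers the informative texture feature", {
  # outcome driven by cT and one feature: the extended model must select
  # that feature and beat the clinical-only reference after correction
  n <- 400
  withr::with_seed(41, {
    tbl <- noise_feature_table(n, 10, seed = 42)
    eta <- -1.0 + 1.2 * as.numeric(tbl$cT == "3") + 1.5 * tbl$stat_f05
    trg <- ifelse(rbinom(n, 1, plogis(eta)) == 1, 3L, 1L)
  })
  tbl$TRG <- trg
  ext <- extend_model(tbl, endpoint = "trg234", n_bootstrap = 40, seed = 6)
  ref <- extend_model(tbl, endpoint = "trg234", clinical_only = TRUE,
                      n_bootstrap = 40, seed = 6)
  expect_true("stat_f05" %in% ext$selected_variables$variable)
  expect_gt(ext$optimism_corrected_auc, ref$optimism_corrected_auc)
  g <- glance(ext)
  expect_equal(g$optimism_corrected_auc, ext$optimism_corrected_auc)
})

test_that("the subsampling benchmark separates signal from noise", {
  # perfectly separable data
  n <- 120
  withr::with_seed(51, {
    tbl <- noise_feature_table(n, 4, seed = 52)
    y <- as.integer(tbl$stat_f01 > 0)
    tbl$stat_f01 <- tbl$stat_f01 + 10 * y # huge margin
  })
  bench <- subsampling_benchmark(tbl, y, n_partitions = 10, seed = 1,
                                 include_clinical = FALSE)
  expect_true(all(bench$mean_auc > 0.99))

  # pure noise: intervals cover 0.5, runs are seed-deterministic
  tbl0 <- noise_feature_table(150, 6, seed = 61)
  y0 <- withr::with_seed(62, rbinom(150, 1, 0.45))
  b1 <- subsampling_benchmark(tbl0, y0, n_partitions = 25, seed = 9)
  b2 <- subsampling_benchmark(tbl0, y0, n_partitions = 25, seed = 9)
  expect_identical(b1$mean_auc, b2$mean_auc)
  expect_true(all(b1$auc_lo <= 0.5 & b1$auc_hi >= 0.5))
})
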