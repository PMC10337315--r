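test_that("config validation rejects malformed probability inputs", {
  expect_error(sim_config(trg_probs = c(0.5, 0.5, 0.2, 0, -0.2)), "trg_probs")
  expect_error(sim_config(ct_probs = c(`1` = 0.6, `2` = 0.6, `3` = 0,
                                       `4a` = 0)), "ct_probs")
  expect_error(sim_config(n_patients = 1), "n_patients")
  expect_error(sim_config(scanner_profiles = list()), "scanner")
})

test_that("a degenerate TRG distribution yields an all-TRG-1 cohort", {
  cfg <- tiny_sim_config(n_patients = 30, seed = 4,
                         trg_probs = c(1, 0, 0, 0, 0))
  clin <- generate_clinical_cohort(cfg)
  expect_true(all(clin$TRG == 1L))
})

test_that("clinical generation is seed-deterministic", {
  cfg <- tiny_sim_config(n_patients = 40, seed = 9)
  expect_identical(generate_clinical_cohort(cfg), generate_clinical_cohort(cfg))
})

test_that("empirical marginals track the configured distributions", {
  cfg <- sim_config(n_patients = 2000, seed = 3)
  clin <- generate_clinical_cohort(cfg)
  n <- nrow(clin)
  se <- function(p) sqrt(p * (1 - p) / n)
  # TRG-1 prevalence emulating the pooled cohorts
  expect_lt(abs(mean(clin$TRG == 1) - 0.214), 3 * se(0.214))
  expect_lt(abs(mean(clin$sex == "M") - cfg$sex_prob), 3 * se(cfg$sex_prob))
  expect_lt(abs(mean(clin$histology == "AC") - cfg$histology_prob),
            3 * se(cfg$histology_prob))
  p3 <- unname(cfg$ct_probs["3"])
  expect_lt(abs(mean(clin$cT == "3") - p3), 3 * se(p3))
  # advanced cT stage raises the residual-tumour rate (latent model works)
  r12 <- mean(clin$TRG[clin$cT %in% c("1", "2")] >= 2)
  r34 <- mean(clin$TRG[clin$cT %in% c("3", "4a")] >= 2)
  expect_gt(r34, r12 + 0.15)
})

test_that("a uniform lesion with no blur or noise is exactly flat in-mask", {
  cfg <- tiny_sim_config(
    n_patients = 2, seed = 5,
    scanner_profiles = list(scanner_profile("flat", psf_fwhm_mm = 0,
                                            noise_sd = 0, gain = 1))
  )
  cfg$lesion$base_amp <- 0
  cfg$lesion$amp_residual <- 0
  clin <- generate_clinical_cohort(cfg)
  meta <- generate_acquisition_meta(cfg, clin)
  st <- generate_pet_study(clin[1, ], meta[1, ], cfg)
  vals <- mask_values(st$volume, st$mask)
  expect_lt(diff(range(vals)), 1e-12)
})

test_that("gain is an exact multiplicative factor on the whole volume", {
  mk <- function(gain) {
    tiny_sim_config(n_patients = 2, seed = 6,
                    scanner_profiles = list(
                      scanner_profile("s", psf_fwhm_mm = 5, noise_sd = 0.05,
                                      gain = gain)))
  }
  c1 <- mk(1); c2 <- mk(2)
  clin <- generate_clinical_cohort(c1)
  meta <- generate_acquisition_meta(c1, clin)
  v1 <- generate_pet_study(clin[1, ], meta[1, ], c1)$volume
  v2 <- generate_pet_study(clin[1, ], meta[1, ], c2)$volume
  expect_equal(v2$values, 2 * v1$values, tolerance = 1e-12)
})

test_that("residual-tumour lesions are more heterogeneous than TRG-1 lesions", {
  cfg <- tiny_sim_config(n_patients = 2, seed = 13)
  clin1 <- tibble::tibble(patient_id = sprintf("a%03d", 1:50), TRG = 1L,
                          scanner = "gemini",
                          heterogeneity = withr::with_seed(1, rnorm(50)))
  clin2 <- tibble::tibble(patient_id = sprintf("b%03d", 1:50), TRG = 4L,
                          scanner = "gemini",
                          heterogeneity = withr::with_seed(2, rnorm(50)))
  meta <- list(injected_dose_bq = 250e6, body_weight_kg = 80,
               serum_glucose_mmol_l = 5.5)
  invar <- function(clin) {
    vapply(seq_len(nrow(clin)), function(i) {
      st <- generate_pet_study(clin[i, ], meta, cfg)
      var(mask_values(st$volume, st$mask))
    }, numeric(1))
  }
  expect_gt(mean(invar(clin2)), mean(invar(clin1)))
})

test_that("cohort bundles are complete, reproducible and self-consistent", {
  cfg <- tiny_sim_config(n_patients = 3, seed = 21)
  d1 <- file.path(withr::local_tempdir(), "b1")
  d2 <- file.path(withr::local_tempdir(), "b2")
  b1 <- generate_cohort(cfg, d1)
  b2 <- generate_cohort(cfg, d2)
  expect_length(list.files(d1, pattern = "_pet\\.nii$"), 3)
  expect_length(list.files(d1, pattern = "_mask\\.nii$"), 3)
  clin <- readr::read_csv(file.path(d1, "clinical.csv"), show_col_types = FALSE)
  expect_equal(nrow(clin), 3)
  expect_identical(names(clin), c("patient_id", "cohort", "age", "sex",
                                  "histology", "cT", "cN", "TRG", "scanner"))
  # regeneration with the same seed is byte-identical
  for (f in c("clinical.csv", "metadata.csv", "latent.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # round trip: recomputed TRG-1 count equals the manifest count
  rb <- read_cohort(d1)
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(sum(rb$clinical$TRG == 1), manifest$trg1_count)
  expect_true(all(file.exists(rb$index$volume_path)))
})

test_that("scanner profiles shift downstream intensity features detectably", {
  profiles <- list(scanner_profile("low", psf_fwhm_mm = 5, noise_sd = 0.04,
                                   gain = 0.9),
                   scanner_profile("high", psf_fwhm_mm = 7.5, noise_sd = 0.08,
                                   gain = 1.2))
  cfg <- tiny_sim_config(n_patients = 2, seed = 31,
                         scanner_profiles = profiles)
  meta <- list(injected_dose_bq = 250e6, body_weight_kg = 80,
               serum_glucose_mmol_l = 5.5)
  mean_suv <- function(scanner, seeds) {
    vapply(seeds, function(s) {
      rec <- tibble::tibble(patient_id = sprintf("%s%03d", scanner, s),
                            TRG = 2L, scanner = scanner,
                            heterogeneity = withr::with_seed(s, rnorm(1)))
      st <- generate_pet_study(rec, meta, cfg)
      mean(mask_values(to_suv(st$volume, meta), st$mask))
    }, numeric(1))
  }
  a <- mean_suv("low", 1:40)
  b <- mean_suv("high", 41:80)
  expect_lt(t.test(a, b)$p.value, 0.01)
})
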