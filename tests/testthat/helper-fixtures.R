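# Shared fixture builders; everything is generated in code at test time.

# A pet_volume/tumour_mask pair from an explicit array with a full mask.
roi_pair <- function(values, spacing = c(2, 2, 2), units = "suv_glucose") {
  arr <- if (is.array(values)) values else array(values, c(length(values), 1, 1))
  list(
    volume = pet_volume(arr, spacing = spacing, units = units),
    mask = tumour_mask(array(1, dim(arr)), spacing = spacing)
  )
}

# Random small ROI with an irregular mask, for oracle-equivalence suites.
random_droi <- function(dims, ng = 4, seed = 1, mask_prob = 0.85) {
  withr::with_seed(seed, {
    vals <- array(runif(prod(dims)), dims)
    msk <- array(as.numeric(runif(prod(dims)) < mask_prob), dims)
    if (sum(msk) < 2) msk[1:2] <- 1
    vol <- pet_volume(vals, spacing = c(2, 2, 2), units = "suv_glucose")
    discretise(vol, tumour_mask(msk, spacing = c(2, 2, 2)), bin_param = ng)
  })
}

# Small, fast simulation config: coarse grid, small lesion, mild noise.
tiny_sim_config <- function(n_patients = 12, seed = 1, ...) {
  sim_config(
    n_patients = n_patients,
    grid = list(dim = c(32, 32, 24), spacing_mm = c(4, 4, 3)),
    lesion = list(semi_axes_mm = c(10, 9, 12), background_suv = 0.8,
                  tube_suv = 1.5, tube_radius_mm = 8, lesion_suv = 2.5,
                  residual_suv_shift = 0.4, base_amp = 0.25,
                  amp_h_scale = 0.3, amp_residual = 0.5,
                  texture_corr_mm = 6),
    seed = seed,
    ...
  )
}

# Feature table with pure-noise features and clinical columns, for the
# model-extension machinery.
noise_feature_table <- function(n, p, seed = 1, scanners = c("a", "b")) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- sprintf("stat_f%02d", seq_len(p))
    tibble::as_tibble(as.data.frame(x)) |>
      dplyr::mutate(
        patient_id = sprintf("pt%04d", seq_len(n)),
        scanner = sample(scanners, n, replace = TRUE),
        cT = sample(c("2", "3"), n, replace = TRUE),
        cN = sample(c("0", "1"), n, replace = TRUE),
        age = round(runif(n, 50, 80)),
        sex = sample(c("M", "F"), n, replace = TRUE),
        histology = sample(c("AC", "SCC"), n, replace = TRUE)
      )
  })
}
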