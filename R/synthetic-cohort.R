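#' Scanner profile
#'
#' Describes a scanner model's systematic effect on reconstructed images:
#' point-spread blur (FWHM in mm), additive noise (SD in pre-gain SUV
#' units) and a multiplicative gain (sensitivity calibration). These are
#' invented effect sizes - no per-scanner magnitudes are published for
#' the cohorts being emulated - chosen to produce clearly detectable
#' between-scanner feature shifts that per-scanner standardisation must
#' remove.
#'
#' @param name Scanner identifier.
#' @param psf_fwhm_mm Gaussian point-spread FWHM (mm), `>= 0`.
#' @param noise_sd Additive noise SD in pre-gain SUV units, `>= 0`.
#' @param gain Multiplicative intensity scale, `> 0`, applied last.
#' @return A list of class `scanner_profile`.
#' @export
scanner_profile <- function(name, psf_fwhm_mm = 6, noise_sd = 0.05, gain = 1) {
  if (!isTRUE(psf_fwhm_mm >= 0)) abort("psf_fwhm_mm must be >= 0.")
  if (!isTRUE(noise_sd >= 0)) abort("noise_sd must be >= 0.")
  if (!isTRUE(gain > 0)) abort("gain must be > 0.")
  structure(list(name = name, psf_fwhm_mm = psf_fwhm_mm,
                 noise_sd = noise_sd, gain = gain),
            class = "scanner_profile")
}

default_scanner_profiles <- function() {
  list(
    scanner_profile("vereos", psf_fwhm_mm = 5, noise_sd = 0.04, gain = 0.90),
    scanner_profile("gemini", psf_fwhm_mm = 6.5, noise_sd = 0.06, gain = 1.00),
    scanner_profile("biograph", psf_fwhm_mm = 7.5, noise_sd = 0.08, gain = 1.20)
  )
}

check_probs <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    abort(sprintf("`%s` must be a probability vector summing to 1.", what))
  }
  invisible(p)
}

#' Simulation configuration for the synthetic PET cohort
#'
#' Defines a two-cohort, multi-scanner synthetic dataset whose marginals
#' emulate the pooled development + external-validation oesophageal-cancer
#' cohorts (262 patients): TRG-1 prevalence ~0.21, ~82% male, ~81%
#' adenocarcinoma, cT dominated by cT3, and a latent logistic outcome
#' model in which the probability of residual tumour (TRG 2-5) depends on
#' advanced cT stage and a per-patient lesion-heterogeneity latent. The
#' model intercept is calibrated deterministically (quadrature +
#' root-finding) so the configured TRG-1 marginal is matched exactly in
#' expectation.
#'
#' @param n_patients Number of patients, `>= 2`.
#' @param cohort_split Named probability vector over cohorts.
#' @param trg_probs Probability vector over TRG grades 1-5.
#' @param ct_probs Named probability vector over cT stages 1, 2, 3, 4a.
#' @param cn_probs Named probability vector over cN stages 0-3.
#' @param cnx_prob Probability of a cNx (unassessable) stage, about one
#'   patient per 200, exercising the cN0/cNx grouping rule.
#' @param sex_prob Probability of male sex.
#' @param histology_prob Probability of adenocarcinoma.
#' @param scanner_profiles List of [scanner_profile()]s.
#' @param cohort_scanner_probs Named list: per-cohort probability vector
#'   over scanner profiles (distinct mixes emulate single-centre
#'   development vs multi-centre validation).
#' @param outcome_model List with `ct_effect`, `heterogeneity_effect` and
#'   optionally `intercept` (calibrated to the TRG-1 marginal when `NULL`)
#'   on the log-odds-of-residual-tumour scale.
#' @param grid List with `dim` (voxels) and `spacing_mm`; the default
#'   64 x 64 x 48 at 4 x 4 x 3 mm is PET-like and anisotropic so the 2 mm
#'   resampling step is non-trivial.
#' @param lesion Lesion/phantom geometry and texture parameters (SUV
#'   units); see Details in the package vignette.
#' @param seed Integer seed; all generator output is reproducible given
#'   the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 262,
                       cohort_split = c(development = 73 / 262,
                                        validation = 189 / 262),
                       trg_probs = c(0.214, 0.279, 0.286, 0.190, 0.031),
                       ct_probs = c(`1` = 0.004, `2` = 0.191,
                                    `3` = 0.759, `4a` = 0.046),
                       cn_probs = c(`0` = 0.313, `1` = 0.424,
                                    `2` = 0.236, `3` = 0.027),
                       cnx_prob = 0.005,
                       sex_prob = 0.824,
                       histology_prob = 0.809,
                       scanner_profiles = default_scanner_profiles(),
                       cohort_scanner_probs = NULL,
                       outcome_model = list(ct_effect = 2.8,
                                            heterogeneity_effect = 1.0,
                                            intercept = NULL),
                       grid = list(dim = c(64, 64, 48),
                                   spacing_mm = c(4, 4, 3)),
                       lesion = list(semi_axes_mm = c(12, 10, 16),
                                     background_suv = 0.8,
                                     tube_suv = 1.5,
                                     tube_radius_mm = 8,
                                     lesion_suv = 2.5,
                                     residual_suv_shift = 0.4,
                                     base_amp = 0.25,
                                     amp_h_scale = 0.3,
                                     amp_residual = 0.5,
                                     texture_corr_mm = 6),
                       seed = 1L) {
  if (!isTRUE(n_patients >= 2)) abort("n_patients must be >= 2.")
  check_probs(cohort_split, "cohort_split")
  check_probs(trg_probs, "trg_probs")
  check_probs(ct_probs, "ct_probs")
  check_probs(cn_probs, "cn_probs")
  stopifnot(length(trg_probs) == 5)
  if (length(scanner_profiles) < 1) abort("at least one scanner profile.")
  sc_names <- vapply(scanner_profiles, `[[`, character(1), "name")
  names(scanner_profiles) <- sc_names
  if (is.null(cohort_scanner_probs)) {
    k <- length(sc_names)
    cohort_scanner_probs <- lapply(seq_along(cohort_split), function(ci) {
      if (ci == 1 || k == 1) {
        setNames(c(1, rep(0, k - 1)), sc_names)
      } else {
        setNames(rep(1 / k, k), sc_names)
      }
    })
    names(cohort_scanner_probs) <- names(cohort_split)
  }
  cfg <- structure(
    list(n_patients = as.integer(n_patients), cohort_split = cohort_split,
         trg_probs = trg_probs, ct_probs = ct_probs, cn_probs = cn_probs,
         cnx_prob = cnx_prob, sex_prob = sex_prob,
         histology_prob = histology_prob,
         scanner_profiles = scanner_profiles,
         cohort_scanner_probs = cohort_scanner_probs,
         outcome_model = outcome_model, grid = grid, lesion = lesion,
         seed = as.integer(seed)),
    class = "sim_config"
  )
  if (is.null(cfg$outcome_model$intercept)) {
    cfg$outcome_model$intercept <- calibrate_intercept(cfg)
  }
  cfg
}

# Solve E[plogis(a + b*ct34 + c*h)] = 1 - P(TRG 1) with h ~ N(0,1) by
# fixed quadrature + root finding; deterministic, no simulation.
calibrate_intercept <- function(config) {
  p1 <- config$trg_probs[1]
  if (p1 >= 1 - 1e-12) return(-Inf)
  if (p1 <= 1e-12) return(Inf)
  b <- config$outcome_model$ct_effect
  cc <- config$outcome_model$heterogeneity_effect
  p34 <- sum(config$ct_probs[names(config$ct_probs) %in% c("3", "4a", "4b")])
  h <- seq(-8, 8, length.out = 401)
  w <- stats::dnorm(h); w <- w / sum(w)
  target <- 1 - p1
  f <- function(a) {
    sum(w * ((1 - p34) * plogis(a + cc * h) + p34 * plogis(a + b + cc * h))) -
      target
  }
  uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Generate the synthetic clinical table
#'
#' One record per patient with cohort label, demographics, clinical
#' stage, assigned scanner, the latent lesion-heterogeneity value, and a
#' TRG grade drawn from the latent logistic outcome model (TRG 1 vs
#' residual from the model; grade within the residual arm from the
#' configured conditional distribution). Reproducible given the config
#' seed.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `patient_id`, `cohort`, `age`, `sex`,
#'   `histology`, `cT`, `cN`, `TRG`, `scanner`, and the generator-internal
#'   `heterogeneity` latent.
#' @export
generate_clinical_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  om <- config$outcome_model
  withr::with_seed(child_seed(config$seed, 1L), {
    cohort <- sample(names(config$cohort_split), n, replace = TRUE,
                     prob = config$cohort_split)
    age <- pmin(pmax(round(rnorm(n, 66, 8)), 30), 90)
    sex <- sample(c("M", "F"), n, replace = TRUE,
                  prob = c(config$sex_prob, 1 - config$sex_prob))
    histology <- sample(c("AC", "SCC"), n, replace = TRUE,
                        prob = c(config$histology_prob,
                                 1 - config$histology_prob))
    ct <- sample(names(config$ct_probs), n, replace = TRUE,
                 prob = config$ct_probs)
    cn <- ifelse(runif(n) < config$cnx_prob, "x",
                 sample(names(config$cn_probs), n, replace = TRUE,
                        prob = config$cn_probs))
    scanner <- character(n)
    for (co in names(config$cohort_scanner_probs)) {
      sel <- cohort == co
      if (!any(sel)) next
      pr <- config$cohort_scanner_probs[[co]]
      scanner[sel] <- sample(names(pr), sum(sel), replace = TRUE, prob = pr)
    }
    h <- rnorm(n)
    ct34 <- as.numeric(ct %in% c("3", "4a", "4b"))
    p_resid <- plogis(om$intercept + om$ct_effect * ct34 +
                        om$heterogeneity_effect * h)
    residual <- rbinom(n, 1, p_resid)
    trg <- integer(n)
    trg[residual == 0] <- 1L
    if (any(residual == 1)) {
      pr <- config$trg_probs[2:5]
      pr <- if (sum(pr) > 0) pr / sum(pr) else c(1, 0, 0, 0)
      trg[residual == 1] <- sample(2:5, sum(residual == 1), replace = TRUE,
                                   prob = pr)
    }
    tibble(
      patient_id = sprintf("pt%04d", seq_len(n)),
      cohort = cohort, age = age, sex = sex, histology = histology,
      cT = ct, cN = cn, TRG = trg, scanner = scanner, heterogeneity = h
    )
  })
}

#' Generate per-patient acquisition metadata
#'
#' Injected dose (weight-based, ~3 MBq/kg), body weight, serum glucose
#' and scan timing after chemoradiotherapy; all strictly positive.
#'
#' @param config A [sim_config()].
#' @param clinical Output of [generate_clinical_cohort()].
#' @return Tibble with `patient_id`, `injected_dose_bq`, `body_weight_kg`,
#'   `serum_glucose_mmol_l`, `scan_weeks_post_ncrt`, `scanner`.
#' @export
generate_acquisition_meta <- function(config, clinical) {
  n <- nrow(clinical)
  withr::with_seed(child_seed(config$seed, 2L), {
    weight <- pmin(pmax(rnorm(n, 80, 12), 45), 130)
    dose <- weight * 3e6 * exp(rnorm(n, 0, 0.05))
    glucose <- pmin(pmax(rnorm(n, 5.5, 0.8), 3.5), 9)
    weeks <- runif(n, 6, 12)
    tibble(
      patient_id = clinical$patient_id,
      injected_dose_bq = dose,
      body_weight_kg = weight,
      serum_glucose_mmol_l = glucose,
      scan_weeks_post_ncrt = weeks,
      scanner = clinical$scanner
    )
  })
}

patient_stream <- function(patient_id) {
  100L + sum(utf8ToInt(patient_id) * seq_along(utf8ToInt(patient_id)))
}

#' Generate one synthetic PET study
#'
#' Builds an activity-concentration volume containing a smooth background
#' field, an oesophagus-like tube along the craniocaudal axis, and an
#' ellipsoidal lesion whose intra-lesion texture amplitude grows with the
#' patient's latent heterogeneity and with residual-tumour status (TRG
#' 2-5). The assigned scanner profile is then applied: Gaussian PSF blur,
#' additive noise, and gain as the final multiplicative step. The mask
#' covers the lesion ellipsoid. Voxel spacing is anisotropic by default.
#'
#' @param record One row of the clinical table (needs `patient_id`,
#'   `TRG`, `scanner` and, if present, `heterogeneity`).
#' @param meta Matching row of the acquisition metadata.
#' @param config A [sim_config()].
#' @return List with `volume` (a [pet_volume()] in activity units) and
#'   `mask` (a [tumour_mask()]).
#' @export
generate_pet_study <- function(record, meta, config) {
  stopifnot(inherits(config, "sim_config"))
  gd <- config$grid$dim
  sp <- config$grid$spacing_mm
  L <- config$lesion
  h <- if (!is.null(record$heterogeneity)) record$heterogeneity else 0
  residual <- as.numeric(record$TRG >= 2)
  profile <- config$scanner_profiles[[record$scanner]]
  if (is.null(profile)) {
    abort(paste0("unknown scanner profile: ", record$scanner))
  }

  withr::with_seed(child_seed(config$seed, patient_stream(record$patient_id)), {
    # world coordinates of voxel centres
    wx <- (seq_len(gd[1]) - 1) * sp[1]
    wy <- (seq_len(gd[2]) - 1) * sp[2]
    wz <- (seq_len(gd[3]) - 1) * sp[3]
    centre <- c(max(wx), max(wy), max(wz)) / 2

    grf <- function(corr_mm) {
      z <- array(rnorm(prod(gd)), gd)
      f <- blur3d(z, corr_mm / 2.355 / sp)
      f / max(sd(f), 1e-12)
    }

    img <- L$background_suv * (1 + 0.08 * grf(20))

    r2 <- outer((wx - centre[1])^2, (wy - centre[2])^2, `+`)
    tube2d <- r2 <= L$tube_radius_mm^2
    tube <- array(rep(tube2d, gd[3]), gd)
    img[tube] <- L$tube_suv

    dx2 <- ((wx - centre[1]) / L$semi_axes_mm[1])^2
    dy2 <- ((wy - centre[2]) / L$semi_axes_mm[2])^2
    dz2 <- ((wz - centre[3]) / L$semi_axes_mm[3])^2
    ell <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    if (sum(ell) < 1) abort("lesion generation produced an empty mask.")

    amp <- L$base_amp * exp(L$amp_h_scale * h) + L$amp_residual * residual
    lesion_vals <- L$lesion_suv + L$residual_suv_shift * residual +
      amp * grf(L$texture_corr_mm)
    img[ell] <- lesion_vals[ell]

    # scanner model: PSF blur, additive noise, gain last (linearity in gain)
    if (profile$psf_fwhm_mm > 0) {
      img <- blur3d(img, profile$psf_fwhm_mm / 2.355 / sp)
    }
    if (profile$noise_sd > 0) {
      img <- img + array(rnorm(prod(gd), 0, profile$noise_sd), gd)
    }
    img <- img * profile$gain

    # store as activity concentration consistent with the patient's meta
    k <- meta$injected_dose_bq / (meta$body_weight_kg * 1000)
    list(
      volume = pet_volume(img * k, spacing = sp, units = "activity"),
      mask = tumour_mask(array(as.numeric(ell), gd), spacing = sp)
    )
  })
}

#' Generate and write a full synthetic cohort bundle
#'
#' Writes per-patient NIfTI volume and mask files, the clinical CSV
#' (`patient_id,cohort,age,sex,histology,cT,cN,TRG,scanner`), the
#' acquisition-metadata CSV, a generator-internal latent CSV, and a JSON
#' manifest indexing every artefact.
#'
#' @param config A [sim_config()].
#' @param out_dir Writable output directory (created if needed).
#' @return Invisibly, a list with the `clinical` and `meta` tibbles, the
#'   per-patient file `index` tibble, and the `manifest` path.
#' @export
generate_cohort <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(paste0("cannot create output directory: ", out_dir))
  }
  clinical <- generate_clinical_cohort(config)
  meta <- generate_acquisition_meta(config, clinical)

  vol_paths <- file.path(out_dir, paste0(clinical$patient_id, "_pet.nii"))
  mask_paths <- file.path(out_dir, paste0(clinical$patient_id, "_mask.nii"))
  for (i in seq_len(nrow(clinical))) {
    study <- generate_pet_study(clinical[i, ], meta[i, ], config)
    tryCatch(
      write_pet_study(study$volume, study$mask, vol_paths[i], mask_paths[i]),
      error = function(e) abort(paste0("failed writing '", vol_paths[i],
                                       "': ", conditionMessage(e)))
    )
  }

  write_one <- function(df, path) {
    tryCatch(readr::write_csv(df, path),
             error = function(e) abort(paste0("failed writing '", path, "'")))
    path
  }
  clin_path <- write_one(
    dplyr::select(clinical, "patient_id", "cohort", "age", "sex", "histology",
                  "cT", "cN", "TRG", "scanner"),
    file.path(out_dir, "clinical.csv")
  )
  meta_path <- write_one(
    dplyr::select(meta, "patient_id", "injected_dose_bq", "body_weight_kg",
                  "serum_glucose_mmol_l", "scan_weeks_post_ncrt"),
    file.path(out_dir, "metadata.csv")
  )
  latent_path <- write_one(
    dplyr::select(clinical, "patient_id", "heterogeneity"),
    file.path(out_dir, "latent.csv")
  )

  manifest <- list(
    n_patients = nrow(clinical),
    trg1_count = sum(clinical$TRG == 1),
    seed = config$seed,
    config_hash = config_hash(deparse(config[setdiff(names(config),
                                                     "scanner_profiles")])),
    clinical_csv = basename(clin_path),
    metadata_csv = basename(meta_path),
    latent_csv = basename(latent_path),
    volumes = basename(vol_paths),
    masks = basename(mask_paths)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(
    clinical = clinical, meta = meta,
    index = tibble(patient_id = clinical$patient_id,
                   volume_path = vol_paths, mask_path = mask_paths),
    manifest = manifest_path
  ))
}

#' Read a cohort bundle written by [generate_cohort()]
#'
#' @param dir Bundle directory containing `manifest.json`.
#' @return List with `clinical`, `meta`, `index` (file paths) and the
#'   parsed `manifest`.
#' @export
read_cohort <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) abort(paste0("no manifest.json in ", dir))
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  clinical <- readr::read_csv(file.path(dir, manifest$clinical_csv),
                              show_col_types = FALSE)
  meta <- readr::read_csv(file.path(dir, manifest$metadata_csv),
                          show_col_types = FALSE)
  if (!is.null(manifest$latent_csv) &&
      file.exists(file.path(dir, manifest$latent_csv))) {
    latent <- readr::read_csv(file.path(dir, manifest$latent_csv),
                              show_col_types = FALSE)
    clinical <- dplyr::left_join(clinical, latent, by = "patient_id")
  }
  list(
    clinical = clinical, meta = meta,
    index = tibble(patient_id = clinical$patient_id,
                   volume_path = file.path(dir, manifest$volumes),
                   mask_path = file.path(dir, manifest$masks)),
    manifest = manifest
  )
}
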