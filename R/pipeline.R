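#' Crop a study to the mask bounding box
#'
#' Restricts a volume/mask pair to the mask's bounding box plus a margin.
#' Texture features only see in-mask voxels, so cropping before
#' resampling changes nothing downstream while keeping the interpolation
#' cheap.
#'
#' @param volume A [pet_volume()].
#' @param mask A [tumour_mask()] on the same grid.
#' @param margin_mm Margin around the bounding box, in mm.
#' @return List with cropped `volume` and `mask`.
#' @export
crop_to_mask <- function(volume, mask, margin_mm = 12) {
  stopifnot_same_grid(volume, mask)
  idx <- which(mask$values > 0.5, arr.ind = TRUE)
  d <- dim(mask$values)
  mar <- ceiling(margin_mm / volume$spacing)
  lo <- pmax(apply(idx, 2, min) - mar, 1)
  hi <- pmin(apply(idx, 2, max) + mar, d)
  v <- volume$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  m <- mask$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  origin <- volume$origin + (lo - 1) * volume$spacing
  list(
    volume = pet_volume(array(v, hi - lo + 1), volume$spacing, origin,
                        units = volume$units),
    mask = tumour_mask(array(m, hi - lo + 1), mask$spacing, origin)
  )
}

#' Preprocess one PET study
#'
#' Activity to SUV, serum-glucose correction, crop to the mask
#' neighbourhood, and resampling to the uniform isotropic grid (volume:
#' trilinear; mask: nearest neighbour).
#'
#' @param volume A [pet_volume()] in activity units.
#' @param mask A [tumour_mask()] on the same grid.
#' @param meta List/row with `injected_dose_bq`, `body_weight_kg`,
#'   `serum_glucose_mmol_l`.
#' @param target_mm Target isotropic spacing (mm).
#' @param glucose_reference Reference glucose (mmol/L).
#' @param crop_margin_mm Crop margin; `NULL` disables cropping.
#' @return List with preprocessed `volume` and `mask`.
#' @export
preprocess_study <- function(volume, mask, meta, target_mm = c(2, 2, 2),
                             glucose_reference = 5.0, crop_margin_mm = 12) {
  v <- to_suv(volume, meta)
  v <- glucose_correct(v, meta$serum_glucose_mmol_l, glucose_reference)
  if (!is.null(crop_margin_mm)) {
    cr <- crop_to_mask(v, mask, crop_margin_mm)
    v <- cr$volume; mask <- cr$mask
  }
  vr <- resample_isotropic(v, target_mm)
  mr <- resample_mask(mask, vr)
  list(volume = vr, mask = mr)
}

#' Extract features for a whole cohort bundle
#'
#' Reads every study in a [generate_cohort()] bundle, preprocesses it and
#' extracts the radiomic feature vector, returning the feature table:
#' clinical covariates, scanner label, and one column per feature.
#'
#' @param bundle A [read_cohort()] result or a bundle directory.
#' @param config A [feature_config()].
#' @param target_mm,glucose_reference,crop_margin_mm Passed to
#'   [preprocess_study()].
#' @return Feature table (tibble), one row per patient.
#' @export
extract_cohort_features <- function(bundle, config = feature_config(),
                                    target_mm = c(2, 2, 2),
                                    glucose_reference = 5.0,
                                    crop_margin_mm = 12) {
  if (is.character(bundle)) bundle <- read_cohort(bundle)
  rows <- purrr::map(seq_len(nrow(bundle$index)), function(i) {
    study <- read_pet_study(bundle$index$volume_path[i],
                            bundle$index$mask_path[i])
    meta <- bundle$meta[i, ]
    pp <- preprocess_study(study$volume, study$mask, meta,
                           target_mm = target_mm,
                           glucose_reference = glucose_reference,
                           crop_margin_mm = crop_margin_mm)
    extract_features(pp$volume, pp$mask, config)
  })
  dplyr::bind_cols(bundle$clinical, dplyr::bind_rows(rows))
}

#' Pipeline configuration
#'
#' @param sim A [sim_config()].
#' @param out_dir Output directory for all stage artefacts.
#' @param features A [feature_config()].
#' @param target_mm,glucose_reference,crop_margin_mm Preprocessing
#'   settings.
#' @param models_path JSON file of [logistic_model_spec()]s; defaults to
#'   the synthetic placeholder six-model file shipped with the package.
#' @param endpoint Extension endpoint.
#' @param n_boot Bootstrap replicates for validation CIs.
#' @param n_bootstrap Bootstrap resamples for optimism correction.
#' @param seed Global seed; per-stage streams are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir,
                            features = feature_config(),
                            target_mm = c(2, 2, 2), glucose_reference = 5.0,
                            crop_margin_mm = 12,
                            models_path = system.file("extdata",
                                                      "models_synthetic.json",
                                                      package = "petrad"),
                            endpoint = "trg234", n_boot = 2000,
                            n_bootstrap = 200, seed = 1) {
  structure(
    list(sim = sim, out_dir = out_dir, features = features,
         target_mm = target_mm, glucose_reference = glucose_reference,
         crop_margin_mm = crop_margin_mm, models_path = models_path,
         endpoint = endpoint, n_boot = n_boot, n_bootstrap = n_bootstrap,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

stage_hash <- function(config, stage) {
  strip <- config[setdiff(names(config), "out_dir")]
  config_hash(paste(stage, paste(deparse(strip), collapse = "")))
}

#' Run the end-to-end pipeline
#'
#' Executes simulation, feature extraction, external validation, model
#' extension and cohort statistics in order, writing one artefact per
#' stage under `config$out_dir` plus a run manifest. Stages whose output
#' already exists with a matching config hash are skipped; the whole run
#' is deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list), invisibly written to
#'   `run_manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "run_manifest.json")
  old <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  stages <- list()

  run_stage <- function(name, outputs, fun) {
    h <- stage_hash(config, name)
    done <- !is.null(old) && !is.null(old$stages[[name]]) &&
      identical(old$stages[[name]]$hash, h) &&
      all(file.exists(file.path(out, outputs)))
    if (done) {
      stages[[name]] <<- list(hash = h, outputs = outputs, skipped = TRUE)
      return(invisible(NULL))
    }
    tryCatch(fun(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    stages[[name]] <<- list(hash = h, outputs = outputs, skipped = FALSE)
  }

  bundle_dir <- file.path(out, "cohort")
  run_stage("simulate", file.path("cohort", "manifest.json"), function() {
    generate_cohort(config$sim, bundle_dir)
  })

  features_path <- file.path(out, "features.csv")
  run_stage("features", "features.csv", function() {
    ft <- extract_cohort_features(bundle_dir, config$features,
                                  target_mm = config$target_mm,
                                  glucose_reference = config$glucose_reference,
                                  crop_margin_mm = config$crop_margin_mm)
    readr::write_csv(dplyr::select(ft, -dplyr::any_of("heterogeneity")),
                     features_path)
  })

  run_stage("validate", "validation.json", function() {
    ft <- readr::read_csv(features_path, show_col_types = FALSE)
    models <- load_model_specs(config$models_path)
    reports <- purrr::map_dfr(models, function(m) {
      tidy(validate_model(m, ft, endpoint = "trg234",
                          n_boot = config$n_boot,
                          seed = child_seed(config$seed, 11L)))
    })
    jsonlite::write_json(reports, file.path(out, "validation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  })

  run_stage("extend", "extension.json", function() {
    ft <- readr::read_csv(features_path, show_col_types = FALSE)
    ext <- extend_model(ft, endpoint = config$endpoint,
                        n_bootstrap = config$n_bootstrap,
                        seed = child_seed(config$seed, 12L))
    ref <- extend_model(ft, endpoint = config$endpoint, clinical_only = TRUE,
                        n_bootstrap = config$n_bootstrap,
                        seed = child_seed(config$seed, 13L))
    res <- list(
      radiomic_clinical = c(glance(ext),
                            list(selected = ext$selected_variables)),
      clinical_only = c(glance(ref), list(selected = ref$selected_variables))
    )
    jsonlite::write_json(res, file.path(out, "extension.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  })

  run_stage("stats", "cohort_stats.csv", function() {
    clin <- readr::read_csv(file.path(bundle_dir, "clinical.csv"),
                            show_col_types = FALSE)
    cohorts <- split(clin, clin$cohort)
    if (length(cohorts) >= 2) {
      rep <- compare_cohorts(cohorts[[1]], cohorts[[2]])
      readr::write_csv(rep, file.path(out, "cohort_stats.csv"))
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("petrad")),
    seed = config$seed,
    config_hash = stage_hash(config, "all"),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = stages
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
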