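#' Logistic model specification
#'
#' A published prediction model of the form
#' `LogO = intercept + coef_ct * 1[cT in 3/4a/4b] + coef_feature * feature`,
#' the linear predictor of the probability of complete response (TRG 1).
#' cT4b is grouped with cT3-4a.
#'
#' @param name Model identifier.
#' @param intercept,coef_ct,coef_feature Real coefficients.
#' @param feature_name Name of the radiomic feature column the model uses.
#' @return A list of class `logistic_model_spec`.
#' @export
logistic_model_spec <- function(name, intercept, coef_ct,
                                feature_name, coef_feature) {
  for (v in list(intercept, coef_ct, coef_feature)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(sprintf("model '%s': coefficients must be finite numbers.", name))
    }
  }
  structure(list(name = name, intercept = intercept, coef_ct = coef_ct,
                 feature_name = feature_name, coef_feature = coef_feature),
            class = "logistic_model_spec")
}

#' Load logistic model specifications from JSON
#'
#' Expects a JSON array of objects with exactly the fields `name`,
#' `intercept`, `coef_ct`, `feature_name`, `coef_feature`; unknown fields
#' are rejected to catch typos in hand-edited specs.
#'
#' @param path Path to a JSON file.
#' @return List of [logistic_model_spec()]s.
#' @export
load_model_specs <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(raw) == 0) abort("no models in spec file.")
  required <- c("name", "intercept", "coef_ct", "feature_name", "coef_feature")
  lapply(raw, function(m) {
    missing <- setdiff(required, names(m))
    if (length(missing) > 0) {
      abort(sprintf("model '%s': missing field(s) %s",
                    m$name %||% "<unnamed>", paste(missing, collapse = ", ")))
    }
    extra <- setdiff(names(m), required)
    if (length(extra) > 0) {
      abort(sprintf("model '%s': unknown field(s) %s",
                    m$name, paste(extra, collapse = ", ")))
    }
    for (f in c("intercept", "coef_ct", "coef_feature")) {
      if (!is.numeric(m[[f]])) {
        abort(sprintf("model '%s': field '%s' must be numeric.", m$name, f))
      }
    }
    logistic_model_spec(m$name, m$intercept, m$coef_ct,
                        m$feature_name, m$coef_feature)
  })
}

ct_indicator <- function(ct) {
  ct <- as.character(ct)
  known <- c("1", "2", "3", "4a", "4b")
  if (any(!ct %in% known)) {
    abort(paste0("unknown cT stage: ",
                 paste(unique(ct[!ct %in% known]), collapse = ", ")))
  }
  as.numeric(ct %in% c("3", "4a", "4b"))
}

#' Linear predictor of a published model
#'
#' @param model A [logistic_model_spec()].
#' @param table A feature table with columns `cT` and the model's feature.
#' @return Numeric vector of linear predictors (log-odds of TRG 1).
#' @export
linear_predictor <- function(model, table) {
  if (!model$feature_name %in% names(table)) {
    abort(paste0("feature not found in table: ", model$feature_name))
  }
  model$intercept + model$coef_ct * ct_indicator(table$cT) +
    model$coef_feature * table[[model$feature_name]]
}

#' Logistic transform of a linear predictor
#'
#' @param logo Numeric vector of log-odds.
#' @return Probabilities in (0, 1).
#' @export
predict_probability <- function(logo) {
  if (any(!is.finite(logo))) abort("linear predictor must be finite.")
  plogis(logo)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = (concordant + 0.5 * tied) / (n1 * n0)` over all case-control
#' pairs, computed via midranks (exact, including ties).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary outcome (0/1 or logical).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) abort("length mismatch.")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both outcome classes must be present.")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Seeded nonparametric bootstrap percentile interval
#'
#' Resamples rows of `data` with replacement; replicates on which the
#' statistic is undefined (error or `NA`, e.g. a single-outcome-class
#' resample) are redrawn. Errors if more than half of the attempted
#' replicates fail.
#'
#' @param data A data frame of patient-level rows.
#' @param statistic Function `data -> numeric(1)`.
#' @param n_replicates Number of bootstrap replicates (2000 for reported
#'   confidence intervals).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return List with `lo`, `hi`, `level`, `replicates` (the statistic on
#'   each replicate) and `seed`.
#' @export
bootstrap_ci <- function(data, statistic, n_replicates = 2000, seed = 1,
                         level = 0.95) {
  n <- nrow(data)
  if (is.null(n) || n < 2) abort("data must have at least two rows.")
  withr::with_seed(as.integer(seed), {
    vals <- numeric(n_replicates)
    failures <- 0
    for (b in seq_len(n_replicates)) {
      v <- NA_real_
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        v <- tryCatch(statistic(data[idx, , drop = FALSE]),
                      error = function(e) NA_real_)
        if (is.finite(v)) break
        failures <- failures + 1
        if (failures > n_replicates / 2) {
          abort("statistic undefined on more than half of bootstrap replicates.")
        }
      }
      if (!is.finite(v)) {
        abort("bootstrap replicate failed repeatedly; data too degenerate.")
      }
      vals[b] <- v
    }
    alpha <- (1 - level) / 2
    ci <- quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
    list(lo = ci[1], hi = ci[2], level = level, replicates = vals,
         seed = as.integer(seed))
  })
}

#' Calibration slope and intercept
#'
#' Slope: coefficient of a logistic regression of outcomes on the linear
#' predictor (ideal 1). Intercept: calibration-in-the-large, the intercept
#' of a logistic fit with the linear predictor as a fixed offset (slope
#' fixed at 1; ideal 0). A joint-fit intercept (slope re-estimated) is
#' available behind `intercept_method = "joint"`.
#'
#' @param logos Numeric linear predictors (log-odds).
#' @param labels Binary outcomes.
#' @param intercept_method `"offset"` (default) or `"joint"`.
#' @return List with `slope` and `intercept`.
#' @export
calibration <- function(logos, labels, intercept_method = c("offset", "joint")) {
  intercept_method <- match.arg(intercept_method)
  labels <- as.numeric(labels)
  if (any(!is.finite(logos))) abort("linear predictors must be finite.")
  if (length(unique(labels)) < 2) abort("both outcome classes must be present.")
  if (min(logos[labels == 1]) > max(logos[labels == 0]) ||
      max(logos[labels == 1]) < min(logos[labels == 0])) {
    abort("perfect separation: calibration fit does not converge.")
  }
  # near-separation triggers harmless fitted-0/1 notices in resamples;
  # hard separation is caught above
  slope_fit <- suppressWarnings(glm(labels ~ logos, family = binomial()))
  slope <- unname(coef(slope_fit)[2])
  intercept <- if (intercept_method == "offset") {
    unname(coef(suppressWarnings(
      glm(labels ~ 1 + offset(logos), family = binomial())))[1])
  } else {
    unname(coef(slope_fit)[1])
  }
  list(slope = slope, intercept = intercept)
}

#' Operating point at a target sensitivity
#'
#' Chooses the largest observed score threshold `t` such that
#' `sensitivity(score >= t) >= target` - the threshold maximising
#' specificity subject to the sensitivity constraint, ties broken toward
#' the larger threshold - and reports the confusion-matrix metrics there.
#'
#' @param probs Numeric scores (predicted probabilities of the positive
#'   class).
#' @param labels Binary outcomes.
#' @param target Target sensitivity in \[0, 1\].
#' @return List with `threshold`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy`.
#' @export
threshold_at_sensitivity <- function(probs, labels, target = 0.90) {
  labels <- as.numeric(labels)
  if (!isTRUE(target >= 0 && target <= 1)) abort("target must be in [0, 1].")
  if (sum(labels == 1) == 0) abort("no positive cases.")
  cand <- sort(unique(probs), decreasing = TRUE)
  npos <- sum(labels == 1)
  for (t in cand) {
    sens <- sum(probs >= t & labels == 1) / npos
    if (sens >= target) {
      pred <- as.numeric(probs >= t)
      tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
      tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
      return(list(
        threshold = t,
        sensitivity = tp / (tp + fn),
        specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
        ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
        npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
        accuracy = (tp + tn) / length(labels)
      ))
    }
  }
  abort("no threshold attains the target sensitivity.") # unreachable: t = min
}

#' Externally validate a published model on a feature table
#'
#' Computes, for one [logistic_model_spec()], the full external-validation
#' report: AUC with a bootstrap percentile CI, calibration slope and
#' intercept with CIs (on the model's native TRG-1 log-odds), and the
#' operating point at the target sensitivity for the configured positive
#' class (default: residual tumour, using `1 - P(TRG 1)` as the score).
#'
#' @param model A [logistic_model_spec()].
#' @param table Feature table with `cT`, `TRG`, and the model's feature.
#' @param endpoint `"trg234"` (TRG 1 vs 2-5, default) or `"trg34"`.
#' @param target_sensitivity Sensitivity at which the operating point is
#'   reported (0.90, the endoscopy benchmark for residual-tumour
#'   detection).
#' @param n_boot Bootstrap replicates for all CIs.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `validation_report`.
#' @export
validate_model <- function(model, table, endpoint = c("trg234", "trg34"),
                           target_sensitivity = 0.90, n_boot = 2000,
                           seed = 1) {
  endpoint <- match.arg(endpoint)
  positive <- dichotomise_trg(table$TRG, endpoint)
  logo <- linear_predictor(model, table)
  p_trg1 <- predict_probability(logo)
  score <- 1 - p_trg1 # probability of the positive (residual) class

  a <- auc(score, positive)
  dat <- tibble(score = score, logo = logo, y = positive)
  auc_ci <- bootstrap_ci(dat, function(d) auc(d$score, d$y),
                         n_replicates = n_boot, seed = seed)
  cal <- calibration(logo, 1 - positive) # native orientation: P(TRG 1)
  slope_ci <- bootstrap_ci(dat, function(d) calibration(d$logo, 1 - d$y)$slope,
                           n_replicates = n_boot, seed = seed + 1)
  int_ci <- bootstrap_ci(dat, function(d) calibration(d$logo, 1 - d$y)$intercept,
                         n_replicates = n_boot, seed = seed + 2)
  op <- threshold_at_sensitivity(score, positive, target_sensitivity)

  structure(
    list(model = model$name, endpoint = endpoint, n = nrow(table),
         auc = a, auc_ci = c(auc_ci$lo, auc_ci$hi),
         calibration_slope = cal$slope,
         calibration_slope_ci = c(slope_ci$lo, slope_ci$hi),
         calibration_intercept = cal$intercept,
         calibration_intercept_ci = c(int_ci$lo, int_ci$hi),
         threshold = op$threshold, sensitivity = op$sensitivity,
         specificity = op$specificity, ppv = op$ppv, npv = op$npv,
         accuracy = op$accuracy, target_sensitivity = target_sensitivity,
         n_boot = n_boot, seed = as.integer(seed),
         scores = score, labels = positive),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> model %s (%s, n = %d)\n",
              x$model, x$endpoint, x$n))
  cat(sprintf("  AUC %.3f (%.3f-%.3f)\n", x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  calibration slope %.3f (%.3f-%.3f), intercept %.3f (%.3f-%.3f)\n",
              x$calibration_slope, x$calibration_slope_ci[1],
              x$calibration_slope_ci[2], x$calibration_intercept,
              x$calibration_intercept_ci[1], x$calibration_intercept_ci[2]))
  cat(sprintf("  at sens %.0f%%: thresh %.3f, spec %.2f, PPV %.2f, NPV %.2f, acc %.2f\n",
              100 * x$target_sensitivity, x$threshold, x$specificity,
              x$ppv, x$npv, x$accuracy))
  invisible(x)
}

#' @export
tidy.validation_report <- function(x, ...) {
  tibble(
    model = x$model, endpoint = x$endpoint, n = x$n,
    auc = x$auc, auc_lo = x$auc_ci[1], auc_hi = x$auc_ci[2],
    calibration_slope = x$calibration_slope,
    calibration_slope_lo = x$calibration_slope_ci[1],
    calibration_slope_hi = x$calibration_slope_ci[2],
    calibration_intercept = x$calibration_intercept,
    calibration_intercept_lo = x$calibration_intercept_ci[1],
    calibration_intercept_hi = x$calibration_intercept_ci[2],
    threshold = x$threshold, sensitivity = x$sensitivity,
    specificity = x$specificity, ppv = x$ppv, npv = x$npv,
    accuracy = x$accuracy
  )
}

#' @export
glance.validation_report <- function(x, ...) {
  tibble(model = x$model, endpoint = x$endpoint, n = x$n, auc = x$auc,
         calibration_slope = x$calibration_slope,
         calibration_intercept = x$calibration_intercept)
}

#' @export
autoplot.validation_report <- function(object, ...) {
  thr <- c(Inf, sort(unique(object$scores), decreasing = TRUE))
  roc <- purrr::map_dfr(thr, function(t) {
    pred <- object$scores >= t
    tibble(
      tpr = sum(pred & object$labels == 1) / sum(object$labels == 1),
      fpr = sum(pred & object$labels == 0) / sum(object$labels == 0)
    )
  })
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("Model %s: AUC %.2f (%.2f-%.2f)",
                      object$model, object$auc,
                      object$auc_ci[1], object$auc_ci[2])
    ) +
    ggplot2::theme_minimal()
}
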