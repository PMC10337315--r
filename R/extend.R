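#' Dichotomise a tumour regression grade
#'
#' Chirieac grades: TRG 1 = 0% residual tumour, TRG 2 = 1-10%,
#' TRG 3 = 11-50%, TRG 4 = >50% (grade 5 is grouped with 4). The primary
#' endpoint `"trg234"` marks any residual tumour (TRG >= 2) positive; the
#' secondary endpoint `"trg34"` marks substantial residual tumour
#' (TRG >= 3) positive.
#'
#' @param trg Integer grades in 1-5.
#' @param endpoint `"trg234"` or `"trg34"`.
#' @return Integer 0/1 vector.
#' @export
dichotomise_trg <- function(trg, endpoint = c("trg234", "trg34")) {
  endpoint <- match.arg(endpoint)
  trg <- as.integer(trg)
  if (any(is.na(trg)) || any(!trg %in% 1:5)) {
    abort("TRG grades must be integers in 1..5.")
  }
  if (endpoint == "trg234") as.integer(trg >= 2) else as.integer(trg >= 3)
}

#' Standardise features per scanner model
#'
#' Within each scanner group every feature column is centred and scaled to
#' mean 0, SD 1, removing multiplicative and additive scanner batch
#' effects that are constant within a scanner. Zero-variance features
#' within a scanner are set to 0 for that scanner with a warning. The
#' per-scanner means and SDs are retained in the `"scaling"` attribute
#' for reuse on new data.
#'
#' @param table Feature table with a `scanner` column.
#' @param features Feature column names; defaults to [feature_columns()].
#' @return The table with standardised features (tibble); scaling
#'   parameters in `attr(, "scaling")`.
#' @export
standardise_per_scanner <- function(table, features = NULL) {
  if (!"scanner" %in% names(table)) abort("table needs a `scanner` column.")
  features <- features %||% feature_columns(table)
  if (length(features) == 0) abort("no feature columns found.")
  counts <- table(table$scanner)
  if (any(counts < 2)) {
    abort("every scanner group needs at least 2 patients.")
  }
  scaling <- list()
  out <- table
  for (sc in names(counts)) {
    sel <- table$scanner == sc
    for (f in features) {
      x <- table[[f]][sel]
      m <- mean(x); s <- sd(x)
      if (!is.finite(s) || s < 1e-12) {
        warn(sprintf("feature '%s' has zero variance within scanner '%s'; set to 0.",
                     f, sc))
        out[[f]][sel] <- 0
        s <- NA_real_
      } else {
        out[[f]][sel] <- (x - m) / s
      }
      scaling[[length(scaling) + 1]] <- tibble(scanner = sc, feature = f,
                                               mean = m, sd = s)
    }
  }
  attr(out, "scaling") <- dplyr::bind_rows(scaling)
  out
}

#' Greedy pairwise correlation filter
#'
#' Repeatedly finds the feature pair with the largest absolute Pearson
#' correlation above the cutoff and drops the member with the larger mean
#' absolute correlation to all remaining features; deterministic given
#' column order. On return no surviving pair has `|r| > cutoff`.
#'
#' @param table Feature table.
#' @param cutoff Absolute-correlation cutoff in (0, 1].
#' @param features Candidate columns; defaults to [feature_columns()].
#' @return Character vector of kept feature names, with the dropped names
#'   in `attr(, "removed")`.
#' @export
correlation_filter <- function(table, cutoff = 0.9, features = NULL) {
  if (!isTRUE(cutoff > 0 && cutoff <= 1)) abort("cutoff must be in (0, 1].")
  features <- features %||% feature_columns(table)
  x <- as.matrix(table[, features, drop = FALSE])
  if (!is.numeric(x)) abort("features must be numeric columns.")
  # constant columns have undefined correlations; treat as uncorrelated
  suppressWarnings(r <- abs(cor(x)))
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  keep <- rep(TRUE, ncol(r))
  removed <- character(0)
  repeat {
    rr <- r[keep, keep, drop = FALSE]
    if (length(rr) == 0 || max(rr) <= cutoff) break
    w <- which(rr == max(rr), arr.ind = TRUE)[1, ]
    pair <- colnames(rr)[w]
    mac <- colMeans(r[keep, keep, drop = FALSE])[pair]
    drop <- pair[which.max(mac)] # ties resolved toward the first = column order
    removed <- c(removed, drop)
    keep[match(drop, colnames(r))] <- FALSE
  }
  out <- features[keep]
  attr(out, "removed") <- removed
  out
}

# Clinical covariates encoded for model matrices: cT3-4 indicator, cN+
# indicator (cNx grouped with cN0), age, male sex, squamous histology.
clinical_model_columns <- function(table,
                                   variables = c("cT", "cN", "age", "sex",
                                                 "histology")) {
  out <- list()
  if ("cT" %in% variables) out$clin_ct34 <- ct_indicator(table$cT)
  if ("cN" %in% variables) {
    out$clin_cn_pos <- as.numeric(!(as.character(table$cN) %in% c("0", "x")))
  }
  if ("age" %in% variables) out$clin_age <- as.numeric(table$age)
  if ("sex" %in% variables) out$clin_male <- as.numeric(table$sex == "M")
  if ("histology" %in% variables) {
    out$clin_scc <- as.numeric(table$histology == "SCC")
  }
  as_tibble(out)
}

#' Fit an L1-penalised (LASSO) logistic model
#'
#' Penalty chosen by seeded 10-fold cross-validated binomial deviance
#' (`"min"` rule by default, `"1se"` available). Returns the variables
#' with non-zero coefficients at the chosen penalty.
#'
#' @param table Feature table (features should already be standardised).
#' @param outcome Binary outcome vector, or the name of a 0/1 column.
#' @param features Predictor column names.
#' @param lambda_rule `"min"` or `"1se"`.
#' @param nfolds Cross-validation folds.
#' @param seed Integer seed for fold assignment.
#' @return Object of class `radiomic_lasso`: the `cv.glmnet` fit, the
#'   chosen `lambda`, and a `selected` tibble of non-zero coefficients.
#' @export
fit_lasso <- function(table, outcome, features = NULL,
                      lambda_rule = c("min", "1se"), nfolds = 10, seed = 1) {
  lambda_rule <- match.arg(lambda_rule)
  y <- if (is.character(outcome) && length(outcome) == 1) table[[outcome]] else outcome
  y <- as.numeric(y)
  if (length(unique(y)) < 2) abort("outcome has a single class.")
  features <- features %||% feature_columns(table)
  x <- as.matrix(table[, features, drop = FALSE])
  withr::with_seed(as.integer(seed), {
    foldid <- sample(rep(seq_len(nfolds), length.out = nrow(x)))
    cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                               foldid = foldid, type.measure = "deviance")
  })
  lambda <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  beta <- coef(cvfit, s = lambda)
  nz <- which(beta[-1] != 0)
  structure(
    list(cvfit = cvfit, lambda = lambda, lambda_rule = lambda_rule,
         features = features,
         intercept = beta[1],
         selected = tibble(variable = features[nz],
                           coefficient = beta[-1][nz]),
         seed = as.integer(seed)),
    class = "radiomic_lasso"
  )
}

#' @export
print.radiomic_lasso <- function(x, ...) {
  cat(sprintf("<radiomic_lasso> lambda (%s) = %.4g, %d of %d variables selected\n",
              x$lambda_rule, x$lambda, nrow(x$selected), length(x$features)))
  if (nrow(x$selected) > 0) print(x$selected)
  invisible(x)
}

#' @export
tidy.radiomic_lasso <- function(x, ...) {
  dplyr::bind_rows(
    tibble(variable = "(Intercept)", coefficient = x$intercept),
    x$selected
  )
}

#' @export
predict.radiomic_lasso <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  as.numeric(predict(object$cvfit, newx = x, s = object$lambda,
                     type = "response"))
}

#' Optimism-corrected AUC of the LASSO pipeline
#'
#' Harrell bootstrap optimism correction: the whole modelling pipeline
#' (optionally the correlation filter, then penalised fit including
#' cross-validated penalty selection) is refit on each bootstrap resample;
#' optimism is the mean difference between each resample-model's AUC on
#' its own resample and on the original data, and is subtracted from the
#' apparent AUC. Resamples with a single outcome class are redrawn.
#'
#' @param table Standardised feature table.
#' @param outcome Binary outcome vector or 0/1 column name.
#' @param features Predictor columns.
#' @param n_bootstrap Bootstrap resamples (200 by default).
#' @param refilter Re-run the correlation filter inside each resample.
#' @param correlation_cutoff Cutoff for the filter when `refilter = TRUE`.
#' @param lambda_rule,nfolds Passed to [fit_lasso()].
#' @param seed Integer seed.
#' @param identity_resample Replace every bootstrap resample by the
#'   original data (degenerate bootstrap with optimism exactly 0; for
#'   checking the correction machinery).
#' @return List with `apparent`, `corrected`, `optimism`, `fit` (the
#'   full-data [fit_lasso()] object) and `n_bootstrap`.
#' @export
optimism_corrected_auc <- function(table, outcome, features = NULL,
                                   n_bootstrap = 200, refilter = TRUE,
                                   correlation_cutoff = 0.9,
                                   lambda_rule = "min", nfolds = 10,
                                   seed = 1, identity_resample = FALSE) {
  y <- if (is.character(outcome) && length(outcome) == 1) table[[outcome]] else outcome
  y <- as.numeric(y)
  features <- features %||% feature_columns(table)

  fit_pipeline <- function(tbl, yy, fit_seed) {
    feats <- if (refilter && length(features) > 1) {
      as.character(correlation_filter(tbl, cutoff = correlation_cutoff,
                                      features = features))
    } else features
    fit_lasso(tbl, yy, features = feats, lambda_rule = lambda_rule,
              nfolds = nfolds, seed = fit_seed)
  }

  full_fit <- fit_pipeline(table, y, child_seed(seed, 0L))
  apparent <- auc(predict(full_fit, table), y)

  n <- nrow(table)
  optimism <- numeric(n_bootstrap)
  withr::with_seed(as.integer(seed), {
    boot_seeds <- sample.int(2^31 - 2, n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      repeat {
        idx <- if (identity_resample) seq_len(n) else
          sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2) break
      }
      bt <- table[idx, , drop = FALSE]
      bfit <- fit_pipeline(bt, y[idx], boot_seeds[b])
      auc_boot <- auc(predict(bfit, bt), y[idx])
      auc_orig <- auc(predict(bfit, table), y)
      optimism[b] <- auc_boot - auc_orig
    }
  })
  list(apparent = apparent, corrected = apparent - mean(optimism),
       optimism = mean(optimism), fit = full_fit,
       n_bootstrap = n_bootstrap, seed = as.integer(seed))
}

#' Extend a prediction model on the pooled cohorts
#'
#' The full model-extension workflow: per-scanner feature
#' standardisation, greedy correlation filtering (cutoff 0.9),
#' bootstrapped LASSO with optimism-corrected AUC (200 resamples), and
#' the 90%-sensitivity operating point of the apparent model. With
#' `clinical_only = TRUE` the radiomic features are dropped, giving the
#' clinical reference model.
#'
#' @param table Feature table with clinical columns (`cT`, `cN`, `age`,
#'   `sex`, `histology`), `scanner`, `TRG` and radiomic features.
#' @param endpoint `"trg234"` or `"trg34"`; see [dichotomise_trg()].
#' @param clinical_only Drop radiomic features (reference model).
#' @param correlation_cutoff,n_bootstrap,lambda_rule,seed Workflow
#'   parameters.
#' @param standardise Standardise features per scanner first (disable if
#'   the table is already standardised).
#' @return Object of class `extended_model`.
#' @export
extend_model <- function(table, endpoint = c("trg234", "trg34"),
                         clinical_only = FALSE, correlation_cutoff = 0.9,
                         n_bootstrap = 200, lambda_rule = "min", seed = 1,
                         standardise = TRUE) {
  endpoint <- match.arg(endpoint)
  y <- dichotomise_trg(table$TRG, endpoint)
  scaling <- NULL
  if (standardise && !clinical_only) {
    table <- standardise_per_scanner(table)
    scaling <- attr(table, "scaling")
  }
  clin <- clinical_model_columns(table)
  tbl <- dplyr::bind_cols(table, clin)
  predictors <- if (clinical_only) names(clin) else
    c(feature_columns(table), names(clin))
  kept <- correlation_filter(tbl, cutoff = correlation_cutoff,
                             features = predictors)
  oc <- optimism_corrected_auc(tbl, y, features = as.character(kept),
                               n_bootstrap = n_bootstrap, refilter = FALSE,
                               lambda_rule = lambda_rule, seed = seed)
  probs <- predict(oc$fit, tbl)
  op <- threshold_at_sensitivity(probs, y, 0.90)
  structure(
    list(endpoint = endpoint, clinical_only = clinical_only,
         selected_variables = oc$fit$selected,
         apparent_auc = oc$apparent,
         optimism_corrected_auc = oc$corrected,
         operating_point = op,
         scaling_parameters = scaling,
         removed_by_filter = attr(kept, "removed"),
         fit = oc$fit, n = nrow(tbl), n_bootstrap = n_bootstrap,
         seed = as.integer(seed)),
    class = "extended_model"
  )
}

#' @export
print.extended_model <- function(x, ...) {
  cat(sprintf("<extended_model> endpoint %s%s, n = %d\n", x$endpoint,
              if (x$clinical_only) " (clinical only)" else "", x$n))
  cat(sprintf("  apparent AUC %.3f, optimism-corrected %.3f (%d bootstraps)\n",
              x$apparent_auc, x$optimism_corrected_auc, x$n_bootstrap))
  cat(sprintf("  %d variables selected: %s\n", nrow(x$selected_variables),
              paste(x$selected_variables$variable, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.extended_model <- function(x, ...) x$selected_variables

#' @export
glance.extended_model <- function(x, ...) {
  tibble(endpoint = x$endpoint, clinical_only = x$clinical_only, n = x$n,
         n_selected = nrow(x$selected_variables),
         apparent_auc = x$apparent_auc,
         optimism_corrected_auc = x$optimism_corrected_auc)
}

#' Stratified-subsampling classifier benchmark
#'
#' The comparator workflow: over seeded training/validation partitions
#' stratified by outcome, features are pre-selected on the training part
#' by univariate AUC ranking, each configured classifier is fitted on the
#' training part, and its AUC is evaluated on the validation part.
#' Defaults: logistic regression, linear discriminant analysis, Gaussian
#' naive Bayes, and a random forest, over 100 partitions with a 2/3
#' training fraction.
#'
#' @param table Feature table (standardised) with clinical columns.
#' @param outcome Binary outcome vector or 0/1 column name.
#' @param classifiers Subset of `"logistic"`, `"lda"`, `"naive_bayes"`,
#'   `"random_forest"`.
#' @param n_partitions Number of partitions.
#' @param train_fraction Training fraction in (0, 1).
#' @param n_features Number of top-ranked radiomic features kept by the
#'   univariate pre-selection (clinical columns always enter).
#' @param include_clinical Add encoded clinical covariates.
#' @param seed Integer seed.
#' @return Object of class `subsampling_benchmark`: a tibble of
#'   per-classifier mean AUC and 95% percentile interval, with the
#'   per-partition AUCs in `attr(, "partitions")`.
#' @export
subsampling_benchmark <- function(table, outcome,
                                  classifiers = c("logistic", "lda",
                                                  "naive_bayes",
                                                  "random_forest"),
                                  n_partitions = 100, train_fraction = 2 / 3,
                                  n_features = 10, include_clinical = TRUE,
                                  seed = 1) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (!isTRUE(train_fraction > 0 && train_fraction < 1)) {
    abort("train_fraction must be in (0, 1).")
  }
  y <- if (is.character(outcome) && length(outcome) == 1) table[[outcome]] else outcome
  y <- as.numeric(y)
  feats <- feature_columns(table)
  clin <- if (include_clinical) clinical_model_columns(table) else NULL
  x_all <- dplyr::bind_cols(table[, feats, drop = FALSE], clin)

  res <- matrix(NA_real_, n_partitions, length(classifiers),
                dimnames = list(NULL, classifiers))
  withr::with_seed(as.integer(seed), {
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    for (p in seq_len(n_partitions)) {
      repeat {
        tr <- c(sample(idx1, max(1, round(train_fraction * length(idx1)))),
                sample(idx0, max(1, round(train_fraction * length(idx0)))))
        if (length(unique(y[tr])) == 2 && length(unique(y[-tr])) == 2) break
      }
      va <- setdiff(seq_along(y), tr)
      # univariate-AUC feature pre-selection on the training part only
      sel_feats <- feats
      if (length(feats) > n_features) {
        u <- vapply(feats, function(f) abs(auc(x_all[[f]][tr], y[tr]) - 0.5),
                    numeric(1))
        sel_feats <- names(sort(u, decreasing = TRUE))[seq_len(n_features)]
      }
      cols <- c(sel_feats, names(clin))
      xtr <- x_all[tr, cols, drop = FALSE]
      xva <- x_all[va, cols, drop = FALSE]
      ytr <- y[tr]
      for (cl in classifiers) {
        score <- switch(
          cl,
          logistic = {
            df <- data.frame(y = ytr, xtr)
            fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
            suppressWarnings(
              predict(fit, newdata = data.frame(xva), type = "response"))
          },
          lda = {
            fit <- MASS::lda(x = as.matrix(xtr), grouping = factor(ytr))
            predict(fit, newdata = as.matrix(xva))$posterior[, "1"]
          },
          naive_bayes = {
            fit <- e1071::naiveBayes(x = as.data.frame(xtr),
                                     y = factor(ytr))
            predict(fit, newdata = as.data.frame(xva), type = "raw")[, "1"]
          },
          random_forest = {
            fit <- randomForest::randomForest(x = as.data.frame(xtr),
                                              y = factor(ytr), ntree = 200)
            predict(fit, newdata = as.data.frame(xva), type = "prob")[, "1"]
          }
        )
        res[p, cl] <- auc(score, y[va])
      }
    }
  })
  summary <- purrr::map_dfr(classifiers, function(cl) {
    v <- res[, cl]
    ci <- quantile(v, c(.025, .975), names = FALSE)
    tibble(classifier = cl, mean_auc = mean(v), auc_lo = ci[1], auc_hi = ci[2],
           n_partitions = n_partitions)
  })
  structure(summary, partitions = as_tibble(as.data.frame(res)),
            class = c("subsampling_benchmark", class(summary)))
}

#' @export
autoplot.subsampling_benchmark <- function(object, ...) {
  parts <- attr(object, "partitions")
  long <- tidyr::pivot_longer(parts, cols = dplyr::everything(),
                              names_to = "classifier", values_to = "auc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$classifier, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "Validation AUC",
                  title = "Stratified-subsampling benchmark") +
    ggplot2::theme_minimal()
}
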