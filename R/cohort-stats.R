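#' Chi-squared test with continuity correction for a 2x2 table
#'
#' Yates-corrected Pearson chi-squared test (the correction clamps at
#' zero, so tables with `|ad - bc| <= n/2` give a statistic of exactly 0
#' and p = 1). Wraps [stats::chisq.test()] with `correct = TRUE`.
#'
#' @param tab 2x2 matrix of non-negative counts (rows = cohorts).
#' @return List with `statistic`, `p_value`, `df`.
#' @examples
#' # cN0/cNx vs cN+ in two cohorts of 73 and 189 patients
#' chi2_yates(matrix(c(15, 58, 68, 121), 2, byrow = TRUE))$p_value # 0.024
#' @export
chi2_yates <- function(tab) {
  tab <- as.matrix(tab)
  check_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate margin: a row or column of the table is all zero.")
  }
  res <- suppressWarnings(chisq.test(tab, correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       df = unname(res$parameter))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities, over all
#' tables with the observed margins, of tables no more probable than the
#' observed one. Wraps [stats::fisher.test()]. A degenerate margin gives
#' p = 1 with a warning (the table carries no information).
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  check_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("degenerate margin: Fisher p = 1 by convention.")
    return(1)
  }
  fisher.test(tab)$p.value
}

check_2x2 <- function(tab) {
  if (!all(dim(tab) == c(2, 2))) abort("table must be 2x2.")
  if (any(tab < 0) || sum(tab) == 0) {
    abort("counts must be non-negative with a positive total.")
  }
  invisible(tab)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank ties: exact two-sided p for combined
#' n <= 20 without ties, normal approximation with tie correction (and
#' continuity correction) otherwise. Wraps [stats::wilcox.test()]; the
#' reported `U` is the number of (x, y) pairs with x > y (+ half the
#' ties).
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` and `p_value`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  res <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(res$statistic), p_value = res$p.value)
}

#' Compare two cohorts variable by variable
#'
#' Reproduces the structure of a baseline-characteristics table:
#' categorical variables are dichotomised by the standard grouping rules
#' (cT1-2 vs cT3-4, cN0/cNx vs cN+, TRG 1 vs TRG 2-5, sex M vs F,
#' histology AC vs SCC) and compared with the continuity-corrected
#' chi-squared test, falling back to Fisher's exact test when any
#' expected cell count is below 5; continuous variables (age) use the
#' Mann-Whitney U test.
#'
#' @param clinical_a,clinical_b Clinical tibbles sharing the schema
#'   `age, sex, histology, cT, cN, TRG`.
#' @param variables Variables to compare.
#' @return Tibble with one row per variable: `variable`, `test`,
#'   `statistic`, `p_value`, and the per-cohort summaries.
#' @export
compare_cohorts <- function(clinical_a, clinical_b,
                            variables = c("sex", "age", "histology",
                                          "cT", "cN", "TRG")) {
  dich <- list(
    sex = function(d) d$sex == "M",
    histology = function(d) d$histology == "AC",
    cT = function(d) ct_indicator(d$cT) == 0, # cT1-2 vs cT3-4
    cN = function(d) as.character(d$cN) %in% c("0", "x"), # cN0/cNx vs cN+
    TRG = function(d) d$TRG == 1
  )
  labels <- c(sex = "sex (M vs F)", histology = "histology (AC vs SCC)",
              cT = "cT (1-2 vs 3-4)", cN = "cN (0/x vs +)",
              TRG = "TRG (1 vs 2-5)")
  rows <- lapply(variables, function(v) {
    if (!v %in% c(names(dich), "age")) {
      abort(paste0("unknown variable: ", v))
    }
    if (v == "age") {
      mw <- mann_whitney(clinical_a$age, clinical_b$age)
      return(tibble(
        variable = "age (median [IQR])", test = "mann_whitney",
        statistic = as.numeric(mw$U), p_value = mw$p_value,
        summary_a = sprintf("%.0f [%.0f-%.0f]", median(clinical_a$age),
                            quantile(clinical_a$age, .25),
                            quantile(clinical_a$age, .75)),
        summary_b = sprintf("%.0f [%.0f-%.0f]", median(clinical_b$age),
                            quantile(clinical_b$age, .25),
                            quantile(clinical_b$age, .75))
      ))
    }
    ga <- dich[[v]](clinical_a); gb <- dich[[v]](clinical_b)
    tab <- matrix(c(sum(ga), sum(!ga), sum(gb), sum(!gb)), 2, byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      p <- fisher_exact(tab)
      tibble(variable = labels[[v]], test = "fisher_exact",
             statistic = NA_real_, p_value = p,
             summary_a = sprintf("%d/%d", sum(ga), length(ga)),
             summary_b = sprintf("%d/%d", sum(gb), length(gb)))
    } else {
      ch <- chi2_yates(tab)
      tibble(variable = labels[[v]], test = "chi2_yates",
             statistic = ch$statistic, p_value = ch$p_value,
             summary_a = sprintf("%d/%d", sum(ga), length(ga)),
             summary_b = sprintf("%d/%d", sum(gb), length(gb)))
    }
  })
  dplyr::bind_rows(rows)
}
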