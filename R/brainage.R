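#' Brain age gap (BrainAGE)
#'
#' The brain age gap is the difference between the age a model predicts
#' from a brain image and the subject's chronological age, in years. A
#' positive gap means the brain "looks older" than the subject is.
#'
#' @param predicted predicted age(s), years.
#' @param age chronological age(s), years.
#' @return `predicted - age`, years.
#' @export
compute_brainage <- function(predicted, age) {
  if (!all(is.finite(predicted)) || !all(is.finite(age))) {
    stop("`predicted` and `age` must be finite", call. = FALSE)
  }
  predicted - age
}

#' Mean absolute error of age predictions
#'
#' @param predicted predicted ages, years.
#' @param age chronological ages, years (same length).
#' @return MAE in years.
#' @export
mae <- function(predicted, age) {
  if (length(predicted) == 0L || length(age) == 0L) {
    stop("inputs must be non-empty", call. = FALSE)
  }
  if (length(predicted) != length(age)) {
    stop("`predicted` and `age` must have equal length", call. = FALSE)
  }
  mean(abs(predicted - age))
}

#' Fit the linear BrainAGE bias correction
#'
#' Brain age models systematically overestimate young and underestimate old
#' subjects, leaving a residual age trend in the gap. The correction is an
#' ordinary least squares fit of the gap on chronological age,
#' `gap = alpha * age + beta`, estimated on a dedicated healthy cohort and
#' later subtracted from the gaps of evaluation cohorts (the fitted
#' coefficients are reused, never refitted).
#'
#' @param gaps raw brain age gaps, years.
#' @param ages chronological ages, years.
#' @param fit_set_id optional identifier of the fitting cohort, recorded for
#'   bookkeeping so the fit and evaluation sets can be kept disjoint.
#' @return an object of class `bias_model` with `alpha` (years of gap per
#'   year of age) and `beta` (years).
#' @export
fit_bias_correction <- function(gaps, ages, fit_set_id = "correction-set") {
  if (length(gaps) < 3L) stop("need at least 3 subjects to fit the bias", call. = FALSE)
  if (length(gaps) != length(ages)) stop("length mismatch", call. = FALSE)
  if (stats::var(ages) <= 0) {
    stop("age variance is zero: cannot fit an age bias", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, ages), gaps)
  structure(list(alpha = unname(fit$coefficients[2]),
                 beta = unname(fit$coefficients[1]),
                 fit_set_id = fit_set_id),
            class = "bias_model")
}

#' Apply a fitted bias correction to a prediction table
#'
#' Adds/overwrites the `gap_corrected` column:
#' `gap_corrected = gap_raw - (alpha * age + beta)`. On its own fitting set
#' this makes the corrected gap exactly orthogonal to age (OLS residuals).
#'
#' @param table a prediction table with columns `age` and `gap_raw` (see
#'   [prediction_table()]).
#' @param model a [fit_bias_correction()] result.
#' @return the table with `gap_corrected` filled in.
#' @export
apply_bias_correction <- function(table, model) {
  stopifnot(inherits(model, "bias_model"))
  if (!all(c("age", "gap_raw") %in% names(table))) {
    stop("`table` must contain `age` and `gap_raw`", call. = FALSE)
  }
  table$gap_corrected <- table$gap_raw - (model$alpha * table$age + model$beta)
  table
}

#' Assemble a prediction table
#'
#' @param ids subject ids.
#' @param age chronological ages, years.
#' @param predicted_age model predictions, years.
#' @param group,sex factors carried through to the group-level statistics.
#' @return a data.frame with `gap_raw = predicted_age - age` and an empty
#'   `gap_corrected` column (filled by [apply_bias_correction()]).
#' @export
prediction_table <- function(ids, age, predicted_age, group, sex) {
  data.frame(
    participant_id = as.character(ids),
    age = age,
    predicted_age = predicted_age,
    gap_raw = compute_brainage(predicted_age, age),
    gap_corrected = NA_real_,
    group = as.character(group),
    sex = as.character(sex),
    stringsAsFactors = FALSE
  )
}

# Shared Type II ANCOVA engine: additive linear model, per-term sums of
# squares from car::Anova, partial eta squared SS / (SS + SS_res).
# The response is standardized before fitting (F, p and np2 are invariant
# under affine response scaling) and the sums of squares rescaled back, so
# maps of any physical magnitude are handled with the same numerics.
ancova_table <- function(data, response, terms) {
  y_sd <- stats::sd(data[[response]])
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  data[[response]] <- data[[response]] / y_sd
  f <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  fit <- stats::lm(f, data = data)
  a <- car::Anova(fit, type = 2)
  a[, "Sum Sq"] <- a[, "Sum Sq"] * y_sd^2
  ss_res <- a["Residuals", "Sum Sq"]
  rows <- setdiff(rownames(a), "Residuals")
  out <- data.frame(
    factor = rows,
    SS = a[rows, "Sum Sq"],
    F = a[rows, "F value"],
    p = a[rows, "Pr(>F)"],
    np2 = a[rows, "Sum Sq"] / (a[rows, "Sum Sq"] + ss_res),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "ss_residual") <- ss_res
  out
}

#' Group ANCOVA on BrainAGE
#'
#' Compares the brain age gap between clinical conditions with an analysis
#' of covariance controlling for age and sex (Type II sums of squares,
#' additive model, no interactions). Age remains a covariate even after
#' bias correction because the correction may not remove the bias
#' completely. Reports, per factor, the sum of squares, F statistic,
#' p-value and partial eta squared.
#'
#' @param table a prediction table with `group`, `age`, `sex` and the gap
#'   columns.
#' @param gap which gap to analyse: `"corrected"` or `"raw"`.
#' @param covariates covariates entered alongside the condition factor; any
#'   subset of `c("age", "sex")`.
#' @return a data.frame with one row per factor (`condition`, `age`,
#'   `sex`): `factor`, `SS`, `F`, `p`, `np2`.
#' @export
ancova_brainage <- function(table, gap = c("corrected", "raw"),
                            covariates = c("age", "sex")) {
  gap <- match.arg(gap)
  col <- if (gap == "corrected") "gap_corrected" else "gap_raw"
  if (!col %in% names(table) || anyNA(table[[col]])) {
    stop(sprintf("column `%s` is missing or incomplete", col), call. = FALSE)
  }
  tab <- table
  tab$group <- factor(tab$group)
  if (nlevels(tab$group) < 2L || any(table(tab$group) < 2L)) {
    stop("need at least two groups with at least two subjects each", call. = FALSE)
  }
  covariates <- match.arg(covariates, c("age", "sex"), several.ok = TRUE)
  if ("sex" %in% covariates) tab$sex <- factor(tab$sex)
  tab$.gap <- tab[[col]]
  out <- ancova_table(tab, ".gap", c("group", covariates))
  out$factor <- c(group = "condition", age = "age", sex = "sex")[out$factor]
  out
}
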