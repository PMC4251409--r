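#' Fraction of subjects with predicted heart age above body age
#'
#' In a healthy cohort the generative model is symmetric around body age,
#' so this fraction should be close to 0.5; groups with risk factors or
#' disease shift it upward. Ties (`heart_age == body_age`) count as
#' not-above.
#'
#' @param predictions A data frame with `heart_age` and `body_age` columns
#'   (or a `delta` column), as returned by [predict_heart_age()].
#' @return The proportion, a single number in \[0, 1\].
#' @examples
#' fraction_above(tibble::tibble(body_age = 1:4, heart_age = c(2, 1, 5, 0)))
#' @export
fraction_above <- function(predictions) {
  predictions <- as_tibble(predictions)
  if (nrow(predictions) == 0) abort("`predictions` is empty.")
  delta <- if (all(c("heart_age", "body_age") %in% names(predictions))) {
    predictions$heart_age - predictions$body_age
  } else if ("delta" %in% names(predictions)) {
    predictions$delta
  } else {
    abort("`predictions` needs `heart_age` and `body_age` (or `delta`).")
  }
  mean(delta > 0)
}

#' Shrinkage slope of predictions against the true heart-age offset
#'
#' On synthetic cohorts (where the latent heart age `a_true` is known),
#' regressing the predicted offset `heart_age - body_age` on the true
#' offset `a_true - body_age` by OLS recovers the model's shrinkage weight
#' `w = theta' Lambda^-1 theta / (1 / sigma_a^2 + theta' Lambda^-1 theta)`
#' in expectation (about 0.90 for the published male model): the posterior
#' mean pulls a fraction `w` of the true offset back from the prior.
#'
#' @param predictions A data frame with `heart_age`, `body_age` and
#'   `a_true` columns.
#' @return The OLS slope, a single number.
#' @seealso [shrinkage_weight()]
#' @export
shrinkage_slope <- function(predictions) {
  predictions <- as_tibble(predictions)
  require_columns(predictions, c("heart_age", "body_age", "a_true"),
                  "`predictions`")
  true_offset <- predictions$a_true - predictions$body_age
  if (stats::var(true_offset) == 0) {
    abort("The true offset a_true - body_age has zero variance; the slope is undefined.")
  }
  pred_offset <- predictions$heart_age - predictions$body_age
  unname(coef(lm(pred_offset ~ true_offset))[2])
}

#' Paired comparison of two prediction sets
#'
#' Mean difference `a` minus `b` with a paired t confidence interval,
#' optionally per gender. Used by [compare_gs_ngs()]; exported because the
#' paired contrast is useful on its own.
#'
#' @param pred_a,pred_b Prediction data frames of equal length on the same
#'   subjects, each with `heart_age` (and `gender` if `by_gender`).
#' @param by_gender Split the contrast by gender (default `TRUE`).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with `gender`, `n`, `mean_diff`, `conf_low`,
#'   `conf_high`, `statistic`, `p_value`. A zero-variance difference gives
#'   a degenerate interval at the mean with `p_value = NA`.
#' @export
prediction_difference_ci <- function(pred_a, pred_b, by_gender = TRUE,
                                     conf_level = 0.95) {
  pred_a <- as_tibble(pred_a)
  pred_b <- as_tibble(pred_b)
  if (nrow(pred_a) != nrow(pred_b)) {
    abort("`pred_a` and `pred_b` must have the same subjects (same row count).")
  }
  d <- pred_a$heart_age - pred_b$heart_age
  groups <- if (by_gender) {
    require_columns(pred_a, "gender", "`pred_a`")
    gender_label(normalize_gender(pred_a$gender))
  } else {
    rep("all", length(d))
  }
  one <- function(di) {
    n <- length(di)
    mu <- mean(di)
    se <- if (n > 1) sd(di) / sqrt(n) else NA_real_
    if (is.na(se) || se == 0) {
      tibble(n = n, mean_diff = mu, conf_low = mu, conf_high = mu,
             statistic = NA_real_, p_value = NA_real_)
    } else {
      tcrit <- qt(1 - (1 - conf_level) / 2, df = n - 1)
      tstat <- mu / se
      tibble(n = n, mean_diff = mu,
             conf_low = mu - tcrit * se, conf_high = mu + tcrit * se,
             statistic = tstat,
             p_value = 2 * stats::pt(-abs(tstat), df = n - 1))
    }
  }
  dplyr::bind_rows(lapply(split(d, groups), one), .id = "gender")
}

#' Gender-specific versus pooled model comparison
#'
#' Fits a gender-specific (GS) model set and a pooled, non-gender-specific
#' (NGS) model on the same training records, predicts every subject under
#' both, and summarizes the per-gender paired mean difference (NGS - GS)
#' with a t confidence interval. When the genders genuinely differ (as in
#' the published constants), the pooled model is biased in opposite
#' directions for males and females, so the two intervals exclude zero with
#' opposite signs for large cohorts.
#'
#' @param cohort Training cohort with both genders: `gender`, `body_age`,
#'   output columns.
#' @param repeats Repeated-measure data for [estimate_lambda()].
#' @param outputs Output column names (default `c("y1", "y2")`).
#' @param sigma_a Prior standard deviation in years.
#' @param conf_level Confidence level for the paired t interval.
#' @return A tibble with one row per gender: `gender`, `n`, `mean_diff`
#'   (NGS - GS, years), `conf_low`, `conf_high`, `statistic`, `p_value`.
#' @export
compare_gs_ngs <- function(cohort, repeats, outputs = c("y1", "y2"),
                           sigma_a = 7.5, conf_level = 0.95) {
  cohort <- as_tibble(cohort)
  require_columns(cohort, "gender", "`cohort`")
  if (length(unique(normalize_gender(cohort$gender))) < 2) {
    abort("`cohort` must contain both genders for the GS/NGS comparison.")
  }
  gs <- fit_heart_age_model(cohort, repeats, outputs = outputs,
                            by_gender = TRUE, sigma_a = sigma_a)
  ngs <- fit_heart_age_model(cohort, repeats, outputs = outputs,
                             by_gender = FALSE, sigma_a = sigma_a)
  pred_gs <- predict_heart_age(cohort, gs)
  pred_ngs <- predict_heart_age(cohort, ngs$models$pooled)
  pred_ngs$gender <- pred_gs$gender
  prediction_difference_ci(pred_ngs, pred_gs, by_gender = TRUE,
                           conf_level = conf_level)
}

#' Parameter-recovery report over simulation replicates
#'
#' Summarizes replicated estimates of model parameters against their
#' generative truth: mean estimate, bias, and root-mean-square error.
#'
#' @param estimates A data frame with columns `parameter`, `estimate` and
#'   optionally `replicate`.
#' @param truth Named numeric vector of true values, names matching
#'   `parameter`.
#' @param seed Optional seed to record in the report.
#' @return A tibble with one row per parameter: `parameter`, `truth`,
#'   `estimate_mean`, `bias`, `rmse`, `n_replicates`, `seed`. RMSE is
#'   always at least |bias|.
#' @export
recovery_report <- function(estimates, truth, seed = NA_integer_) {
  estimates <- as_tibble(estimates)
  require_columns(estimates, c("parameter", "estimate"), "`estimates`")
  missing <- setdiff(unique(estimates$parameter), names(truth))
  if (length(missing) > 0) {
    abort(sprintf("No truth supplied for parameter(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- estimates |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(estimate_mean = mean(.data$estimate),
                     estimate_sq = mean(.data$estimate^2),
                     n_replicates = dplyr::n(),
                     .groups = "drop")
  out$truth <- unname(truth[out$parameter])
  out$bias <- out$estimate_mean - out$truth
  # E[(est - truth)^2] = E[est^2] - 2 truth E[est] + truth^2
  out$rmse <- sqrt(pmax(
    out$estimate_sq - 2 * out$truth * out$estimate_mean + out$truth^2, 0))
  out$seed <- seed
  out[, c("parameter", "truth", "estimate_mean", "bias", "rmse",
          "n_replicates", "seed")]
}
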