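#' Fit the heart-age model from cohort data and repeated measures
#'
#' Runs the full estimation pipeline on a healthy cohort:
#' 1. per gender and per output, a quadratic-in-age OLS regression
#'    ([fit_age_regression()]) giving `beta` rows and residual variances
#'    `sigma_nu2`;
#' 2. the measurement-noise covariance `Lambda` from month-apart repeated
#'    measures ([estimate_lambda()]), shared across genders by default
#'    (repeatability samples are typically too small to stratify);
#' 3. per output, the drift coefficient
#'    `theta_j = sgn(beta1_j) * sqrt(sigma_nu2_j - lambda_jj) / sigma_a`
#'    ([estimate_theta()]).
#'
#' @param data Training cohort: a data frame with `body_age` (or `age`),
#'   the output columns, and — unless `by_gender = FALSE` — a `gender`
#'   column. At least 4 subjects per fitted stratum are required.
#' @param repeats Repeated-measure data for [estimate_lambda()]: long-form
#'   data frame with `subject_id`, `session` and the output columns (or an
#'   m x k difference matrix). When `share_lambda = FALSE` it must also
#'   have a `gender` column.
#' @param outputs Character vector of output column names (default
#'   `c("y1", "y2")`).
#' @param by_gender Fit separate male/female models (default) or one
#'   pooled model.
#' @param share_lambda Estimate one Lambda from all pairs (default); if
#'   `FALSE`, estimate per gender.
#' @param sigma_a Prior standard deviation in years or a [prior_spec()].
#' @return An object of class `heart_age_fit`: a list with `models` (named
#'   list of [heart_age_model()]s), `regressions` (the per-output
#'   [fit_age_regression()] objects), `lambda` (estimate(s) with pair count
#'   attribute), and `n` per stratum. [tidy()] and [glance()] methods are
#'   available, and the object can be passed straight to
#'   [predict_heart_age()].
#' @examples
#' models <- published_heart_age_models()
#' cohort <- simulate_cohort(models, n = 200, seed = 1)
#' reps <- simulate_repeats(models$male, m = 15, seed = 2)
#' fit <- fit_heart_age_model(cohort, reps)
#' glance(fit)
#' @export
fit_heart_age_model <- function(data, repeats, outputs = c("y1", "y2"),
                                by_gender = TRUE, share_lambda = TRUE,
                                sigma_a = 7.5) {
  data <- as_tibble(data)
  if (!"body_age" %in% names(data) && "age" %in% names(data)) {
    data$body_age <- data$age
  }
  require_columns(data, c("body_age", outputs), "`data`")
  sigma_a <- as_sigma_a(sigma_a)

  strata <- if (by_gender) {
    require_columns(data, "gender", "`data` (by_gender = TRUE)")
    codes <- normalize_gender(data$gender)
    present <- sort(unique(codes))
    setNames(lapply(present, function(g) which(codes == g)),
             gender_label(present))
  } else {
    list(pooled = seq_len(nrow(data)))
  }

  lambda_for <- function(stratum) {
    reps <- repeats
    if (!share_lambda) {
      if (!is.data.frame(reps) || !"gender" %in% names(reps)) {
        abort("`share_lambda = FALSE` needs a `gender` column in `repeats`.")
      }
      reps <- reps[gender_label(normalize_gender(reps$gender)) == stratum, ,
                   drop = FALSE]
    }
    estimate_lambda(reps, outputs = outputs, nonpd = "diagonal")
  }
  lambdas <- if (share_lambda) {
    shared <- lambda_for(NULL)
    setNames(rep(list(shared), length(strata)), names(strata))
  } else {
    setNames(lapply(names(strata), lambda_for), names(strata))
  }

  regressions <- list()
  models <- list()
  for (g in names(strata)) {
    rows <- strata[[g]]
    if (length(rows) < 4) {
      abort(sprintf("Stratum `%s` has %d subject(s); at least 4 are needed (residual df = n - 3).",
                    g, length(rows)))
    }
    lambda <- lambdas[[g]]
    fits <- lapply(outputs, function(id) {
      fit_age_regression(data$body_age[rows], data[[id]][rows],
                         output_id = id, gender = g)
    })
    names(fits) <- outputs
    theta <- vapply(seq_along(outputs), function(j) {
      estimate_theta(fits[[j]], lambda[j, j], sigma_a)
    }, numeric(1))
    beta <- do.call(rbind, lapply(fits, function(f) f$coeffs))
    models[[g]] <- heart_age_model(
      gender = g, beta = beta, theta = theta, lambda_cov = lambda,
      sigma_a = sigma_a, output_ids = outputs)
    regressions[[g]] <- fits
  }

  structure(
    list(models = models, regressions = regressions, lambda = lambdas,
         n = vapply(strata, length, integer(1)),
         m = attr(lambdas[[1]], "m"), outputs = outputs, sigma_a = sigma_a,
         share_lambda = share_lambda),
    class = "heart_age_fit")
}

#' @export
print.heart_age_fit <- function(x, ...) {
  cat(sprintf("Heart-age model fit: %s; %s subject(s); m = %d repeat pair(s)\n",
              paste(names(x$models), collapse = " + "),
              paste(x$n, collapse = " + "), x$m))
  for (g in names(x$models)) {
    m <- x$models[[g]]
    cat(sprintf("  %s: theta = (%s), w = %.4f\n", g,
                paste(format(m$theta, digits = 6), collapse = ", "),
                shrinkage_weight(m)))
  }
  invisible(x)
}
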