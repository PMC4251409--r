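#' Tidy a quadratic age-regression fit
#'
#' @param x An [fit_age_regression()] object.
#' @param ... Unused.
#' @return A tibble with one row per term (`(Intercept)`, `age`, `age^2`)
#'   and columns `output_id`, `gender`, `term`, `estimate`.
#' @export
tidy.age_regression_fit <- function(x, ...) {
  tibble(output_id = x$output_id, gender = x$gender,
         term = c("(Intercept)", "age", "age^2"),
         estimate = unname(x$coeffs))
}

#' @rdname tidy.age_regression_fit
#' @return `glance()` returns a one-row tibble with `output_id`, `gender`,
#'   `sigma_nu2`, `n`.
#' @export
glance.age_regression_fit <- function(x, ...) {
  tibble(output_id = x$output_id, gender = x$gender,
         sigma_nu2 = x$sigma_nu2, n = x$n)
}

#' Tidy a heart-age model
#'
#' @param x A [heart_age_model()].
#' @param ... Unused.
#' @return A tibble with one row per output: `gender`, `output_id`,
#'   `theta`, `beta0`, `beta1`, `beta2`, `lambda_jj` (noise variance).
#' @export
tidy.heart_age_model <- function(x, ...) {
  tibble(gender = x$gender, output_id = x$output_ids,
         theta = unname(x$theta),
         beta0 = unname(x$beta[, 1]), beta1 = unname(x$beta[, 2]),
         beta2 = unname(x$beta[, 3]),
         lambda_jj = unname(diag(x$lambda_cov)))
}

#' @rdname tidy.heart_age_model
#' @return `glance()` returns a one-row tibble with `gender`, `k`,
#'   `sigma_a`, `shrinkage_weight` and `posterior_sd`.
#' @export
glance.heart_age_model <- function(x, ...) {
  tibble(gender = x$gender, k = x$k, sigma_a = x$sigma_a,
         shrinkage_weight = shrinkage_weight(x),
         posterior_sd = posterior_sd(x))
}

#' Tidy a full heart-age model fit
#'
#' @param x A [fit_heart_age_model()] object.
#' @param ... Unused.
#' @return `tidy()` binds the per-gender [tidy.heart_age_model()] rows and
#'   adds each output's `sigma_nu2` and regression sample size; `glance()`
#'   binds the per-gender [glance.heart_age_model()] rows and adds `n`
#'   (training subjects) and `m` (repeat pairs).
#' @export
tidy.heart_age_fit <- function(x, ...) {
  rows <- lapply(names(x$models), function(g) {
    base <- tidy(x$models[[g]])
    base$sigma_nu2 <- vapply(x$regressions[[g]], function(f) f$sigma_nu2,
                             numeric(1))
    base$n <- vapply(x$regressions[[g]], function(f) f$n, integer(1))
    base
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy.heart_age_fit
#' @export
glance.heart_age_fit <- function(x, ...) {
  out <- dplyr::bind_rows(lapply(x$models, glance))
  out$n <- unname(x$n[out$gender])
  out$m <- x$m
  out
}
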