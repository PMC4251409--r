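#' Quadratic-in-age regression of an ECG output
#'
#' Fits `y = beta0 + beta1 * x + beta2 * x^2 + nu` by ordinary least
#' squares, where `x` is body age in years and `y` one ECG output. The
#' residual variance is estimated with the quadratic model's residual
#' degrees of freedom: `sigma_nu2 = SSE / (n - 3)`. This total residual
#' variance later decomposes as `theta^2 * sigma_a^2 + lambda^2`
#' (age-drift signal plus measurement noise); see [estimate_theta()].
#'
#' @param ages Numeric vector of body ages (years).
#' @param outputs Numeric vector of one ECG output, same length as `ages`.
#' @param output_id Label for the output (e.g. `"y1"`).
#' @param gender Gender label the fit applies to (1/"male", 2/"female",
#'   or "pooled").
#' @return An object of class `age_regression_fit`: a list with `output_id`,
#'   `gender`, `coeffs` (beta0, beta1, beta2), `sigma_nu2`, and `n`.
#'   [tidy()] and [glance()] methods are available.
#' @examples
#' x <- c(20, 30, 40, 50, 60, 70, 80, 25, 35, 45)
#' fit_age_regression(x, 1 + 2 * x + 0.1 * x^2, "y1", "male")
#' @export
fit_age_regression <- function(ages, outputs, output_id = "y1",
                               gender = "pooled") {
  ages <- as.numeric(ages)
  outputs <- as.numeric(outputs)
  if (length(ages) != length(outputs)) {
    abort("`ages` and `outputs` must have the same length.")
  }
  keep <- is.finite(ages) & is.finite(outputs)
  if (!all(keep)) abort("`ages` and `outputs` must be finite.")
  n <- length(ages)
  if (n < 4) {
    abort(sprintf(
      "Need at least 4 subjects to fit the quadratic age model (got %d); residual degrees of freedom n - 3 would be <= 0.",
      n))
  }
  if (length(unique(ages)) < 3) {
    abort("`ages` must contain at least 3 distinct values; the design columns (1, age, age^2) are collinear otherwise.")
  }

  fit <- lm(outputs ~ ages + I(ages^2))
  if (fit$rank < 3) {
    bad <- c("(Intercept)", "age", "age^2")[is.na(coef(fit))]
    abort(sprintf("Quadratic design is rank-deficient; collinear column(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  coeffs <- unname(coef(fit))
  sse <- sum(fit$residuals^2)

  gender_chr <- as.character(gender)
  if (!identical(gender_chr, "pooled")) {
    gender_chr <- gender_label(normalize_gender(gender))
  }

  structure(
    list(output_id = output_id, gender = gender_chr,
         coeffs = setNames(coeffs, c("beta0", "beta1", "beta2")),
         sigma_nu2 = sse / (n - 3), n = n),
    class = "age_regression_fit")
}

#' @export
print.age_regression_fit <- function(x, ...) {
  cat(sprintf("Quadratic age regression for %s (%s), n = %d\n",
              x$output_id, x$gender, x$n))
  cat(sprintf("  E(y|x) = %.6g + %.6g x + %.6g x^2,  sigma_nu^2 = %.6g\n",
              x$coeffs[1], x$coeffs[2], x$coeffs[3], x$sigma_nu2))
  invisible(x)
}

#' Measurement-noise covariance from repeated ECG measures
#'
#' Estimates the within-subject noise covariance `Lambda` of the ECG
#' outputs from pairs of measurements taken close enough in time (a month
#' apart) that the subject's latent heart age is unchanged. With
#' `d_i = y_first - y_second` for pair i, `E(d d') = 2 Lambda`, so
#' `Lambda_hat = sum(d_i d_i') / (2 m)`.
#'
#' @param repeats A data frame of repeated measures in long form: one row
#'   per (subject, session) with columns `subject_id`, `session` (two
#'   sessions per subject, ordered 1 then 2) and the output columns; or a
#'   numeric matrix/vector of per-subject differences `d` (m x k).
#' @param outputs Character vector naming the output columns when `repeats`
#'   is a data frame. Defaults to all columns other than
#'   `subject_id`/`session`.
#' @param nonpd What to do when k >= 2 and the estimate is not positive
#'   definite (possible for small m): `"error"` (default) stops with a
#'   message suggesting the diagonal fallback, `"diagonal"` keeps only the
#'   diagonal (per-output noise variances) with a warning.
#' @return A k x k symmetric matrix (a 1 x 1 matrix when k = 1).
#' @examples
#' estimate_lambda(matrix(c(1, 0, 0, 2), nrow = 2, byrow = TRUE))
#' @export
estimate_lambda <- function(repeats, outputs = NULL,
                            nonpd = c("error", "diagonal")) {
  nonpd <- match.arg(nonpd)
  d <- repeat_differences(repeats, outputs)
  m <- nrow(d)
  if (m < 1) abort("Need at least one repeated-measure pair (m >= 1).")
  if (!all(is.finite(d))) abort("Repeated-measure values must be finite.")

  lambda <- crossprod(d) / (2 * m)
  lambda <- (lambda + t(lambda)) / 2
  k <- ncol(lambda)

  # The PD requirement only bites once every output shows some
  # within-subject variability; an all-zero row is a degenerate input the
  # model constructor will reject later.
  if (k >= 2 && all(diag(lambda) > 0) && !is_spd(lambda)) {
    if (nonpd == "error") {
      abort(sprintf(
        "Estimated Lambda is not positive definite (m = %d pairs, k = %d outputs); re-run with nonpd = \"diagonal\" to keep only per-output noise variances.",
        m, k))
    }
    warn(sprintf(
      "Estimated Lambda not positive definite with m = %d pairs; falling back to its diagonal.",
      m))
    lambda <- diag(diag(lambda), nrow = k)
  }
  attr(lambda, "m") <- m
  lambda
}

# Coerce the accepted repeated-measure representations to an m x k matrix
# of first-minus-second differences.
repeat_differences <- function(repeats, outputs = NULL) {
  if (is.numeric(repeats) && is.null(dim(repeats))) {
    return(matrix(repeats, ncol = 1))
  }
  if (is.matrix(repeats)) return(repeats)
  if (!is.data.frame(repeats)) {
    abort("`repeats` must be a data frame of (subject, session) rows or a matrix of differences.")
  }
  require_columns(repeats, c("subject_id", "session"), "`repeats`")
  if (is.null(outputs)) {
    outputs <- setdiff(names(repeats),
                       c("subject_id", "session", "gender", "body_age",
                         "age", "a_true", "delta_true", "group"))
  }
  require_columns(repeats, outputs, "`repeats`")
  split_rows <- split(seq_len(nrow(repeats)), repeats$subject_id)
  bad <- names(split_rows)[lengths(split_rows) != 2]
  if (length(bad) > 0) {
    abort(sprintf("Each subject needs exactly two sessions; offending subject_id(s): %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  d <- t(vapply(split_rows, function(idx) {
    rows <- repeats[idx, , drop = FALSE]
    rows <- rows[order(rows$session), , drop = FALSE]
    as.numeric(rows[1, outputs, drop = TRUE]) -
      as.numeric(rows[2, outputs, drop = TRUE])
  }, numeric(length(outputs))))
  if (length(outputs) == 1) d <- matrix(as.numeric(d), ncol = 1)
  colnames(d) <- outputs
  d
}

#' Drift coefficient from the variance decomposition
#'
#' The total residual variance of an output around its quadratic-in-age
#' mean decomposes as `sigma_nu^2 = theta^2 * sigma_a^2 + lambda^2`:
#' age-drift signal plus measurement noise. Solving for theta and taking
#' the sign from the linear age coefficient gives
#' `theta_hat = sgn(beta1) * sqrt(sigma_nu2 - lambda2) / sigma_a`.
#' When `sigma_nu2 <= lambda2` no age-drift variance remains: the estimate
#' is clamped to 0 with a warning and predictions from this output fall
#' back to the prior. The tie-break `sgn(0) = +1` is used.
#'
#' @param fit An [fit_age_regression()] result, or a list with elements
#'   `sigma_nu2` and `coeffs` (length 3).
#' @param lambda_jj Measurement-noise variance of this output (the j-th
#'   diagonal entry of Lambda); must be >= 0.
#' @param sigma_a Prior standard deviation in years or a [prior_spec()].
#' @return The scalar drift coefficient estimate (output units per year).
#' @examples
#' f <- list(sigma_nu2 = 169, coeffs = c(0, 1, 0))
#' estimate_theta(f, lambda_jj = 100) # sqrt(69) / 7.5
#' @export
estimate_theta <- function(fit, lambda_jj, sigma_a = 7.5) {
  sigma_a <- as_sigma_a(sigma_a)
  if (!is.numeric(lambda_jj) || length(lambda_jj) != 1 ||
      !is.finite(lambda_jj) || lambda_jj < 0) {
    abort("`lambda_jj` must be a single non-negative noise variance.")
  }
  sigma_nu2 <- fit$sigma_nu2
  beta1 <- fit$coeffs[[2]]
  if (sigma_nu2 <= lambda_jj) {
    warn(sprintf(
      "Residual variance (%.4g) does not exceed measurement-noise variance (%.4g) for %s; theta set to 0 (output carries no age signal beyond noise).",
      sigma_nu2, lambda_jj,
      if (!is.null(fit$output_id)) fit$output_id else "this output"))
    return(0)
  }
  sgn <- if (beta1 >= 0) 1 else -1
  sgn * sqrt(sigma_nu2 - lambda_jj) / sigma_a
}
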