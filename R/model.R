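#' Construct a heart-age model
#'
#' A heart-age model holds, for one gender (or a pooled fit), everything the
#' posterior-mean predictor needs: the k x 3 quadratic-in-age regression
#' coefficient matrix `beta` (one row per ECG output, columns intercept,
#' age, age squared), the drift coefficients `theta` (output units per year
#' of heart-age offset), the k x k measurement-noise covariance
#' `lambda_cov`, and the prior scale `sigma_a`.
#'
#' @param gender Gender the model applies to: 1/"male", 2/"female", or
#'   "pooled" for a non-gender-specific fit.
#' @param beta Numeric k x 3 matrix (or length-3 vector when k = 1) of
#'   regression coefficients; row j gives (beta0, beta1, beta2) for output j.
#' @param theta Numeric length-k vector of drift coefficients.
#' @param lambda_cov Numeric k x k symmetric positive-definite noise
#'   covariance (output units squared). A scalar is accepted when k = 1.
#' @param sigma_a Prior standard deviation in years, or a [prior_spec()].
#' @param output_ids Character labels for the k outputs; defaults to
#'   `y1 ... yk`.
#' @return An object of class `heart_age_model`.
#' @examples
#' m <- heart_age_model("male", beta = c(0, 1, 0), theta = 1, lambda_cov = 4)
#' m
#' @seealso [published_heart_age_model()], [fit_heart_age_model()],
#'   [predict_heart_age()]
#' @export
heart_age_model <- function(gender, beta, theta, lambda_cov,
                            sigma_a = 7.5, output_ids = NULL) {
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1)
  beta <- as.matrix(beta)
  theta <- as.numeric(theta)
  if (is.null(dim(lambda_cov))) {
    lambda_cov <- diag(as.numeric(lambda_cov), nrow = length(lambda_cov))
  }
  lambda_cov <- as.matrix(lambda_cov)
  k <- length(theta)

  if (ncol(beta) != 3) {
    abort("`beta` must have 3 columns: intercept, age, age squared.")
  }
  if (nrow(beta) != k) {
    abort(sprintf(
      "`beta` has %d row(s) but `theta` has length %d; one row per output.",
      nrow(beta), k))
  }
  if (!all(dim(lambda_cov) == c(k, k))) {
    abort(sprintf("`lambda_cov` must be %d x %d.", k, k))
  }
  if (!all(is.finite(beta)) || !all(is.finite(theta)) ||
      !all(is.finite(lambda_cov))) {
    abort("Model parameters must be finite.")
  }
  if (!is_spd(lambda_cov)) {
    abort("`lambda_cov` must be symmetric positive-definite.")
  }
  lambda_cov <- (lambda_cov + t(lambda_cov)) / 2
  lambda_inv <- solve(lambda_cov)
  lambda_inv <- (lambda_inv + t(lambda_inv)) / 2

  gender_chr <- as.character(gender)
  if (!identical(gender_chr, "pooled")) {
    gender_chr <- gender_label(normalize_gender(gender))
  }
  if (is.null(output_ids)) output_ids <- paste0("y", seq_len(k))
  if (length(output_ids) != k) {
    abort("`output_ids` must have one label per output.")
  }
  dimnames(beta) <- list(output_ids, c("beta0", "beta1", "beta2"))
  names(theta) <- output_ids
  dimnames(lambda_cov) <- dimnames(lambda_inv) <- list(output_ids, output_ids)

  structure(
    list(gender = gender_chr, k = k, beta = beta, theta = theta,
         lambda_cov = lambda_cov, lambda_inv = lambda_inv,
         sigma_a = as_sigma_a(sigma_a), output_ids = output_ids),
    class = "heart_age_model")
}

#' @export
print.heart_age_model <- function(x, ...) {
  cat(sprintf("Heart-age model (%s), k = %d output(s): %s\n",
              x$gender, x$k, paste(x$output_ids, collapse = ", ")))
  cat(sprintf("  prior: N(body age, %.4g^2) years\n", x$sigma_a))
  cat(sprintf("  shrinkage weight w = %.4f, posterior sd = %.3f years\n",
              shrinkage_weight(x), posterior_sd(x)))
  cat("  theta:", format(x$theta, digits = 6), "\n")
  invisible(x)
}

# Precision contributed by the ECG outputs: theta' Lambda^-1 theta.
output_precision <- function(model) {
  drop(crossprod(model$theta, model$lambda_inv %*% model$theta))
}

#' Shrinkage weight and posterior standard deviation of a model
#'
#' The posterior mean recovers, on average, a fraction
#' `w = q / (1 / sigma_a^2 + q)` of the true heart-age offset, where
#' `q = theta' Lambda^-1 theta`. The posterior standard deviation is
#' `(1 / sigma_a^2 + q)^(-1/2)` and does not depend on the observed
#' outputs; it equals `sigma_a` when `theta = 0` and decreases as any
#' |theta_j| grows.
#'
#' @param model A [heart_age_model()].
#' @return A scalar.
#' @examples
#' shrinkage_weight(published_heart_age_model("male")) # about 0.90
#' @export
shrinkage_weight <- function(model) {
  stopifnot(inherits(model, "heart_age_model"))
  q <- output_precision(model)
  q / (1 / model$sigma_a^2 + q)
}

#' @rdname shrinkage_weight
#' @export
posterior_sd <- function(model) {
  stopifnot(inherits(model, "heart_age_model"))
  1 / sqrt(1 / model$sigma_a^2 + output_precision(model))
}

#' Serialize and restore heart-age models as JSON
#'
#' Models are written as JSON with fields `gender`, `beta` (k x 3,
#' row-major), `theta`, `lambda_cov`, `sigma_a` and `output_ids`; a set of
#' gender-specific models is written as a named list. The reader
#' revalidates all model invariants.
#'
#' @param model A `heart_age_model` or a named list of them (as returned by
#'   [fit_heart_age_model()] or [published_heart_age_models()]).
#' @param path File path.
#' @return `write_heart_age_model()` returns `path` invisibly;
#'   `read_heart_age_model()` returns the model or named model list.
#' @export
write_heart_age_model <- function(model, path) {
  to_json_list <- function(m) {
    list(gender = m$gender,
         output_ids = m$output_ids,
         beta = unname(m$beta),
         theta = unname(m$theta),
         lambda_cov = unname(m$lambda_cov),
         sigma_a = m$sigma_a)
  }
  payload <- if (inherits(model, "heart_age_model")) {
    to_json_list(model)
  } else if (is.list(model) &&
             all(vapply(model, inherits, TRUE, "heart_age_model"))) {
    list(models = lapply(model, to_json_list))
  } else {
    abort("`model` must be a heart_age_model or a named list of them.")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_heart_age_model
#' @export
read_heart_age_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  from_json_list <- function(r) {
    heart_age_model(
      gender = r$gender,
      beta = matrix(unlist(r$beta), ncol = 3, byrow = !is.matrix(r$beta)),
      theta = r$theta,
      lambda_cov = if (is.matrix(r$lambda_cov)) r$lambda_cov else
        matrix(unlist(r$lambda_cov), nrow = length(r$theta), byrow = TRUE),
      sigma_a = r$sigma_a,
      output_ids = r$output_ids)
  }
  if (!is.null(raw$models)) {
    lapply(raw$models, from_json_list)
  } else {
    from_json_list(raw)
  }
}
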