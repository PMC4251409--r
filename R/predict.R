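#' Posterior-mean heart age for a single ECG output (k = 1)
#'
#' Closed form of the posterior mean when one ECG output is used:
#' `a_hat = x + (theta * (y - beta' x_vec) / lambda2) /
#' (1 / sigma_a^2 + theta^2 / lambda2)` with design row
#' `x_vec = (1, x, x^2)`, and posterior standard deviation
#' `(1 / sigma_a^2 + theta^2 / lambda2)^(-1/2)`.
#'
#' @param x Body age(s) in years.
#' @param y Observed ECG output(s), same length as `x`.
#' @param coeffs Length-3 regression coefficients (beta0, beta1, beta2).
#' @param theta Drift coefficient (output units per year).
#' @param lambda2 Measurement-noise variance of the output; must be > 0.
#' @param sigma_a Prior standard deviation in years or a [prior_spec()].
#' @return A tibble with one row per subject: `body_age`, `heart_age`,
#'   `posterior_sd`, `delta` (= heart_age - body_age).
#' @examples
#' predict_heart_age_single(50, y = 1, coeffs = c(0, 0, 0),
#'                          theta = 1, lambda2 = 1)
#' @export
predict_heart_age_single <- function(x, y, coeffs, theta, lambda2,
                                     sigma_a = 7.5) {
  sigma_a <- as_sigma_a(sigma_a)
  if (!is.numeric(lambda2) || length(lambda2) != 1 || !is.finite(lambda2) ||
      lambda2 <= 0) {
    abort("`lambda2` must be a single positive noise variance.")
  }
  if (length(coeffs) != 3) abort("`coeffs` must have length 3.")
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  resid <- y - drop(design_rows(x) %*% as.numeric(coeffs))
  precision <- 1 / sigma_a^2 + theta^2 / lambda2
  a_hat <- x + (theta * resid / lambda2) / precision
  tibble(body_age = x, heart_age = a_hat,
         posterior_sd = 1 / sqrt(precision), delta = a_hat - x)
}

# Core multivariate posterior moments for one gender's model.
# x: n-vector, y: n x k matrix. Returns list(a_hat, posterior_sd).
posterior_moments <- function(x, y, model) {
  resid <- y - design_rows(x) %*% t(model$beta)
  q <- output_precision(model)
  precision <- 1 / model$sigma_a^2 + q
  score <- drop(resid %*% (model$lambda_inv %*% model$theta))
  list(a_hat = x + score / precision, posterior_sd = 1 / sqrt(precision))
}

#' Predict heart age from ECG outputs
#'
#' Computes the posterior-mean heart age
#' `a_hat = x + (theta' Lambda^-1 (y - beta x_vec)) /
#' (1 / sigma_a^2 + theta' Lambda^-1 theta)`
#' and its posterior standard deviation for every subject in `data`.
#' The prior is `N(x, sigma_a^2)`; a subject whose outputs sit exactly on
#' the age-expected curve gets `heart_age = body_age`.
#'
#' @param data A data frame with a `body_age` (or `age`) column and the
#'   model's output columns (`model$output_ids`, e.g. `y1`, `y2`). When
#'   `model` is a named list of gender-specific models, a `gender` column
#'   (1/M/male, 2/F/female) selects the model per subject. Columns
#'   `subject_id`, `group`, `a_true`, `delta_true` are carried through.
#' @param model A [heart_age_model()] or a named list of them with names
#'   `male`/`female` (as from [fit_heart_age_model()] or
#'   [published_heart_age_models()]).
#' @return A tibble of class `heart_age_prediction`: carried-through
#'   identifier columns plus `body_age`, `heart_age`, `posterior_sd`, and
#'   `delta = heart_age - body_age`.
#' @examples
#' model <- published_heart_age_model("male")
#' subjects <- tibble::tibble(
#'   body_age = c(40, 50),
#'   y1 = c(-1.5, 0), y2 = c(-1.2, 0))
#' predict_heart_age(subjects, model)
#' @export
predict_heart_age <- function(data, model) {
  data <- as_tibble(data)
  if (!"body_age" %in% names(data) && "age" %in% names(data)) {
    data$body_age <- data$age
  }
  require_columns(data, "body_age", "`data`")
  if (!all(is.finite(data$body_age))) {
    abort("`body_age` must be finite for every subject.")
  }

  models <- as_model_list(model)
  if (length(models) > 1) {
    require_columns(data, "gender", "`data` (gender-specific model list)")
    gender_code <- normalize_gender(data$gender)
    if (anyNA(gender_code)) abort("`gender` contains missing values.")
  } else {
    gender_code <- rep(1L, nrow(data))
  }

  out_ids <- models[[1]]$output_ids
  for (m in models) {
    if (!identical(m$output_ids, out_ids)) {
      abort("All models in the list must use the same output_ids.")
    }
  }
  require_columns(data, out_ids, "`data`")
  for (id in out_ids) {
    if (!all(is.finite(data[[id]]))) {
      bad <- which(!is.finite(data[[id]]))
      abort(sprintf("Output `%s` has non-finite value(s) in row(s) %s.",
                    id, paste(utils::head(bad, 5), collapse = ", ")))
    }
  }

  y <- as.matrix(data[, out_ids, drop = FALSE])
  a_hat <- numeric(nrow(data))
  post_sd <- numeric(nrow(data))
  for (i in seq_along(models)) {
    rows <- if (length(models) > 1) {
      which(gender_code == normalize_gender(models[[i]]$gender))
    } else {
      seq_len(nrow(data))
    }
    if (length(rows) == 0) next
    mom <- posterior_moments(data$body_age[rows],
                             y[rows, , drop = FALSE], models[[i]])
    a_hat[rows] <- mom$a_hat
    post_sd[rows] <- mom$posterior_sd
  }

  keep <- intersect(c("subject_id", "gender", "group", "a_true",
                      "delta_true"), names(data))
  out <- dplyr::bind_cols(
    data[, keep, drop = FALSE],
    tibble(body_age = data$body_age, heart_age = a_hat,
           posterior_sd = post_sd, delta = a_hat - data$body_age))
  class(out) <- c("heart_age_prediction", class(out))
  out
}

# Accept a single model or a named list keyed by gender.
as_model_list <- function(model) {
  if (inherits(model, "heart_age_model")) return(list(model))
  if (inherits(model, "heart_age_fit")) model <- model$models
  if (is.list(model) &&
      all(vapply(model, inherits, TRUE, "heart_age_model"))) {
    if (length(model) > 1) {
      genders <- vapply(model, function(m) m$gender, character(1))
      if (anyDuplicated(genders) || any(genders == "pooled")) {
        abort("A model list must contain distinct gender-specific models.")
      }
    }
    return(model)
  }
  abort("`model` must be a heart_age_model or a named list of them.")
}

#' Posterior density of heart age on a grid
#'
#' Evaluates the posterior `p(a | x, y)` proportional to
#' `N(a; x, sigma_a^2) * N(y; beta x_vec + theta (a - x), Lambda)` on a
#' user-supplied grid and normalizes it by the trapezoid rule. The grid
#' mean matches the closed-form posterior mean of [predict_heart_age()] to
#' numerical tolerance, so this function serves as an independent check of
#' the closed form.
#'
#' @param a_grid Strictly increasing grid of candidate heart ages (years),
#'   spanning at least `x +/- 5 * sigma_a`.
#' @param x Body age (scalar, years).
#' @param y Length-k vector of observed ECG outputs.
#' @param model A [heart_age_model()].
#' @return A tibble with columns `a` and `density`, carrying attributes
#'   `mean` (trapezoid posterior mean) and `mass` (total integral before
#'   normalization checks).
#' @examples
#' m <- heart_age_model("male", beta = c(0, 0, 0), theta = 1, lambda_cov = 4)
#' d <- posterior_density(seq(0, 100, by = 0.05), x = 50, y = 3, m)
#' attr(d, "mean")
#' @export
posterior_density <- function(a_grid, x, y, model) {
  stopifnot(inherits(model, "heart_age_model"))
  a_grid <- as.numeric(a_grid)
  if (length(a_grid) < 10 || any(diff(a_grid) <= 0)) {
    abort("`a_grid` must be strictly increasing with at least 10 points.")
  }
  if (length(x) != 1 || !is.finite(x)) abort("`x` must be a finite scalar.")
  y <- as.numeric(y)
  if (length(y) != model$k) {
    abort(sprintf("`y` must have length k = %d.", model$k))
  }
  span <- 5 * model$sigma_a
  if (a_grid[1] > x - span || a_grid[length(a_grid)] < x + span) {
    abort(sprintf("`a_grid` must span at least x +/- 5 sigma_a = [%.1f, %.1f].",
                  x - span, x + span))
  }

  # direct pointwise evaluation of prior x likelihood on the grid
  resid0 <- y - drop(model$beta %*% design_rows(x)[1, ])
  t_off <- a_grid - x
  resid <- matrix(resid0, length(a_grid), model$k, byrow = TRUE) -
    outer(t_off, model$theta)
  quad <- rowSums((resid %*% model$lambda_inv) * resid)
  log_dens <- -0.5 * (t_off^2 / model$sigma_a^2 + quad)
  dens <- exp(log_dens - max(log_dens))

  trapz <- function(fx) sum(diff(a_grid) * (fx[-1] + fx[-length(fx)]) / 2)
  mass <- trapz(dens)
  dens <- dens / mass

  n <- length(a_grid)
  edge_mass <- sum(diff(a_grid[1:2]) * (dens[1] + dens[2]) / 2,
                   diff(a_grid[(n - 1):n]) * (dens[n - 1] + dens[n]) / 2)
  if (edge_mass > 1e-6) {
    abort(sprintf(
      "`a_grid` is too narrow: %.3g of the posterior mass sits in the edge cells; widen the grid.",
      edge_mass))
  }

  out <- tibble(a = a_grid, density = dens)
  attr(out, "mean") <- trapz(a_grid * dens)
  attr(out, "mass") <- trapz(dens)
  out
}
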