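#' Prior on heart age
#'
#' The prior for a subject's heart age `a` given body age `x` is
#' `N(x, sigma_a^2)`: with no ECG information, heart age is expected to lie
#' within about two standard deviations of body age. The default scale of
#' 7.5 years is consistent with coronary-artery-calcium-based age
#' adjustments to Framingham risk scoring (see [grundy_prior_sd()]).
#'
#' @param sigma_a Prior standard deviation of heart age around body age,
#'   in years. Must be positive. Default 7.5.
#' @return An object of class `prior_spec` (a list with element `sigma_a`).
#' @examples
#' prior_spec()
#' prior_spec(sigma_a = 10)
#' @export
prior_spec <- function(sigma_a = 7.5) {
  sigma_a <- as_sigma_a(sigma_a)
  structure(list(sigma_a = sigma_a), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Heart-age prior: a | x ~ N(x, %.4g^2) years\n", x$sigma_a))
  invisible(x)
}

#' Prior scale implied by CAC-based age adjustment
#'
#' Grundy's coronary-artery-calcium (CAC) table adjusts Framingham risk by
#' about `risk_points` points up or down for subjects above the 75th or
#' below the 25th percentile of CAC for their age group. At roughly
#' `years_per_point` years of age per risk point, the extremes correspond
#' to an age adjustment of `risk_points * years_per_point` years (see
#' [grundy_age_adjustment()]). Equating "above the 75th percentile" with
#' the 87.5th percentile of a normal distribution of adjusted age gives an
#' implied standard deviation of
#' `risk_points * years_per_point / qnorm(percentile)` — about 7.8 years
#' with the defaults, supporting the package's default prior scale of 7.5.
#'
#' @param risk_points Average Framingham risk-point adjustment at the CAC
#'   extremes (default 4.5).
#' @param years_per_point Years of age equivalent to one risk point
#'   (default 2).
#' @param percentile Normal percentile taken to represent "above the 75th
#'   percentile" (default 0.875).
#' @return Implied prior standard deviation in years (scalar).
#' @examples
#' grundy_prior_sd() # about 7.8 years
#' @export
grundy_prior_sd <- function(risk_points = 4.5, years_per_point = 2,
                            percentile = 0.875) {
  stopifnot(risk_points > 0, years_per_point > 0,
            percentile > 0.5, percentile < 1)
  grundy_age_adjustment(risk_points, years_per_point) / qnorm(percentile)
}

#' Age adjustment at the CAC extremes
#'
#' @inheritParams grundy_prior_sd
#' @return Age adjustment in years (`risk_points * years_per_point`);
#'   9 years with the defaults.
#' @examples
#' grundy_age_adjustment() # 9 years
#' @export
grundy_age_adjustment <- function(risk_points = 4.5, years_per_point = 2) {
  risk_points * years_per_point
}
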