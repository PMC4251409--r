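#' Published heart-age model constants
#'
#' Loads the published gender-specific model for the two composite ECG
#' outputs (k = 2): drift coefficients theta, quadratic-in-age regression
#' matrices beta (per gender), the shared inverse noise covariance
#' `Lambda^-1` (the covariance itself is obtained by matrix inversion),
#' and the prior scale sigma_a = 7.5 years. The constants ship as a
#' versioned JSON resource inside the package.
#'
#' Gender is encoded 1 = male, 2 = female; `"M"`/`"F"` are accepted.
#' The noise covariance was estimated from m = 15 subjects with repeated
#' ECGs a month apart and is shared across genders.
#'
#' @param gender Which model: 1/"male" or 2/"female".
#' @param version Resource version (only `"1"` exists).
#' @return `published_heart_age_model()` returns a [heart_age_model()];
#'   `published_heart_age_models()` a named list with elements `male` and
#'   `female`; `published_composite_coefficients()` the logistic-regression
#'   coefficient vectors as a list with `gamma1` and `gamma2` (length 7
#'   each, intercept first).
#' @examples
#' published_heart_age_model("male")$theta
#' published_composite_coefficients()$gamma1[1]
#' @export
published_heart_age_model <- function(gender, version = "1") {
  raw <- published_constants(version)
  code <- normalize_gender(gender)
  entry <- raw$models[[gender_label(code)]]
  lambda_inv <- raw$lambda_inv
  lambda_cov <- solve(lambda_inv)
  heart_age_model(
    gender = code,
    beta = entry$beta,
    theta = entry$theta,
    lambda_cov = lambda_cov,
    sigma_a = raw$sigma_a,
    output_ids = raw$output_ids)
}

#' @rdname published_heart_age_model
#' @export
published_heart_age_models <- function(version = "1") {
  list(male = published_heart_age_model("male", version),
       female = published_heart_age_model("female", version))
}

#' @rdname published_heart_age_model
#' @export
published_composite_coefficients <- function(version = "1") {
  raw <- published_constants(version)
  structure(list(gamma1 = raw$gamma1, gamma2 = raw$gamma2),
            class = "composite_coefficients")
}

# Raw constants resource, cached per session.
published_constants <- local({
  cache <- new.env(parent = emptyenv())
  function(version = "1") {
    key <- paste0("v", version)
    if (!is.null(cache[[key]])) return(cache[[key]])
    path <- system.file("extdata",
                        sprintf("published_model_v%s.json", version),
                        package = "heartage")
    if (path == "") {
      abort(sprintf("No published constants resource for version \"%s\".",
                    version))
    }
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    as_mat <- function(x, ncol) {
      if (is.matrix(x)) x else matrix(unlist(x), ncol = ncol, byrow = TRUE)
    }
    raw$lambda_inv <- as_mat(raw$lambda_inv, 2)
    for (g in names(raw$models)) {
      raw$models[[g]]$beta <- as_mat(raw$models[[g]]$beta, 3)
    }
    cache[[key]] <- raw
    raw
  }
})
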