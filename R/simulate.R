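#' Simulate a cohort from the heart-age generative model
#'
#' Draws subjects from the model that the estimator assumes: body age
#' `x ~ Uniform(age_range)` (optionally stratified into age bands), latent
#' heart-age offset `delta ~ N(delta_mean, delta_sd^2)` so that
#' `a = x + delta`, and outputs
#' `y = beta x_vec + theta * delta + eps`, `eps ~ N(0, Lambda)`.
#' A healthy cohort has `delta_mean = 0`; groups with risk factors or
#' disease are emulated with positive `delta_mean`.
#'
#' @param model A [heart_age_model()] or a named list of gender-specific
#'   models (e.g. [published_heart_age_models()]). With a single model the
#'   same parameters are used for both genders.
#' @param n Number of subjects.
#' @param age_range Length-2 vector, default `c(20, 80)` years.
#' @param gender_mix Fraction of males (default 0.5).
#' @param delta_mean,delta_sd Mean and standard deviation (years) of the
#'   heart-age offset; defaults 0 and 7.5 (the prior scale).
#' @param group Group label stored in the `group` column.
#' @param age_bands Optional stratified age sampling: a list with `breaks`
#'   (length B + 1 vector of band edges) and `probs` (length B band
#'   probabilities); ages are uniform within the sampled band.
#' @param lambda_cov Optional noise-covariance override (e.g. an all-zero
#'   matrix for degenerate-noise checks); defaults to each model's
#'   `lambda_cov`.
#' @param seed Integer seed; the caller's random stream is left untouched.
#' @return A tibble with `subject_id`, `gender` (1 male / 2 female),
#'   `group`, `body_age`, `a_true`, `delta_true`, and one column per
#'   output. The seed used is recorded in attribute `seed`.
#' @examples
#' cohort <- simulate_cohort(published_heart_age_models(), n = 10, seed = 1)
#' cohort
#' @export
simulate_cohort <- function(model, n, age_range = c(20, 80),
                            gender_mix = 0.5, delta_mean = 0,
                            delta_sd = 7.5, group = "HNA",
                            age_bands = NULL, lambda_cov = NULL,
                            seed = NULL) {
  models <- as_model_list(model)
  if (n < 1) abort("`n` must be at least 1.")
  if (delta_sd < 0) abort("`delta_sd` must be non-negative.")
  if (gender_mix < 0 || gender_mix > 1) abort("`gender_mix` must be in [0, 1].")
  if (age_range[1] < 20) abort("`age_range` starts below 20; the model applies to adults at least 20 years old.")

  out_ids <- models[[1]]$output_ids
  k <- models[[1]]$k

  local_seed(seed, {
    gender <- ifelse(runif(n) < gender_mix, 1L, 2L)
    x <- draw_ages(n, age_range, age_bands)
    delta <- rnorm(n, delta_mean, delta_sd)

    y <- matrix(NA_real_, n, k, dimnames = list(NULL, out_ids))
    for (m in models) {
      rows <- if (length(models) > 1) {
        which(gender == normalize_gender(m$gender))
      } else {
        seq_len(n)
      }
      if (length(rows) == 0) next
      sig <- if (is.null(lambda_cov)) m$lambda_cov else as.matrix(lambda_cov)
      eps <- rmvnorm0(length(rows), sig)
      y[rows, ] <- design_rows(x[rows]) %*% t(m$beta) +
        outer(delta[rows], m$theta) + eps
    }

    out <- dplyr::bind_cols(
      tibble(subject_id = sprintf("%s-%05d", group, seq_len(n)),
             gender = gender, group = group, body_age = x,
             a_true = x + delta, delta_true = delta),
      as_tibble(as.data.frame(y)))
    attr(out, "seed") <- seed
    out
  })
}

draw_ages <- function(n, age_range, age_bands) {
  if (is.null(age_bands)) {
    return(runif(n, age_range[1], age_range[2]))
  }
  breaks <- age_bands$breaks
  probs <- age_bands$probs
  if (length(breaks) != length(probs) + 1 || any(diff(breaks) <= 0)) {
    abort("`age_bands` needs increasing `breaks` of length length(probs) + 1.")
  }
  band <- sample.int(length(probs), n, replace = TRUE,
                     prob = probs / sum(probs))
  runif(n, breaks[band], breaks[band + 1])
}

#' Simulate month-apart repeated ECG measures
#'
#' Each simulated subject has one latent `(x, a)`; the two sessions differ
#' only by independent measurement-noise draws `eps ~ N(0, Lambda)`, so the
#' session differences satisfy `E(d d') = 2 Lambda` — the identity
#' [estimate_lambda()] relies on.
#'
#' @param model A [heart_age_model()] supplying `beta`, `theta` and
#'   `lambda_cov`.
#' @param m Number of subjects (pairs); the published noise covariance was
#'   estimated from m = 15.
#' @param age_range,delta_sd Latent-age generation settings, as in
#'   [simulate_cohort()].
#' @param lambda_cov Optional noise-covariance override (e.g. an all-zero
#'   matrix makes the two sessions identical).
#' @param seed Integer seed.
#' @return A long tibble with two rows per subject: `subject_id`,
#'   `session` (1, 2) and the output columns.
#' @examples
#' simulate_repeats(published_heart_age_model("male"), m = 3, seed = 1)
#' @export
simulate_repeats <- function(model, m, age_range = c(20, 80),
                             delta_sd = 7.5, lambda_cov = NULL,
                             seed = NULL) {
  stopifnot(inherits(model, "heart_age_model"))
  if (m < 1) abort("`m` must be at least 1.")
  sig <- if (is.null(lambda_cov)) model$lambda_cov else as.matrix(lambda_cov)
  local_seed(seed, {
    x <- runif(m, age_range[1], age_range[2])
    delta <- rnorm(m, 0, delta_sd)
    mean_y <- design_rows(x) %*% t(model$beta) + outer(delta, model$theta)
    y1 <- mean_y + rmvnorm0(m, sig)
    y2 <- mean_y + rmvnorm0(m, sig)
    out <- dplyr::bind_rows(
      dplyr::bind_cols(tibble(subject_id = sprintf("rep-%04d", seq_len(m)),
                              session = 1L),
                       as_tibble(as.data.frame(y1))),
      dplyr::bind_cols(tibble(subject_id = sprintf("rep-%04d", seq_len(m)),
                              session = 2L),
                       as_tibble(as.data.frame(y2))))
    names(out)[-(1:2)] <- model$output_ids
    dplyr::arrange(out, .data$subject_id, .data$session)
  })
}

#' Synthetic evaluation-group scenarios
#'
#' Builds the five cohorts used for group-level evaluation, sized and mixed
#' like the published study groups: healthy non-athlete training (n = 545)
#' and test (n = 183) sets, endurance athletes (n = 48), risk-factor
#' subjects (n = 221) and imaging-confirmed disease subjects (n = 441),
#' with the published female percentages and age-band mixes. Healthy
#' cohorts have heart-age offset centered at 0; the athlete, risk-factor
#' and disease cohorts use positive offset means (defaults 2, 8, 18 years)
#' chosen as plausible calibration defaults — configurable, not estimates.
#'
#' @param seed Integer seed; each cohort gets its own derived sub-seed.
#' @param models Named list of gender-specific models (default the
#'   published ones) used as the generative truth.
#' @param delta_means Named numeric vector of offset means (years) for
#'   `ATH`, `RFS`, `DIS`; healthy cohorts are always centered at 0.
#' @param delta_sd Offset standard deviation (years), default 7.5.
#' @return A named list of cohort tibbles: `HNA_train`, `HNA_test`, `ATH`,
#'   `RFS`, `DIS`.
#' @examples
#' sc <- make_group_scenarios(seed = 1)
#' vapply(sc, nrow, integer(1))
#' @export
make_group_scenarios <- function(seed = NULL,
                                 models = published_heart_age_models(),
                                 delta_means = c(ATH = 2, RFS = 8, DIS = 18),
                                 delta_sd = 7.5) {
  specs <- list(
    HNA_train = list(n = 545, female = 0.41, bands = c(0.56, 0.36, 0.08),
                     delta_mean = 0),
    HNA_test = list(n = 183, female = 0.43, bands = c(0.55, 0.36, 0.09),
                    delta_mean = 0),
    ATH = list(n = 48, female = 0.38, bands = c(0.92, 0.06, 0.02),
               delta_mean = unname(delta_means["ATH"])),
    RFS = list(n = 221, female = 0.47, bands = c(0.10, 0.59, 0.31),
               delta_mean = unname(delta_means["RFS"])),
    DIS = list(n = 441, female = 0.34, bands = c(0.07, 0.50, 0.43),
               delta_mean = unname(delta_means["DIS"])))

  out <- vector("list", length(specs))
  names(out) <- names(specs)
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    sub_seed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    out[[i]] <- simulate_cohort(
      models, n = s$n, gender_mix = 1 - s$female,
      delta_mean = s$delta_mean, delta_sd = delta_sd,
      group = names(specs)[i],
      age_bands = list(breaks = c(20, 41, 61, 81), probs = s$bands),
      seed = sub_seed)
  }
  out
}
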