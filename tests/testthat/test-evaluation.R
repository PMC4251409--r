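test_that("fraction_above counts strict exceedance only", {
  # all residuals zero: heart age equals body age, ties are not above
  zero <- tibble::tibble(body_age = c(30, 40, 50),
                         heart_age = c(30, 40, 50))
  expect_equal(fraction_above(zero), 0)

  # 27 of 48 above: the reporting format used for athlete-style groups
  ath <- tibble::tibble(body_age = rep(40, 48),
                        heart_age = 40 + c(rep(1, 27), rep(-1, 21)))
  expect_equal(fraction_above(ath), 0.5625)

  expect_equal(fraction_above(tibble::tibble(delta = c(-1, 1))), 0.5)
  expect_error(fraction_above(tibble::tibble(body_age = numeric(),
                                             heart_age = numeric())),
               "empty")
})

test_that("fraction_above ignores subject ordering and labels", {
  set.seed(12)
  pred <- tibble::tibble(subject_id = sample(letters[1:20]),
                         body_age = runif(20, 20, 80),
                         heart_age = runif(20, 20, 80))
  shuffled <- pred[sample(nrow(pred)), ]
  shuffled$subject_id <- paste0("zz-", shuffled$subject_id)
  expect_equal(fraction_above(pred), fraction_above(shuffled))
})

test_that("shrinkage slope recovers the model's shrinkage weight", {
  models <- published_heart_age_models()
  # theta = 0: predictions never leave the prior mean, slope 0
  null_model <- heart_age_model("male", beta = models$male$beta,
                                theta = c(0, 0),
                                lambda_cov = models$male$lambda_cov)
  cohort <- simulate_cohort(null_model, n = 500, gender_mix = 1, seed = 41)
  p0 <- predict_heart_age(cohort, null_model)
  p0$a_true <- cohort$a_true
  expect_equal(shrinkage_slope(p0), 0, tolerance = 1e-12)

  # published male model at large n: slope near w
  big <- simulate_cohort(models$male, n = 40000, gender_mix = 1, seed = 42)
  slope <- shrinkage_slope(predict_heart_age(big, models$male))
  expect_equal(slope, shrinkage_weight(models$male), tolerance = 0.01)

  # negligible noise: slope approaches 1
  strong <- heart_age_model("male", beta = c(0, 1, 0), theta = 5,
                            lambda_cov = 1e-4)
  sc <- simulate_cohort(strong, n = 3000, gender_mix = 1, seed = 43)
  expect_equal(shrinkage_slope(predict_heart_age(sc, strong)), 1,
               tolerance = 1e-3)

  same <- tibble::tibble(body_age = 1:5, heart_age = 1:5, a_true = 1:5)
  expect_error(shrinkage_slope(same), "zero variance")
})

test_that("paired prediction difference handles the degenerate self-contrast", {
  pred <- tibble::tibble(gender = c(1, 1, 2, 2),
                         heart_age = c(30, 40, 50, 60))
  d <- prediction_difference_ci(pred, pred)
  expect_equal(d$mean_diff, c(0, 0))
  expect_equal(d$conf_low, c(0, 0))
  expect_equal(d$conf_high, c(0, 0))
})

test_that("GS/NGS comparison separates genders generated from distinct models", {
  models <- published_heart_age_models()
  cohort <- simulate_cohort(models, n = 4000, seed = 51)
  reps <- simulate_repeats(models$male, m = 15, seed = 52)
  cmp <- compare_gs_ngs(cohort, reps)
  male_row <- cmp[cmp$gender == "male", ]
  female_row <- cmp[cmp$gender == "female", ]
  # pooled model biased upward for males, downward for females
  expect_gt(male_row$conf_low, 0)
  expect_lt(female_row$conf_high, 0)

  expect_error(compare_gs_ngs(cohort[cohort$gender == 1, ], reps),
               "both genders")
})

test_that("GS/NGS difference is null-centered when genders share parameters", {
  # With identical male/female generative parameters the pooled and
  # gender-specific fits estimate the same model, so the per-gender mean
  # difference is estimation noise centered at zero and far smaller than
  # under genuinely distinct gender models.
  male <- published_heart_age_model("male")
  shared <- list(male = male,
                 female = heart_age_model("female", beta = male$beta,
                                          theta = male$theta,
                                          lambda_cov = male$lambda_cov))
  n_rep <- 25
  diffs <- matrix(NA_real_, n_rep, 2)
  for (r in seq_len(n_rep)) {
    cohort <- simulate_cohort(shared, n = 400, seed = 700 + r)
    reps <- simulate_repeats(male, m = 15, seed = 800 + r)
    cmp <- suppressWarnings(compare_gs_ngs(cohort, reps))
    diffs[r, ] <- cmp$mean_diff[match(c("male", "female"), cmp$gender)]
  }
  for (j in 1:2) {
    se <- sd(diffs[, j]) / sqrt(n_rep)
    expect_lt(abs(mean(diffs[, j])), 4 * se)
  }

  # distinct published gender models: differences dwarf the null case
  models <- published_heart_age_models()
  cohort_d <- simulate_cohort(models, n = 400, seed = 777)
  cmp_d <- compare_gs_ngs(cohort_d,
                          simulate_repeats(male, m = 15, seed = 778))
  expect_gt(min(abs(cmp_d$mean_diff)), 5 * max(abs(diffs)))
})

test_that("recovery reports satisfy RMSE >= |bias| and shrink with n", {
  set.seed(61)
  est <- tibble::tibble(parameter = rep(c("theta1", "theta2"), each = 50),
                        estimate = c(rnorm(50, 0.17, 0.02),
                                     rnorm(50, 0.30, 0.05)))
  rep_tbl <- recovery_report(est, c(theta1 = 0.170889, theta2 = 0.265498),
                             seed = 61)
  expect_true(all(rep_tbl$rmse >= abs(rep_tbl$bias)))
  expect_equal(rep_tbl$n_replicates, c(50, 50))

  rmse_at <- function(n, seed) {
    model <- published_heart_age_model("male")
    cohort <- simulate_cohort(model, n = n, gender_mix = 1, seed = seed)
    fit <- fit_age_regression(cohort$body_age, cohort$y1, "y1", "male")
    sqrt(mean((fit$coeffs[2] - model$beta[1, 2])^2))
  }
  errs <- vapply(c(200, 2000, 20000), rmse_at, numeric(1), seed = 62)
  expect_lt(errs[3], errs[1])
})
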