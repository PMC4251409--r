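gender_label <- heartage:::gender_label

test_that("cohorts are reproducible and respect degenerate noise", {
  models <- published_heart_age_models()
  a <- simulate_cohort(models, n = 40, seed = 7)
  b <- simulate_cohort(models, n = 40, seed = 7)
  expect_identical(a, b)
  c <- simulate_cohort(models, n = 40, seed = 8)
  expect_false(identical(a$y1, c$y1))

  # zero noise and zero offset: outputs sit exactly on the age curve
  exact <- simulate_cohort(models, n = 30, delta_sd = 0, delta_mean = 0,
                           lambda_cov = matrix(0, 2, 2), seed = 9)
  for (g in c(1L, 2L)) {
    rows <- exact$gender == g
    m <- models[[gender_label(g)]]
    expected <- cbind(1, exact$body_age[rows], exact$body_age[rows]^2) %*%
      t(m$beta)
    expect_identical(as.matrix(exact[rows, c("y1", "y2")]),
                     expected, ignore_attr = TRUE)
    expect_identical(exact$a_true[rows], exact$body_age[rows])
  }
})

test_that("cohort moments match the generative identity", {
  # Cov(y - beta x_vec) = theta theta' sigma_a^2 + Lambda
  model <- published_heart_age_model("male")
  n <- 50000
  cohort <- simulate_cohort(model, n = n, gender_mix = 1, seed = 123)
  resid <- as.matrix(cohort[, c("y1", "y2")]) -
    cbind(1, cohort$body_age, cohort$body_age^2) %*% t(model$beta)
  expected <- outer(model$theta, model$theta) * 7.5^2 + model$lambda_cov
  observed <- stats::cov(resid)
  # 3 Monte-Carlo standard errors per entry; Var(s_jk) for Gaussian data
  mc_se <- sqrt((expected^2 + outer(diag(expected), diag(expected))) / n)
  expect_true(all(abs(observed - expected) < 3 * mc_se))
})

test_that("repeated measures share the latent subject and differ by noise", {
  model <- published_heart_age_model("male")
  reps <- simulate_repeats(model, m = 6, seed = 21)
  expect_equal(nrow(reps), 12)
  expect_identical(simulate_repeats(model, m = 6, seed = 21), reps)

  reps0 <- simulate_repeats(model, m = 5, lambda_cov = matrix(0, 2, 2),
                            seed = 22)
  d <- heartage:::repeat_differences(reps0, c("y1", "y2"))
  expect_true(all(d == 0))

  expect_error(simulate_repeats(model, m = 0), "at least 1")
})

test_that("lambda estimation from simulated repeats is unbiased at m = 15", {
  model <- published_heart_age_model("male")
  truth <- model$lambda_cov
  n_rep <- 300
  ests <- array(NA_real_, c(2, 2, n_rep))
  for (r in seq_len(n_rep)) {
    reps <- simulate_repeats(model, m = 15, seed = 5000 + r)
    ests[, , r] <- suppressWarnings(
      estimate_lambda(reps, c("y1", "y2"), nonpd = "diagonal"))
  }
  est_mean <- apply(ests, c(1, 2), mean)
  mc_se <- apply(ests, c(1, 2), sd) / sqrt(n_rep)
  expect_true(all(abs(est_mean - truth) < 3 * mc_se))
})

test_that("group scenarios reproduce the study-group sizes and mixes", {
  sc <- make_group_scenarios(seed = 31)
  expect_named(sc, c("HNA_train", "HNA_test", "ATH", "RFS", "DIS"))
  expect_equal(vapply(sc, nrow, integer(1)),
               c(HNA_train = 545L, HNA_test = 183L, ATH = 48L,
                 RFS = 221L, DIS = 441L))
  expect_identical(make_group_scenarios(seed = 31)$DIS, sc$DIS)

  # female fraction and age mix approximate the configured percentages
  expect_equal(mean(sc$HNA_train$gender == 2L), 0.41, tolerance = 0.08)
  expect_equal(mean(sc$DIS$body_age > 60), 0.43, tolerance = 0.08)
  expect_gt(mean(sc$ATH$body_age <= 41), 0.8)

  # healthy cohorts centered, shifted groups increasingly above body age
  expect_equal(mean(sc$HNA_train$delta_true), 0, tolerance = 1.5)
  expect_gt(mean(sc$RFS$delta_true), 4)
  expect_gt(mean(sc$DIS$delta_true), mean(sc$RFS$delta_true))
})

test_that("predicted fraction above body age increases with the offset mean", {
  models <- published_heart_age_models()
  fracs <- vapply(c(0, 2, 8, 18), function(dm) {
    cohort <- simulate_cohort(models, n = 2000, delta_mean = dm,
                              seed = 600 + dm)
    fraction_above(predict_heart_age(cohort, models))
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
  expect_gt(fracs[4], 0.95)   # disease-like shift: nearly all above
})

test_that("invalid simulation configs are rejected", {
  models <- published_heart_age_models()
  expect_error(simulate_cohort(models, n = 0), "at least 1")
  expect_error(simulate_cohort(models, n = 5, delta_sd = -1),
               "non-negative")
  expect_error(simulate_cohort(models, n = 5, age_range = c(10, 80)),
               "20")
})
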