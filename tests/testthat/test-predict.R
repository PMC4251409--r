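test_that("single-output closed form matches hand evaluation", {
  # x = 50, theta = 1, lambda2 = 1, residual = 1:
  # a_hat = 50 + 1 / (1/56.25 + 1)
  p <- predict_heart_age_single(50, y = 1, coeffs = c(0, 0, 0),
                                theta = 1, lambda2 = 1)
  expect_equal(p$heart_age, 50 + 1 / (1 / 56.25 + 1), tolerance = 1e-12)
  expect_equal(p$heart_age, 50.9825, tolerance = 1e-4)

  # zero residual: the posterior mean is the prior mean
  x <- c(25, 50, 75)
  coeffs <- c(2, 0.3, -0.001)
  y <- drop(cbind(1, x, x^2) %*% coeffs)
  p0 <- predict_heart_age_single(x, y, coeffs, theta = 0.8, lambda2 = 2)
  expect_equal(p0$heart_age, x, tolerance = 1e-12)

  # theta = 0: uninformative output, posterior is the prior
  pt <- predict_heart_age_single(50, 10, c(0, 0, 0), theta = 0, lambda2 = 1)
  expect_equal(pt$heart_age, 50)
  expect_equal(pt$posterior_sd, 7.5)

  expect_error(predict_heart_age_single(50, 1, c(0, 0, 0), 1, lambda2 = 0),
               "positive")
})

test_that("multivariate predictor returns the prior mean at zero residual", {
  model <- published_heart_age_model("male")
  for (x in c(20, 35.5, 50, 64.2, 80)) {
    y <- drop(model$beta %*% c(1, x, x^2))
    p <- predict_heart_age(subject_row(x, y, model), model)
    expect_equal(p$heart_age, x, tolerance = 1e-10)
  }
})

test_that("published male worked example shrinks a +10-year offset to ~59.04", {
  model <- published_heart_age_model("male")
  x <- 50
  y <- drop(model$beta %*% c(1, x, x^2)) + model$theta * 10
  p <- predict_heart_age(subject_row(x, y, model), model)
  expect_equal(p$heart_age, 59.036, tolerance = 1e-3)
  expect_equal(shrinkage_weight(model), 0.9036, tolerance = 1e-4)
  expect_equal(heartage:::output_precision(model), 0.166563,
               tolerance = 1e-5)
})

test_that("k = 1 multivariate formula reduces to the single-output formula", {
  set.seed(77)
  for (i in 1:100) {
    coeffs <- c(rnorm(1, 0, 5), rnorm(1, 0, 0.2), rnorm(1, 0, 0.005))
    theta <- rnorm(1, 0, 0.5)
    lambda2 <- runif(1, 0.2, 5)
    model <- heart_age_model("male", beta = coeffs, theta = theta,
                             lambda_cov = lambda2)
    x <- runif(1, 20, 80)
    y <- rnorm(1, drop(model$beta %*% c(1, x, x^2)), 3)
    single <- predict_heart_age_single(x, y, coeffs, theta, lambda2)
    multi <- predict_heart_age(subject_row(x, y, model), model)
    expect_equal(multi$heart_age, single$heart_age, tolerance = 1e-12)
    expect_equal(multi$posterior_sd, single$posterior_sd, tolerance = 1e-12)
  }
})

test_that("prediction offset is linear in the residual and bounded", {
  set.seed(88)
  for (k in 1:3) {
    model <- random_model(k)
    x <- runif(1, 20, 80)
    base <- drop(model$beta %*% c(1, x, x^2))
    r <- rnorm(k)
    p1 <- predict_heart_age(subject_row(x, base + r, model), model)
    p2 <- predict_heart_age(subject_row(x, base + 2 * r, model), model)
    expect_equal(2 * p1$delta, p2$delta, tolerance = 1e-10)

    # |a_hat - x| <= |theta' Lambda^-1 r| * sigma_a^2
    score <- abs(drop(crossprod(model$theta, model$lambda_inv %*% r)))
    expect_lte(abs(p1$delta), score * model$sigma_a^2 + 1e-12)
  }
})

test_that("posterior sd equals sigma_a at theta = 0 and shrinks as |theta| grows", {
  lambda <- random_lambda(2)
  m0 <- heart_age_model("male", beta = matrix(0, 2, 3), theta = c(0, 0),
                        lambda_cov = lambda)
  expect_equal(posterior_sd(m0), 7.5)

  sds <- vapply(c(0.1, 0.5, 1, 2), function(t1) {
    posterior_sd(heart_age_model("male", beta = matrix(0, 2, 3),
                                 theta = c(t1, 0.3), lambda_cov = lambda))
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
  expect_true(all(sds < 7.5))
})

test_that("gender-specific model lists dispatch on the gender column", {
  models <- published_heart_age_models()
  x <- 44
  y_m <- drop(models$male$beta %*% c(1, x, x^2))
  y_f <- drop(models$female$beta %*% c(1, x, x^2))
  data <- tibble::tibble(
    gender = c("M", "F"), body_age = x,
    y1 = c(y_m[1], y_f[1]), y2 = c(y_m[2], y_f[2]))
  p <- predict_heart_age(data, models)
  expect_equal(p$heart_age, c(x, x), tolerance = 1e-10)

  # cross-assignment must not return the prior mean
  p_swapped <- predict_heart_age(
    dplyr::mutate(data, gender = rev(gender)), models)
  expect_false(any(abs(p_swapped$heart_age - x) < 1e-6))
})

test_that("prediction inputs are validated", {
  model <- published_heart_age_model("male")
  expect_error(predict_heart_age(tibble::tibble(body_age = 50, y1 = 1),
                                 model), "y2")
  expect_error(predict_heart_age(
    tibble::tibble(body_age = 50, y1 = NA_real_, y2 = 1), model),
    "y1.*non-finite")
  expect_error(predict_heart_age(
    tibble::tibble(body_age = 50, y1 = 0, y2 = 1),
    published_heart_age_models()), "gender")
})
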