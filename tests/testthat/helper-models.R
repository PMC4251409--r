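# Shared fixtures: small models and randomized instances built in code.

# Random SPD noise covariance, well-conditioned.
random_lambda <- function(k) {
  a <- matrix(rnorm(k * k), k)
  crossprod(a) + diag(0.5, k)
}

# Random k-output model with realistic-scale coefficients.
random_model <- function(k, gender = "male", sigma_a = 7.5) {
  heart_age_model(
    gender = gender,
    beta = cbind(rnorm(k, 0, 5), rnorm(k, 0, 0.2), rnorm(k, 0, 0.005)),
    theta = rnorm(k, 0, 0.5),
    lambda_cov = random_lambda(k),
    sigma_a = sigma_a)
}

# One subject drawn from the model's generative process.
random_instance <- function(model, delta_sd = 7.5) {
  x <- runif(1, 20, 80)
  delta <- rnorm(1, 0, delta_sd)
  eps <- drop(heartage:::rmvnorm0(1, model$lambda_cov))
  y <- drop(model$beta %*% c(1, x, x^2)) + model$theta * delta + eps
  list(x = x, y = y, delta = delta)
}

# Posterior mean by dense-grid numerical integration of the Bayes-rule
# posterior; the independent oracle for the closed form.
grid_posterior_mean <- function(x, y, model, half_width = 60, by = 0.02) {
  grid <- seq(x - half_width, x + half_width, by = by)
  attr(posterior_density(grid, x, y, model), "mean")
}

# One-row subject tibble for a (x, y) pair under `model`.
subject_row <- function(x, y, model, gender = model$gender) {
  out <- tibble::as_tibble(as.data.frame(
    matrix(y, nrow = length(x), dimnames = list(NULL, model$output_ids))))
  out$body_age <- x
  out$gender <- gender
  out
}

# Raw advanced-ECG record with internally consistent synthetic values.
raw_record <- function(subject_id = "s1", ...) {
  defaults <- tibble::tibble(
    subject_id = subject_id, gender = 1, body_age = 45, group = "HNA",
    taxis = 38, pd = 102, frqrsmax = 42, hfp = 180, rmssum = 55,
    spatialjt = 310, iiqtvi = -1.1, unexqtvi = 0.6, qrsaxis = 25,
    meanqrst = 70, idr = 2.4)
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}
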