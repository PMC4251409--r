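#' Plot predicted heart age against body age
#'
#' The canonical diagnostic view: one point per subject, the identity line
#' marking heart age equal to body age. Healthy cohorts should scatter
#' around the line; risk-factor and disease groups sit mostly above it.
#'
#' @param object A [predict_heart_age()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.heart_age_prediction <- function(object, ...) {
  df <- as_tibble(object)
  has_gender <- "gender" %in% names(df)
  if (has_gender) {
    df$gender <- factor(gender_label(normalize_gender(df$gender)),
                        levels = c("male", "female"))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$body_age,
                                        y = .data$heart_age)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(x = "Body age (years)", y = "Predicted heart age (years)")
  p <- if (has_gender) {
    p + ggplot2::geom_point(ggplot2::aes(shape = .data$gender,
                                         colour = .data$gender),
                            alpha = 0.7)
  } else {
    p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::theme_minimal()
}

#' Plot the posterior density of heart age for one subject
#'
#' Draws the grid-evaluated posterior ([posterior_density()]) with the
#' closed-form posterior mean and the prior mean (body age) marked.
#'
#' @param x Body age (years).
#' @param y Length-k vector of ECG outputs.
#' @param model A [heart_age_model()].
#' @param a_grid Evaluation grid; defaults to `x +/- 6 sigma_a` at 0.05-year
#'   spacing.
#' @return A ggplot object.
#' @export
plot_heart_age_posterior <- function(x, y, model,
                                     a_grid = NULL) {
  if (is.null(a_grid)) {
    span <- 6 * model$sigma_a
    a_grid <- seq(x - span, x + span, by = 0.05)
  }
  dens <- posterior_density(a_grid, x, y, model)
  subj <- as_tibble(as.data.frame(matrix(y, nrow = 1,
                                         dimnames = list(NULL, model$output_ids))))
  subj$body_age <- x
  one <- predict_heart_age(subj, model)
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$a, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = x, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = one$heart_age, colour = "red") +
    ggplot2::labs(x = "Heart age (years)", y = "Posterior density",
                  subtitle = sprintf(
                    "body age %.1f, posterior mean %.2f (sd %.2f)",
                    x, one$heart_age, one$posterior_sd)) +
    ggplot2::theme_minimal()
}
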