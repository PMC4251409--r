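#' Transform raw advanced-ECG variables into the composite feature vectors
#'
#' Builds, per subject, the two length-7 feature vectors that enter the
#' composite ECG outputs:
#' * `upsilon1 = (1, Taxis, Pd, sin(FrQRSMax * pi/180), log(HFP),
#'   log(RMSsum), log(SpatialJT))`
#' * `upsilon2 = (1, IIQTVI, UnExQTVI, sin(QRSaxis * pi/180), Pd,
#'   MeanQRS-T, log(IDR))`
#'
#' Angles are in degrees and are converted to radians via pi/180 before the
#' sine; logarithms are natural. The log-argument fields (`hfp`, `rmssum`,
#' `spatialjt`, `idr`) must be strictly positive. Units of the raw
#' variables are taken as provided and must match the units in force when
#' the composite coefficients were fitted; no unit conversion is performed.
#' Records with missing raw fields are rejected, not imputed.
#'
#' @param data A data frame with one row per subject and raw-variable
#'   columns `taxis`, `pd`, `frqrsmax`, `hfp`, `rmssum`, `spatialjt`,
#'   `iiqtvi`, `unexqtvi`, `qrsaxis`, `meanqrst`, `idr` (the `_deg`
#'   suffixed aliases used by the delimited-text schema are accepted).
#' @return A tibble: any `subject_id` column, then `u1_1 ... u1_7` and
#'   `u2_1 ... u2_7` in the fixed order above.
#' @examples
#' rec <- tibble::tibble(
#'   subject_id = "s1", taxis = 40, pd = 100, frqrsmax = 90, hfp = 1,
#'   rmssum = 50, spatialjt = 300, iiqtvi = 0.5, unexqtvi = 0.4,
#'   qrsaxis = 0, meanqrst = 60, idr = 2)
#' transform_features(rec)
#' @export
transform_features <- function(data) {
  data <- canonical_raw_names(as_tibble(data))
  raw_cols <- c("taxis", "pd", "frqrsmax", "hfp", "rmssum", "spatialjt",
                "iiqtvi", "unexqtvi", "qrsaxis", "meanqrst", "idr")
  require_columns(data, raw_cols, "`data`")

  ids <- if ("subject_id" %in% names(data)) data$subject_id else
    as.character(seq_len(nrow(data)))
  for (col in raw_cols) {
    miss <- !is.finite(data[[col]])
    if (any(miss)) {
      abort(sprintf("Raw ECG variable `%s` is missing/non-finite for subject(s) %s; records with missing raw fields are rejected.",
                    col, paste(utils::head(ids[miss], 5), collapse = ", ")))
    }
  }
  for (col in c("hfp", "rmssum", "spatialjt", "idr")) {
    bad <- data[[col]] <= 0
    if (any(bad)) {
      abort(sprintf("`%s` must be strictly positive (log argument); offending subject(s): %s",
                    col, paste(utils::head(ids[bad], 5), collapse = ", ")))
    }
  }

  deg2rad <- pi / 180
  u1 <- cbind(1, data$taxis, data$pd, sin(data$frqrsmax * deg2rad),
              log(data$hfp), log(data$rmssum), log(data$spatialjt))
  u2 <- cbind(1, data$iiqtvi, data$unexqtvi, sin(data$qrsaxis * deg2rad),
              data$pd, data$meanqrst, log(data$idr))
  colnames(u1) <- paste0("u1_", 1:7)
  colnames(u2) <- paste0("u2_", 1:7)
  out <- as_tibble(cbind(as.data.frame(u1), as.data.frame(u2)))
  if ("subject_id" %in% names(data)) {
    out <- dplyr::bind_cols(data["subject_id"], out)
  }
  out
}

# The delimited-text schema suffixes angle columns with _deg; strip to the
# canonical internal names.
canonical_raw_names <- function(data) {
  aliases <- c(taxis_deg = "taxis", frqrsmax_deg = "frqrsmax",
               qrsaxis_deg = "qrsaxis", meanqrst_deg = "meanqrst")
  for (from in names(aliases)) {
    to <- aliases[[from]]
    if (from %in% names(data) && !(to %in% names(data))) {
      names(data)[names(data) == from] <- to
    }
  }
  data
}

#' Composite ECG outputs from raw variables
#'
#' Computes the two composite outputs `y1 = gamma1' upsilon1` and
#' `y2 = gamma2' upsilon2` for every subject, where the feature vectors
#' come from [transform_features()] and the coefficient vectors default to
#' the published logistic-regression coefficients
#' ([published_composite_coefficients()]).
#'
#' @param data A data frame of raw-variable records (see
#'   [transform_features()]); identifier columns `subject_id`, `gender`,
#'   `body_age`/`age`, `group` are carried through.
#' @param coeffs A list with `gamma1` and `gamma2` (length-7 vectors,
#'   intercept first).
#' @return A tibble: carried-through identifier columns plus `y1`, `y2`.
#' @export
composite_scores <- function(data, coeffs = published_composite_coefficients()) {
  data <- canonical_raw_names(as_tibble(data))
  feats <- transform_features(data)
  u1 <- as.matrix(feats[, paste0("u1_", 1:7)])
  u2 <- as.matrix(feats[, paste0("u2_", 1:7)])
  y <- composite_from_features(u1, u2, coeffs)
  keep <- intersect(c("subject_id", "gender", "body_age", "age", "group",
                      "a_true", "delta_true"), names(data))
  dplyr::bind_cols(data[, keep, drop = FALSE],
                   tibble(y1 = y[, 1], y2 = y[, 2]))
}

#' @rdname composite_scores
#' @param upsilon1,upsilon2 Length-7 feature vectors (or n x 7 matrices) in
#'   the [transform_features()] order.
#' @return `composite_from_features()` returns an n x 2 matrix with columns
#'   `y1`, `y2` (a 1 x 2 matrix for vector input).
#' @export
composite_from_features <- function(upsilon1, upsilon2,
                                    coeffs = published_composite_coefficients()) {
  if (is.null(dim(upsilon1))) upsilon1 <- matrix(upsilon1, nrow = 1)
  if (is.null(dim(upsilon2))) upsilon2 <- matrix(upsilon2, nrow = 1)
  if (ncol(upsilon1) != 7 || ncol(upsilon2) != 7 ||
      length(coeffs$gamma1) != 7 || length(coeffs$gamma2) != 7) {
    abort("Feature vectors and coefficient vectors must have length 7 (intercept + 6 features).")
  }
  cbind(y1 = drop(upsilon1 %*% coeffs$gamma1),
        y2 = drop(upsilon2 %*% coeffs$gamma2))
}

#' Refit composite-score coefficients by logistic regression
#'
#' Fits maximum-likelihood logistic-regression coefficients of a binary
#' disease label (healthy non-athlete = 0, heart disease = 1) on a 7-column
#' feature matrix (intercept included as the first column), the procedure
#' that produced the published `gamma1`/`gamma2`. Fitting uses iteratively
#' reweighted least squares ([stats::glm()] with binomial family), up to
#' 100 iterations.
#'
#' @param features Numeric n x 7 matrix whose first column is the
#'   intercept (all ones), remaining columns the transformed features.
#' @param labels Binary 0/1 vector of length n.
#' @return Length-7 coefficient vector.
#' @export
fit_composite_coefficients <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (ncol(features) != 7) abort("`features` must have 7 columns (intercept first).")
  if (nrow(features) != length(labels)) {
    abort("`features` and `labels` must have matching rows.")
  }
  if (nrow(features) <= 7) abort("Need n > 7 observations to fit 7 coefficients.")
  if (!all(labels %in% c(0, 1))) abort("`labels` must be 0/1.")
  if (length(unique(labels)) < 2) {
    abort("Both classes (0 and 1) must be present to fit a logistic regression.")
  }
  if (!all(features[, 1] == 1)) {
    abort("The first feature column must be the intercept (all ones).")
  }

  x <- features[, -1, drop = FALSE]
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  fit <- suppressWarnings(
    stats::glm(labels ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  p <- fit$fitted.values
  separated <- all(p[labels == 1] > 1 - 1e-8) && all(p[labels == 0] < 1e-8)
  if (separated || max(abs(coef(fit))) > 1e8) {
    abort("Complete separation: coefficient estimates diverge; consider a penalized logistic regression.")
  }
  if (!fit$converged) {
    warn("Logistic regression did not converge within 100 iterations.")
  }
  unname(coef(fit))
}
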