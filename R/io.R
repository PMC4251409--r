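#' Read a subjects file
#'
#' Reads comma-separated, header-required subject data (UTF-8, "." decimal
#' separator). Accepted schemas, detected by column:
#' * precomputed outputs: `id, gender, age, [group,] y1, y2, ...`
#' * raw advanced-ECG variables: `id, gender, age, group, taxis_deg, pd,
#'   frqrsmax_deg, hfp, rmssum, spatialjt, iiqtvi, unexqtvi, qrsaxis_deg,
#'   meanqrst_deg, idr`
#'
#' Gender is accepted as 1/2 or M/F and normalized to 1 = male,
#' 2 = female. Ages must be at least 20 (the model's validity range) and
#' are used unrounded.
#'
#' @param path Path to a CSV file.
#' @param min_age Reject subjects younger than this (default 20; set to
#'   `-Inf` to disable).
#' @return A tibble with normalized columns `subject_id`, `gender`,
#'   `body_age` plus the remaining schema columns.
#' @export
read_subjects <- function(path, min_age = 20) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  names(raw) <- tolower(names(raw))
  if ("id" %in% names(raw) && !"subject_id" %in% names(raw)) {
    names(raw)[names(raw) == "id"] <- "subject_id"
  }
  if ("age" %in% names(raw) && !"body_age" %in% names(raw)) {
    names(raw)[names(raw) == "age"] <- "body_age"
  }
  require_columns(raw, c("subject_id", "gender", "body_age"),
                  sprintf("subjects file %s", path))
  raw$gender <- normalize_gender(raw$gender)
  if (!is.numeric(raw$body_age) || anyNA(raw$body_age)) {
    abort("Column `age` must be numeric with no missing values.")
  }
  young <- raw$body_age < min_age
  if (any(young)) {
    abort(sprintf("%d subject(s) younger than %s years (model applies to adults >= 20): %s",
                  sum(young), format(min_age),
                  paste(utils::head(raw$subject_id[young], 5), collapse = ", ")))
  }
  canonical_raw_names(raw)
}

#' Write predictions as delimited text
#'
#' Writes one row per subject with header
#' `id, gender, body_age, heart_age, posterior_sd, delta`
#' (`delta = heart_age - body_age`), comma-separated with "." decimals.
#'
#' @param predictions A [predict_heart_age()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  predictions <- as_tibble(predictions)
  require_columns(predictions,
                  c("body_age", "heart_age", "posterior_sd", "delta"),
                  "`predictions`")
  out <- data.frame(
    id = if ("subject_id" %in% names(predictions)) {
      predictions$subject_id
    } else {
      seq_len(nrow(predictions))
    },
    gender = if ("gender" %in% names(predictions)) {
      predictions$gender
    } else {
      NA
    },
    body_age = predictions$body_age,
    heart_age = predictions$heart_age,
    posterior_sd = predictions$posterior_sd,
    delta = predictions$delta)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated cohort as delimited text
#'
#' Same schema as the subjects input ([read_subjects()]) plus the
#' generative-truth columns `a_true` and `delta_true`; the generating seed
#' (if recorded) is embedded as a `# seed:` comment-free sidecar JSON next
#' to the file by the command-line interface, not in the CSV itself.
#'
#' @param cohort A [simulate_cohort()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_tibble(cohort)
  out <- as.data.frame(cohort)
  names(out)[names(out) == "subject_id"] <- "id"
  names(out)[names(out) == "body_age"] <- "age"
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read repeated-measure pairs
#'
#' Long-form CSV: one row per (subject, session), columns
#' `id, session, y1, y2, ...` (optionally `gender`).
#'
#' @param path Path to a CSV file.
#' @return A tibble with `subject_id`, `session` and the output columns.
#' @export
read_repeats <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  names(raw) <- tolower(names(raw))
  if ("id" %in% names(raw) && !"subject_id" %in% names(raw)) {
    names(raw)[names(raw) == "id"] <- "subject_id"
  }
  require_columns(raw, c("subject_id", "session"),
                  sprintf("repeats file %s", path))
  raw
}
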