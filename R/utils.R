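# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. A NULL seed leaves the stream untouched.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Canonical gender codes: 1 = male, 2 = female. M/F, male/female and 1/2
# are all accepted on input.
normalize_gender <- function(gender) {
  g <- tolower(trimws(as.character(gender)))
  out <- rep(NA_integer_, length(g))
  out[g %in% c("1", "m", "male")] <- 1L
  out[g %in% c("2", "f", "female")] <- 2L
  if (anyNA(out[!is.na(g) & g != ""])) {
    bad <- unique(g[is.na(out)])
    abort(sprintf(
      "Unknown gender label(s): %s. Use 1/M/male or 2/F/female.",
      paste(bad, collapse = ", ")))
  }
  out
}

gender_label <- function(code) {
  c("male", "female")[as.integer(code)]
}

# Quadratic design row(s) (1, x, x^2) as an n x 3 matrix.
design_rows <- function(x) {
  cbind(1, x, x^2)
}

# sigma_a from either a prior_spec or a bare number.
as_sigma_a <- function(prior) {
  s <- if (inherits(prior, "prior_spec")) prior$sigma_a else prior
  if (!is.numeric(s) || length(s) != 1 || !is.finite(s) || s <= 0) {
    abort("`sigma_a` must be a single positive number (years).")
  }
  as.numeric(s)
}

is_spd <- function(m, tol = 1e-10) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) return(FALSE)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev), 1))
}

# Draws from N(0, sigma) by Cholesky; an all-zero sigma yields exact zeros
# so degenerate-noise checks are exact.
rmvnorm0 <- function(n, sigma) {
  k <- nrow(sigma)
  if (max(abs(sigma)) == 0) return(matrix(0, n, k))
  z <- matrix(rnorm(n * k), n, k)
  z %*% chol(sigma)
}

require_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}
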