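`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_fraction <- function(x, name, allow_one = TRUE) {
  if (!is.numeric(x) || anyNA(x)) stopf("'%s' must be numeric and non-missing", name)
  hi_ok <- if (allow_one) all(x <= 1) else all(x < 1)
  if (!all(x >= 0) || !hi_ok) {
    stopf("'%s' must lie in [0,%s]; got %s", name, if (allow_one) "1" else "1)",
          paste(signif(x[x < 0 | x > 1], 4), collapse = ", "))
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stopf("'%s' must be non-negative and non-missing", name)
  }
  invisible(x)
}

assert_scalar <- function(x, name) {
  if (length(x) != 1L) stopf("'%s' must be a single value", name)
  invisible(x)
}

slugify <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))

## Format doubles so that CSV round-trips are bit-exact (17 significant
## digits are sufficient for IEEE 754 doubles).
format_double <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  out[is.na(x)] <- NA_character_
  out
}

write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_double(out[[j]])
  }
  write.csv(out, path, row.names = FALSE)
}
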