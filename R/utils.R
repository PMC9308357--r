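# Internal helpers shared across modules.

# Strict ISO-8601 date parsing: "" and NA map to NA, anything else must parse.
# Returns Date; attributes bad rows to `column` in the error message.
parse_iso_date <- function(x, column) {
  x <- as.character(x)
  blank <- is.na(x) | !nzchar(trimws(x))
  out <- rep(as.Date(NA), length(x))
  if (any(!blank)) {
    parsed <- as.Date(x[!blank], format = "%Y-%m-%d", optional = TRUE)
    bad <- is.na(parsed)
    if (any(bad)) {
      rows <- which(!blank)[bad]
      stop(sprintf("column '%s': malformed date '%s' in row %d (expected YYYY-MM-DD)",
                   column, x[rows[1]], rows[1]), call. = FALSE)
    }
    out[!blank] <- parsed
  }
  out
}

as_date_scalar <- function(x, what) {
  d <- tryCatch(as.Date(x), error = function(e) as.Date(NA))
  if (length(d) != 1L || is.na(d)) {
    stop(sprintf("'%s' must be a single valid date", what), call. = FALSE)
  }
  d
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Split `total` into `n` integer parts differing by at most one.
distribute_integer <- function(total, n) {
  stopifnot(n >= 1, total >= 0)
  base <- total %/% n
  rem <- total %% n
  c(rep(base + 1L, rem), rep(base, n - rem))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# days -> numeric, robust to Date or difftime input
day_number <- function(x) as.numeric(unclass(as.Date(x)))
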