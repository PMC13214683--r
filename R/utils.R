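# Shared vocabularies and date handling for the JADER-style SRS schema.

srs_sex_levels <- c("male", "female", "unspecified")
srs_age_levels <- c("<20", "20-59", ">=60", "unspecified")
srs_weight_levels <- c("<40", "40-69", ">=70", "unspecified")
srs_role_levels <- c("suspected", "concomitant", "interacting")
srs_route_levels <- c("intravenous", "oral", "other", "unspecified")

#' Parse SRS date strings
#'
#' Dates in the input tables are ISO-8601 `YYYY-MM-DD`, or `YYYY-MM` for
#' partial (year-month only) dates; empty strings are missing. Partial dates
#' are flagged rather than discarded: they are acceptable for
#' disproportionality counting, which ignores dates, but are excluded from
#' time-to-onset extraction.
#'
#' @param x character vector of date strings.
#' @return A tibble with columns `date` (`Date`, `NA` unless complete),
#'   `partial` and `missing` (logicals).
#' @keywords internal
parse_srs_date <- function(x) {
  x <- ifelse(is.na(x), "", trimws(as.character(x)))
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  partial <- grepl("^\\d{4}-\\d{2}$", x)
  date <- rep(as.Date(NA), length(x))
  date[full] <- as.Date(x[full], format = "%Y-%m-%d")
  # invalid calendar dates (e.g. a 30th of February) count as missing
  full <- full & !is.na(date)
  tibble::tibble(date = date, partial = partial, missing = !full & !partial)
}

check_enum <- function(x, levels, what, table) {
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid %s value(s) in %s table: %s (expected one of %s)",
      what, table, paste(bad, collapse = ", "), paste(levels, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

check_columns <- function(df, required, table) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop(sprintf(
      "missing required column '%s' in %s table", miss[1], table
    ), call. = FALSE)
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
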