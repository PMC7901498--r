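#' @importFrom rlang %||% abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map2
#' @importFrom lubridate year month mday leap_year %m-% %m+%
NULL

# Registry year-of-birth carries no month/day; mid-year imputation (1 July)
# bounds the age error at six months either way.
impute_birth_date <- function(year_of_birth) {
  as.Date(sprintf("%d-07-01", as.integer(year_of_birth)))
}

# Completed years between birth_date and date (vectorised).
age_completed <- function(date, birth_date) {
  y <- year(date) - year(birth_date)
  had_birthday <- (month(date) > month(birth_date)) |
    (month(date) == month(birth_date) & mday(date) >= mday(birth_date))
  as.integer(y - !had_birthday)
}

days_in_year <- function(y) ifelse(leap_year(as.integer(y)), 366L, 365L)

as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(x)
  if (anyNA(out) && !all(is.na(x) | x == "")) {
    bad <- x[is.na(out) & !(is.na(x) | x == "")]
    abort(sprintf("Cannot parse %s value(s): %s", what,
                  paste(utils::head(unique(bad), 5), collapse = ", ")))
  }
  out
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

english_regions <- function() {
  c("East Midlands", "East of England", "London", "North East",
    "North West", "South East", "South West", "West Midlands",
    "Yorkshire & The Humber")
}
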