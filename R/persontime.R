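#' Truncate follow-up for death-registration lag
#'
#' Death registration is delayed when a coroner is involved — common for
#' drug-related deaths — so follow-up is stopped some months before the end
#' of mortality linkage to avoid under-counting recent deaths. The cap is
#' either given directly (`cap_date`) or computed as `linkage_end` minus
#' `lag_months` calendar months. Exits are capped, members left with no
#' follow-up are dropped, and deaths on or after the cap are no longer
#' counted (half-open `[entry, cap)`).
#'
#' @param members Cohort from [build_cohort()].
#' @param linkage_end Final date of mortality linkage.
#' @param lag_months Calendar months subtracted from `linkage_end`
#'   (default 6).
#' @param cap_date Direct cap date; overrides the month arithmetic.
#' @return The truncated cohort (same columns and class).
#' @export
truncate_follow_up <- function(members, linkage_end = NULL, lag_months = 6,
                               cap_date = NULL) {
  if (is.null(cap_date)) {
    if (is.null(linkage_end)) abort("supply linkage_end or cap_date")
    if (lag_months < 0) abort("lag_months must be >= 0")
    cap_date <- as_date_strict(linkage_end, "linkage_end") %m-%
      months(lag_months)
  } else {
    cap_date <- as_date_strict(cap_date, "cap_date")
  }
  out <- members |>
    mutate(exit = pmin(.data$exit, cap_date),
           died = .data$died & !is.na(.data$death_date) &
             .data$death_date < cap_date) |>
    filter(.data$entry < .data$exit)
  attrs <- attributes(members)
  attributes(out) <- c(attributes(out),
                       attrs[setdiff(names(attrs),
                                     c(names(attributes(out)), "row.names"))])
  out
}

# Split [entry, exit) into segments of constant attained age and calendar
# year. Fully vectorised: one row per (member, calendar year) is created,
# then each is cut at that year's birthday. Returns one row per segment with
# the id, sex, age, year, segment start and day count.
lexis_segments <- function(patient_id, sex, entry, exit, year_of_birth) {
  stopifnot(all(exit > entry))
  birth <- impute_birth_date(year_of_birth)
  y0 <- year(entry)
  y1 <- year(exit - 1L)
  nyr <- y1 - y0 + 1L
  idx <- rep.int(seq_along(entry), nyr)
  yr <- sequence(nyr, from = y0, by = 1L)

  seg_start <- pmax(entry[idx], lubridate::make_date(yr, 1L, 1L))
  seg_end <- pmin(exit[idx], lubridate::make_date(yr + 1L, 1L, 1L))
  bday <- lubridate::make_date(yr, month(birth[idx]), mday(birth[idx]))
  cut <- pmin(pmax(bday, seg_start), seg_end)

  base_age <- yr - year_of_birth[idx]
  day_counts <- as.integer(c(cut - seg_start, seg_end - cut))
  starts <- c(seg_start, cut)
  out <- tibble(
    patient_id = rep(patient_id[idx], 2L),
    sex = rep(sex[idx], 2L),
    year = rep(yr, 2L),
    age = c(base_age - 1L, base_age),
    seg_start = starts,
    days = day_counts)
  filter(out, .data$days > 0L)
}

#' Day-level Lexis expansion of cohort follow-up
#'
#' Distributes every follow-up day into a (sex, single year of attained age,
#' calendar year) stratum, so that ageing during follow-up is handled
#' exactly: a member contributes to older age strata as they cross their
#' (imputed, 1 July) birthday and to successive calendar years as follow-up
#' spans year ends. Deaths increment the stratum containing the death day;
#' for decedents the exit is extended to the day after death so the death
#' day's risk time is counted (an event must contribute its own risk time).
#' Total days are conserved exactly and asserted on every run.
#'
#' @param members Cohort (possibly truncated); needs `patient_id`, `sex`,
#'   `year_of_birth`, `entry`, `exit`, `died`, `death_date`.
#' @return Tibble: `sex`, `age`, `year`, `days`, `observed_deaths`.
#' @export
expand_person_time <- function(members) {
  check_columns(members, c("patient_id", "sex", "year_of_birth", "entry",
                           "exit", "died"), "members")
  if (nrow(members) == 0) abort("no members to expand")
  if (any(members$exit <= members$entry)) {
    abort("members with exit <= entry must be filtered before expansion")
  }
  died <- members$died & !is.na(members$death_date)
  exit_eff <- members$exit
  exit_eff[died] <- pmax(members$exit[died],
                         members$death_date[died] + 1L)

  seg <- lexis_segments(members$patient_id, members$sex, members$entry,
                        exit_eff, members$year_of_birth)
  strata <- seg |>
    group_by(.data$sex, .data$age, .data$year) |>
    summarise(days = sum(.data$days), .groups = "drop")

  total <- sum(strata$days)
  expected_total <- sum(as.integer(exit_eff - members$entry))
  stopifnot(total == expected_total)

  if (any(died)) {
    dd <- members$death_date[died]
    dcell <- tibble(
      sex = members$sex[died],
      year = year(dd),
      age = age_completed(dd, impute_birth_date(members$year_of_birth[died]))
    ) |>
      count(.data$sex, .data$age, .data$year, name = "observed_deaths")
    strata <- left_join(strata, dcell, by = c("sex", "age", "year")) |>
      mutate(observed_deaths =
               ifelse(is.na(.data$observed_deaths), 0L,
                      .data$observed_deaths))
    if (sum(strata$observed_deaths) != sum(died)) {
      abort("some deaths fell outside their member's follow-up interval")
    }
  } else {
    strata$observed_deaths <- 0L
  }
  arrange(strata, .data$sex, .data$age, .data$year)
}

#' Expected deaths by indirect standardisation
#'
#' Applies reference-population mortality rates to the cohort's person-time
#' strata: each stratum contributes `days / days-in-that-calendar-year ×
#' rate` expected deaths (366-day denominators in leap years). Every stratum
#' with positive person-time must have a rate; missing cells are a hard
#' error listing every missing (sex, age, year) key.
#'
#' @param strata Output of [expand_person_time()].
#' @param rate_table Tibble: `sex`, `age`, `year`, `rate` (deaths per
#'   person-year).
#' @return Expected number of deaths (scalar).
#' @export
expected_deaths <- function(strata, rate_table) {
  check_columns(strata, c("sex", "age", "year", "days"), "strata")
  check_columns(rate_table, c("sex", "age", "year", "rate"), "rate_table")
  if (anyDuplicated(rate_table[c("sex", "age", "year")])) {
    abort("rate_table has duplicate (sex, age, year) entries")
  }
  pos <- filter(strata, .data$days > 0)
  joined <- left_join(pos, rate_table[c("sex", "age", "year", "rate")],
                      by = c("sex", "age", "year"))
  miss <- filter(joined, is.na(.data$rate))
  if (nrow(miss)) {
    abort(paste0("rate_table is missing ", nrow(miss), " cell(s): ",
                 paste(sprintf("(%s, %d, %d)", miss$sex, miss$age,
                               miss$year),
                       collapse = ", ")))
  }
  sum(joined$days / days_in_year(joined$year) * joined$rate)
}

# Exact Poisson bounds for an observed count. Lower: chi-square quantile at
# alpha/2 with 2*O df, halved (0 when O = 0); upper: quantile at 1 - alpha/2
# with 2*(O + 1) df, halved. Equivalent to inverting the Poisson tails.
poisson_exact_bounds <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (any(x < 0)) abort("counts must be non-negative")
  lower <- ifelse(x == 0, 0, stats::qchisq(alpha / 2, 2 * x) / 2)
  upper <- stats::qchisq(1 - alpha / 2, 2 * (x + 1)) / 2
  tibble(lower = lower, upper = upper)
}
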