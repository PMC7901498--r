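#' Smoking status from the most recent smoking record
#'
#' Status is taken from the latest-dated smoking record a patient has
#' (anywhere in their record by default, mirroring "at the most recent
#' record of smoking"); patients with no records are `NO_RECORDS`. Same-day
#' ties resolve `CURRENT` > `EX` > `NEVER`.
#'
#' @param events Clinical events (`patient_id`, `date`, `code_id`,
#'   `terminology`).
#' @param smoking_codes Codelist tibble with `code_id`, `terminology` and a
#'   `status` column tagging each code `CURRENT` / `EX` / `NEVER`; see
#'   [smoking_codelist()].
#' @param patient_ids Patients to report (default: every patient appearing
#'   in `events`).
#' @param before Optional date: only records strictly before this date are
#'   considered (e.g. an index date).
#' @return Tibble: `patient_id`, `smoking` (`CURRENT`, `EX`, `NEVER`,
#'   `NO_RECORDS`).
#' @export
smoking_status <- function(events, smoking_codes = smoking_codelist(),
                           patient_ids = NULL, before = NULL) {
  check_columns(smoking_codes, c("code_id", "terminology", "status"),
                "smoking_codes")
  ev <- tibble(patient_id = as.character(events$patient_id),
               date = as_date_strict(events$date, "event date"),
               code_id = as.character(events$code_id),
               terminology = toupper(as.character(events$terminology)))
  if (!is.null(before)) ev <- filter(ev, .data$date < as_date_strict(before))
  prio <- c(CURRENT = 1L, EX = 2L, NEVER = 3L)
  hits <- ev |>
    inner_join(smoking_codes[c("code_id", "terminology", "status")],
               by = c("code_id", "terminology")) |>
    mutate(.prio = prio[.data$status]) |>
    arrange(.data$patient_id, desc(.data$date), .data$.prio) |>
    distinct(.data$patient_id, .keep_all = TRUE) |>
    select("patient_id", smoking = "status")
  ids <- patient_ids %||% unique(ev$patient_id)
  tibble(patient_id = as.character(ids)) |>
    left_join(hits, by = "patient_id") |>
    mutate(smoking = ifelse(is.na(.data$smoking), "NO_RECORDS",
                            .data$smoking))
}

#' Lifetime history flags
#'
#' A flag (homelessness, prison, alcohol dependence, ...) is set when the
#' patient has at least one matching code at any time — including after
#' cohort exit, since these are recorded *histories*, not time-at-risk
#' covariates.
#'
#' @param events Clinical events.
#' @param flag_codes Tibble with `code_id`, `terminology`, `flag`; see
#'   [flag_codelists()].
#' @param patient_ids Patients to report (default: all in `events`).
#' @return Tibble: `patient_id` plus one logical column per flag.
#' @export
history_flags <- function(events, flag_codes = flag_codelists(),
                          patient_ids = NULL) {
  check_columns(flag_codes, c("code_id", "terminology", "flag"), "flag_codes")
  ev <- tibble(patient_id = as.character(events$patient_id),
               code_id = as.character(events$code_id),
               terminology = toupper(as.character(events$terminology)))
  ids <- patient_ids %||% unique(ev$patient_id)
  hits <- ev |>
    inner_join(flag_codes[c("code_id", "terminology", "flag")],
               by = c("code_id", "terminology")) |>
    distinct(.data$patient_id, .data$flag) |>
    mutate(value = TRUE) |>
    tidyr::pivot_wider(names_from = "flag", values_from = "value",
                       values_fill = FALSE)
  out <- tibble(patient_id = as.character(ids)) |>
    left_join(hits, by = "patient_id")
  for (f in unique(flag_codes$flag)) {
    if (!f %in% names(out)) out[[f]] <- FALSE
    out[[f]][is.na(out[[f]])] <- FALSE
  }
  out
}

#' Baseline characterisation of the cohort
#'
#' Builds the standard baseline table: counts and percentages by age group
#' at index (18-29, 30-39, 40-49, 50-64), sex, region, smoking status,
#' deprivation (IMD) quintile, and lifetime history flags, plus the median
#' and interquartile range of age at entry and of follow-up years. Each
#' categorical block partitions the cohort, so its counts sum to the cohort
#' size; percentages are reported to one decimal place.
#'
#' @param members Cohort from [build_cohort()].
#' @param events Clinical events (used for smoking and flags); may be
#'   `NULL`.
#' @param smoking_codes,flag_codes Tag-bearing codelists; see
#'   [smoking_codelist()] and [flag_codelists()].
#' @return Tibble of class `opicohort_baseline` with columns `variable`,
#'   `level`, `n`, `pct`; medians/IQRs are attached as attribute
#'   `"continuous"` and shown by `glance()`.
#' @export
baseline_table <- function(members, events = NULL,
                           smoking_codes = smoking_codelist(),
                           flag_codes = flag_codelists()) {
  n_total <- nrow(members)
  if (n_total == 0) abort("empty cohort")
  block <- function(variable, values, levels) {
    counts <- table(factor(values, levels = levels), useNA = "no")
    tibble(variable = variable, level = names(counts),
           n = as.integer(counts),
           pct = round(100 * as.integer(counts) / n_total, 1))
  }
  age_group <- cut(members$age_at_entry, c(17, 29, 39, 49, 64),
                   labels = c("18-29", "30-39", "40-49", "50-64"))
  region <- ifelse(is.na(members$region), "Missing", members$region)
  imd <- ifelse(is.na(members$imd_quintile), "Missing",
                as.character(members$imd_quintile))

  blocks <- list(
    block("age_group", age_group, levels(age_group)),
    block("sex", members$sex, c("M", "F")),
    block("region", region, sort(unique(region))),
    block("imd_quintile", imd,
          c(intersect(as.character(1:5), unique(imd)),
            if ("Missing" %in% imd) "Missing")))

  if (!is.null(events)) {
    smk <- smoking_status(events, smoking_codes,
                          patient_ids = members$patient_id)
    blocks <- c(blocks, list(
      block("smoking", smk$smoking,
            c("CURRENT", "EX", "NEVER", "NO_RECORDS"))))
    flg <- history_flags(events, flag_codes,
                         patient_ids = members$patient_id)
    for (f in setdiff(names(flg), "patient_id")) {
      n_f <- sum(flg[[f]])
      blocks <- c(blocks, list(
        tibble(variable = f, level = "recorded", n = n_f,
               pct = round(100 * n_f / n_total, 1))))
    }
  }

  fu_years <- as.numeric(members$exit - members$entry) / 365.25
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE,
                                    type = 7)
  cont <- tibble(
    measure = c("age_at_entry", "follow_up_years"),
    q1 = c(qs(members$age_at_entry)[1], qs(fu_years)[1]),
    median = c(qs(members$age_at_entry)[2], qs(fu_years)[2]),
    q3 = c(qs(members$age_at_entry)[3], qs(fu_years)[3]))

  structure(bind_rows(blocks),
            class = c("opicohort_baseline", class(blocks[[1]])),
            continuous = cont, n_total = n_total)
}

#' @method glance opicohort_baseline
#' @export
glance.opicohort_baseline <- function(x, ...) {
  cont <- attr(x, "continuous")
  tibble(n = attr(x, "n_total"),
         median_age = cont$median[cont$measure == "age_at_entry"],
         median_follow_up_years =
           cont$median[cont$measure == "follow_up_years"])
}

#' Mean age at entry by calendar year of entry
#'
#' External-validation check: the population using illicit opioids in
#' England is ageing, so the mean age of new entrants should drift upward
#' over calendar time.
#'
#' @param members Cohort from [build_cohort()].
#' @return Tibble: `entry_year`, `n`, `mean_age`.
#' @export
entry_age_trend <- function(members) {
  if (nrow(members) == 0) abort("empty cohort")
  members |>
    mutate(entry_year = year(.data$entry)) |>
    group_by(.data$entry_year) |>
    summarise(n = n(), mean_age = mean(.data$age_at_entry),
              .groups = "drop") |>
    arrange(.data$entry_year)
}

#' Plot the entry-age trend
#'
#' @param trend Output of [entry_age_trend()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
plot_entry_age_trend <- function(trend, ...) {
  ggplot2::ggplot(trend,
                  ggplot2::aes(x = .data$entry_year, y = .data$mean_age)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = "Calendar year of cohort entry",
                  y = "Mean age at entry (years)", size = "Entrants") +
    ggplot2::theme_minimal()
}
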