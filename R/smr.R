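#' Standardised mortality ratio with exact Poisson confidence interval
#'
#' SMR = observed / expected deaths, with the observed count treated as
#' Poisson. Confidence bounds come from the chi-square representation of the
#' exact Poisson tails (lower bound 0 when no deaths were observed).
#' Vectorised over `observed` / `expected`.
#'
#' @param observed Observed death count(s).
#' @param expected Expected death count(s) from indirect standardisation;
#'   must be positive.
#' @param alpha Two-sided significance level (default 0.05 for a 95% CI).
#' @return Tibble of class `opicohort_smr`: `observed`, `expected`, `smr`,
#'   `conf.low`, `conf.high`, `alpha`.
#' @examples
#' smr(observed = 12404, expected = 1872.4)
#' @export
smr <- function(observed, expected, alpha = 0.05) {
  if (any(expected <= 0)) abort("expected must be positive")
  if (any(observed < 0)) abort("observed must be non-negative")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  b <- poisson_exact_bounds(observed, alpha)
  structure(
    tibble(observed = as.numeric(observed),
           expected = as.numeric(expected),
           smr = observed / expected,
           conf.low = b$lower / expected,
           conf.high = b$upper / expected,
           alpha = alpha),
    class = c("opicohort_smr", class(tibble())))
}

#' Crude mortality rate per 1,000 person-years
#'
#' Deaths per 1,000 person-years with an exact Poisson interval on the death
#' count. Supply either person-days (converted at 365.25 days/year) or
#' person-years directly.
#'
#' @param deaths Death count(s).
#' @param person_days Follow-up in days (converted at 365.25 days/year).
#' @param person_years Follow-up in years (alternative to `person_days`).
#' @param alpha Two-sided significance level.
#' @return Tibble of class `opicohort_cmr`: `deaths`, `person_years`,
#'   `rate_per_1000`, `conf.low`, `conf.high`, `alpha`.
#' @examples
#' crude_rate(deaths = 12404, person_years = 910567)
#' @export
crude_rate <- function(deaths, person_days = NULL, person_years = NULL,
                       alpha = 0.05) {
  if (is.null(person_years)) {
    if (is.null(person_days)) abort("supply person_days or person_years")
    person_years <- as.numeric(person_days) / 365.25
  }
  if (any(person_years <= 0)) abort("person-time must be positive")
  if (any(deaths < 0)) abort("deaths must be non-negative")
  b <- poisson_exact_bounds(deaths, alpha)
  structure(
    tibble(deaths = as.numeric(deaths),
           person_years = person_years,
           rate_per_1000 = 1000 * deaths / person_years,
           conf.low = 1000 * b$lower / person_years,
           conf.high = 1000 * b$upper / person_years,
           alpha = alpha),
    class = c("opicohort_cmr", class(tibble())))
}

#' @method tidy opicohort_smr
#' @export
tidy.opicohort_smr <- function(x, ...) as_tibble(unclass(x))

#' @method tidy opicohort_cmr
#' @export
tidy.opicohort_cmr <- function(x, ...) as_tibble(unclass(x))

#' @method glance opicohort_smr
#' @export
glance.opicohort_smr <- function(x, ...) {
  tibble(n_strata = nrow(x), total_observed = sum(x$observed),
         total_expected = sum(x$expected),
         pooled_smr = sum(x$observed) / sum(x$expected))
}

#' Mortality table stratified by sex and attained-age band
#'
#' The reporting view of the mortality analysis: one row per sex (including
#' both sexes combined) and attained-age band, plus all-ages rows. Because
#' stratification is by *attained* age (time-updated during follow-up), a
#' cohort restricted to ages 18-64 at entry still accrues person-time and
#' deaths in the 65+ band. Within each row: baseline N (members whose entry
#' age falls in the band; not defined for 65+), follow-up years
#' (days/365.25), observed deaths, expected deaths from `rate_table`, crude
#' rate per 1,000 person-years and SMR, each with exact Poisson intervals.
#' All-ages rows are exact aggregations of the band rows (observed, expected
#' and days each sum).
#'
#' @param members Cohort (after any [truncate_follow_up()]).
#' @param rate_table Reference rates: `sex`, `age`, `year`, `rate`.
#' @param age_breaks Lower bounds of attained-age bands (default
#'   `c(18, 30, 40, 50, 65)`; the last band is open-ended).
#' @param alpha Significance level for the intervals.
#' @return Tibble of class `opicohort_smr_table`.
#' @export
smr_table <- function(members, rate_table,
                      age_breaks = c(18, 30, 40, 50, 65), alpha = 0.05) {
  strata <- expand_person_time(members)
  labs <- c(paste0(utils::head(age_breaks, -1), "-",
                   age_breaks[-1] - 1),
            paste0(utils::tail(age_breaks, 1), "+"))
  band_of <- function(age) {
    cut(age, c(age_breaks, Inf), labels = labs, right = FALSE)
  }
  strata$band <- band_of(strata$age)
  if (anyNA(strata$band)) {
    abort("person-time at ages below the first age band; extend age_breaks")
  }

  one_group <- function(st, mem, sex_label) {
    per_band <- st |>
      group_by(band = as.character(.data$band)) |>
      summarise(days = sum(.data$days),
                observed = sum(.data$observed_deaths),
                .groups = "drop")
    e_by_band <- vapply(
      split(st, as.character(st$band), drop = TRUE),
      function(d) expected_deaths(d[c("sex", "age", "year", "days")],
                                  rate_table),
      numeric(1))
    per_band$expected <- unname(e_by_band[per_band$band])
    n_base <- mem |>
      mutate(band = as.character(band_of(.data$age_at_entry))) |>
      count(.data$band)
    per_band <- per_band |>
      left_join(n_base, by = "band") |>
      mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
    all_ages <- tibble(band = "All ages",
                       days = sum(per_band$days),
                       observed = sum(per_band$observed),
                       expected = sum(per_band$expected),
                       n = nrow(mem))
    out <- bind_rows(
      mutate(per_band,
             .ord = match(.data$band, labs)) |>
        arrange(.data$.ord) |> select(-".ord"),
      all_ages)
    out$n[out$band == paste0(utils::tail(age_breaks, 1), "+")] <- NA_integer_
    mutate(out, sex = sex_label)
  }

  groups <- list(
    one_group(filter(strata, .data$sex == "F"),
              filter(members, .data$sex == "F"), "F"),
    one_group(filter(strata, .data$sex == "M"),
              filter(members, .data$sex == "M"), "M"),
    one_group(strata, members, "Both"))
  groups <- groups[vapply(groups, function(g) sum(g$days) > 0, logical(1))]
  res <- bind_rows(groups)

  cm <- crude_rate(res$observed, person_days = res$days, alpha = alpha)
  sm <- smr(res$observed, pmax(res$expected, .Machine$double.eps),
            alpha = alpha)
  out <- tibble(
    sex = res$sex,
    age_group = as.character(res$band),
    n_baseline = res$n,
    follow_up_years = res$days / 365.25,
    observed = res$observed,
    expected = res$expected,
    cmr = cm$rate_per_1000, cmr_low = cm$conf.low, cmr_high = cm$conf.high,
    smr = sm$smr, smr_low = sm$conf.low, smr_high = sm$conf.high)
  structure(out, class = c("opicohort_smr_table", class(tibble())),
            alpha = alpha)
}

#' @method tidy opicohort_smr_table
#' @export
tidy.opicohort_smr_table <- function(x, ...) as_tibble(unclass(x))

#' @method glance opicohort_smr_table
#' @export
glance.opicohort_smr_table <- function(x, ...) {
  tot <- x[x$sex == "Both" & x$age_group == "All ages", ]
  if (nrow(tot) == 0) tot <- x[x$age_group == "All ages", ][1, ]
  tibble(observed = tot$observed, expected = tot$expected,
         follow_up_years = tot$follow_up_years,
         cmr = tot$cmr, smr = tot$smr,
         smr_low = tot$smr_low, smr_high = tot$smr_high)
}

#' Forest plot of a stratified mortality table
#'
#' @param object An [smr_table()] result.
#' @param ... Ignored.
#' @return A ggplot: SMR point estimates and exact Poisson intervals by
#'   attained-age band and sex, log-scaled, reference line at 1.
#' @method autoplot opicohort_smr_table
#' @export
autoplot.opicohort_smr_table <- function(object, ...) {
  df <- as_tibble(unclass(object)) |>
    mutate(age_group = factor(.data$age_group,
                              levels = rev(unique(.data$age_group))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$smr, y = .data$age_group,
                                   colour = .data$sex)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 3) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$smr_low, xmax = .data$smr_high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Standardised mortality ratio (log scale)",
                  y = "Attained age", colour = "Sex") +
    ggplot2::theme_minimal()
}
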