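#' Configuration for the synthetic EHR generator
#'
#' Bundles every knob of the synthetic primary-care extract. Defaults are
#' calibrated to the published profile of opioid-use cohorts in English
#' primary care: 69% male, age at first recorded use with median about 35
#' years, strong deprivation skew (over 40% in the most deprived IMD
#' quintile), about three-quarters current smokers, all-cause mortality 6.6
#' times the reference population, and 88% hospital-record sensitivity. The
#' generator defines the study conditions for every simulation-based test;
#' it is configured once, not tuned.
#'
#' @param seed Integer master seed. Each output table draws from its own
#'   named substream derived from this seed, so regenerating one table does
#'   not perturb the others.
#' @param n_patients Total patients (positives + background).
#' @param phenotype_prevalence Fraction of patients who are truly
#'   phenotype-positive.
#' @param male_fraction_positive Male share among positives.
#' @param age_median_positive,age_sdlog_positive Log-normal age at first
#'   use: median in years and SD on the log scale (default SD matches an
#'   interquartile range of roughly 29-43 years at median 35).
#' @param entry_age_drift Years added to the age distribution per calendar
#'   year of first use relative to the study midpoint (the population is
#'   ageing).
#' @param imd_weights_positive Probabilities for IMD quintiles 1-5 among
#'   positives (deprivation-skewed).
#' @param smoking_dist_positive Probabilities for CURRENT / EX / NEVER /
#'   no-record among positives.
#' @param flag_probs Named per-flag probabilities (homelessness, prison,
#'   alcohol dependence).
#' @param hazard_ratio Mortality hazard multiplier for positives from first
#'   use onward.
#' @param clinical_index_prob Probability the index record at first use is a
#'   definite clinical code (otherwise it is an OAT prescription).
#' @param oat_rx_prob Probability a positive has OAT prescriptions.
#' @param probable_code_prob Probability a positive also carries a
#'   probable-class code.
#' @param hospital_sensitivity Fraction of hospital opioid-disorder cases
#'   that also hold a primary-care phenotype code.
#' @param n_hospital_cases Number of hospital cases to generate (default:
#'   25% of positives).
#' @param timing_dist Probabilities that a code-holding hospital case's
#'   first primary-care code is before / within 30 days after / later than
#'   the first admission.
#' @param confusable_rx_prob Probability a background patient receives the
#'   planted analgesic (transdermal-patch-like) product.
#' @param confusable_female_fraction,confusable_age_mean,confusable_age_sd
#'   Demographics of the planted analgesic product's recipients.
#' @param background_female_fraction,background_age_mean,background_age_sd
#'   Demographics of background (non-phenotype) patients at data start.
#' @param registration_mean_years Mean registration duration (exponential).
#' @param study_start,study_end Study window.
#' @param rate_base Reference mortality rate for a 40-year-old man (per
#'   person-year).
#' @param rate_age_slope Log-rate increase per year of age.
#' @param rate_female_mult Female/male rate ratio.
#' @param rate_year_trend Log-rate change per calendar year.
#' @return A list of class `opicohort_sim_config`.
#' @export
sim_config <- function(seed = 20260101L,
                       n_patients = 5000,
                       phenotype_prevalence = 0.2,
                       male_fraction_positive = 0.69,
                       age_median_positive = 35,
                       age_sdlog_positive = 0.2825,
                       entry_age_drift = 0.5,
                       imd_weights_positive = c(0.066, 0.110, 0.159,
                                                0.242, 0.423),
                       smoking_dist_positive = c(CURRENT = 0.76, EX = 0.10,
                                                 NEVER = 0.06, NONE = 0.08),
                       flag_probs = c(homelessness = 0.05, prison = 0.07,
                                      alcohol_dependence = 0.18),
                       hazard_ratio = 6.6,
                       clinical_index_prob = 0.85,
                       oat_rx_prob = 0.35,
                       probable_code_prob = 0.15,
                       hospital_sensitivity = 0.88,
                       n_hospital_cases = NULL,
                       timing_dist = c(BEFORE = 0.76, WITHIN = 0.03,
                                       LATER = 0.21),
                       confusable_rx_prob = 0.15,
                       confusable_female_fraction = 0.8,
                       confusable_age_mean = 62,
                       confusable_age_sd = 12,
                       background_female_fraction = 0.55,
                       background_age_mean = 50,
                       background_age_sd = 15,
                       registration_mean_years = 8,
                       study_start = as.Date("1997-01-01"),
                       study_end = as.Date("2018-12-31"),
                       rate_base = 0.002,
                       rate_age_slope = 0.085,
                       rate_female_mult = 0.6,
                       rate_year_trend = -0.01) {
  cfg <- as.list(environment())
  cfg$study_start <- as_date_strict(study_start)
  cfg$study_end <- as_date_strict(study_end)
  stopifnot(phenotype_prevalence >= 0, phenotype_prevalence <= 1,
            male_fraction_positive >= 0, male_fraction_positive <= 1,
            hazard_ratio > 0, hospital_sensitivity >= 0,
            hospital_sensitivity <= 1,
            abs(sum(smoking_dist_positive) - 1) < 1e-8,
            abs(sum(timing_dist) - 1) < 1e-8,
            cfg$study_start < cfg$study_end)
  cfg$imd_weights_positive <- imd_weights_positive /
    sum(imd_weights_positive)
  structure(cfg, class = "opicohort_sim_config")
}

# Deterministic per-table substream seed below 2^31.
substream_seed <- function(seed, name) {
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147483647
  as.integer(((seed %% 65521) * 65537 + h) %% 2147483647)
}

#' Synthetic reference mortality rate table
#'
#' Smooth Gompertz-type rates: exponential in age, sex-differentiated, with
#' a mild calendar trend; every (sex, age, year) cell over ages 15-110 and
#' the study window (plus a margin year) is covered.
#'
#' @param config A [sim_config()].
#' @return Tibble: `sex`, `age`, `year`, `rate`.
#' @export
generate_reference_rates <- function(config) {
  stopifnot(inherits(config, "opicohort_sim_config"))
  grid <- tidyr::expand_grid(
    sex = c("F", "M"),
    age = 15:110,
    year = seq(year(config$study_start), year(config$study_end) + 1L))
  mutate(grid,
         rate = config$rate_base *
           exp(config$rate_age_slope * (.data$age - 40)) *
           ifelse(.data$sex == "F", config$rate_female_mult, 1) *
           exp(config$rate_year_trend * (.data$year - 2008)))
}

#' Synthetic patient registry with ground truth
#'
#' Draws the two subpopulations: phenotype positives (male-dominated,
#' younger, deprivation-skewed, with a true first-use date inside their
#' registration window) and background patients (older, majority female).
#' A small fraction of patients is registered outside England to exercise
#' the region filter. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List: `patients` (registry tibble, `death_date` still `NA` —
#'   deaths are simulated by [generate_events()]) and `truth` (per-patient
#'   `positive` flag, `first_use_date`, `hazard_multiplier`).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "opicohort_sim_config"))
  set.seed(substream_seed(config$seed, "population"))
  n <- config$n_patients
  span_days <- as.integer(config$study_end - config$study_start)

  positive <- stats::runif(n) < config$phenotype_prevalence
  data_start <- config$study_start +
    floor(stats::runif(n) * (span_days - 365))
  dur <- pmax(183, stats::rexp(n, 1 / (config$registration_mean_years *
                                         365.25)))
  data_end <- pmin(data_start + floor(dur), config$study_end)

  sex <- ifelse(positive,
                ifelse(stats::runif(n) < config$male_fraction_positive,
                       "M", "F"),
                ifelse(stats::runif(n) < config$background_female_fraction,
                       "F", "M"))

  first_use <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  window <- as.numeric(data_end - data_start)
  first_use[positive] <- data_start[positive] +
    floor(stats::runif(sum(positive)) * pmax(1, window[positive] * 0.8))

  mid_year <- mean(c(year(config$study_start), year(config$study_end)))
  age <- numeric(n)
  np <- sum(positive)
  age[positive] <- stats::rlnorm(np, log(config$age_median_positive),
                                 config$age_sdlog_positive) +
    config$entry_age_drift * (year(first_use[positive]) - mid_year)
  age[positive] <- pmin(pmax(age[positive], 16), 72)
  age[!positive] <- pmin(pmax(
    stats::rnorm(n - np, config$background_age_mean,
                 config$background_age_sd), 18), 85)
  ref_date <- dplyr::if_else(positive, first_use, data_start)
  year_of_birth <- year(ref_date) - round(age)

  imd <- integer(n)
  imd[positive] <- sample.int(5, np, replace = TRUE,
                              prob = config$imd_weights_positive)
  imd[!positive] <- sample.int(5, n - np, replace = TRUE,
                               prob = c(0.22, 0.21, 0.20, 0.19, 0.18))

  region <- character(n)
  eng <- english_regions()
  eng_w <- c(0.04, 0.05, 0.15, 0.05, 0.21, 0.16, 0.16, 0.14, 0.04)
  non_england <- stats::runif(n) < 0.02
  region[!non_england] <- sample(eng, sum(!non_england), replace = TRUE,
                                 prob = eng_w)
  region[non_england] <- sample(c("Wales", "Scotland"), sum(non_england),
                                replace = TRUE)

  patients <- tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    sex = sex, year_of_birth = as.integer(year_of_birth),
    region = region, imd_quintile = imd,
    data_start = data_start, data_end = data_end,
    death_date = as.Date(rep(NA_integer_, n), origin = "1970-01-01"))
  truth <- tibble(
    patient_id = patients$patient_id,
    positive = positive,
    first_use_date = first_use,
    hazard_multiplier = ifelse(positive, config$hazard_ratio, 1))
  list(patients = patients, truth = truth)
}

# Inverse-CDF draw from the daily Bernoulli death process with
# piecewise-constant daily probability p = annual rate / days-in-year:
# survive segment i with (1 - p_i)^days_i; one uniform per patient locates
# the death segment and the day within it (geometric).
simulate_deaths <- function(ids, sex, start, end, year_of_birth, mult,
                            rates) {
  keep <- end > start
  if (!any(keep)) {
    return(tibble(patient_id = character(),
                  death_date = as.Date(character())))
  }
  seg <- lexis_segments(ids[keep], sex[keep], start[keep], end[keep],
                        year_of_birth[keep]) |>
    left_join(tibble(patient_id = ids[keep], mult = mult[keep]),
              by = "patient_id") |>
    left_join(rates, by = c("sex", "age", "year"))
  if (anyNA(seg$rate)) {
    miss <- seg[is.na(seg$rate), ]
    abort(sprintf("reference rates missing for %d simulated cell(s), e.g. (%s, %d, %d)",
                  nrow(miss), miss$sex[1], miss$age[1], miss$year[1]))
  }
  seg <- seg |>
    mutate(p_day = pmin(.data$mult * .data$rate / days_in_year(.data$year),
                        0.5),
           surv = (1 - .data$p_day)^.data$days) |>
    arrange(.data$patient_id, .data$seg_start) |>
    group_by(.data$patient_id) |>
    mutate(cum = cumprod(.data$surv),
           cum_prev = dplyr::lag(.data$cum, default = 1)) |>
    ungroup()
  u <- tibble(patient_id = ids[keep], u = stats::runif(sum(keep)))
  seg <- left_join(seg, u, by = "patient_id")
  hit <- seg$cum < seg$u & seg$u <= seg$cum_prev
  d <- seg[hit, ]
  if (nrow(d) == 0) {
    return(tibble(patient_id = character(),
                  death_date = as.Date(character())))
  }
  k <- ceiling(log(d$u / d$cum_prev) / log(1 - d$p_day)) - 1
  k <- pmin(pmax(k, 0), d$days - 1)
  tibble(patient_id = d$patient_id, death_date = d$seg_start + k)
}

#' Synthetic clinical events, prescriptions, admissions and deaths
#'
#' Simulates, in named substreams of the config seed:
#'
#' * deaths — a daily Bernoulli process with probability reference rate /
#'   days-in-year, multiplied by the hazard ratio for positives from their
#'   first-use date (background patients are at the reference rate from
#'   data start); truncated at each patient's data end;
#' * phenotype records — every surviving positive receives an index record
#'   dated exactly at first use (definite clinical code with probability
#'   `clinical_index_prob`, otherwise an OAT prescription), plus later
#'   definite codes, OAT prescriptions and probable-class codes;
#' * smoking records and lifetime-history flag codes for positives;
#' * the planted analgesic product — prescribed predominantly to older
#'   female background patients, for the product screen to reject;
#' * hospital admissions with an F11 diagnosis in some position, with the
#'   configured fraction of cases also holding a primary-care code and the
#'   configured timing mix.
#'
#' @param population Output of [generate_population()].
#' @param rates Output of [generate_reference_rates()].
#' @param config A [sim_config()].
#' @return List: `patients` (with `death_date` filled in), `events`,
#'   `prescriptions`, `admissions`.
#' @export
generate_events <- function(population, rates, config) {
  stopifnot(inherits(config, "opicohort_sim_config"))
  patients <- population$patients
  truth <- population$truth
  pos <- truth$positive

  # -- deaths ---------------------------------------------------------------
  set.seed(substream_seed(config$seed, "deaths"))
  start <- dplyr::if_else(pos, truth$first_use_date, patients$data_start)
  deaths <- simulate_deaths(patients$patient_id, patients$sex, start,
                            patients$data_end + 1L, patients$year_of_birth,
                            truth$hazard_multiplier, rates)
  patients <- patients |>
    select(-"death_date") |>
    left_join(deaths, by = "patient_id")
  obs_end <- dplyr::if_else(is.na(patients$death_date), patients$data_end,
                            pmin(patients$data_end, patients$death_date))

  # -- phenotype and covariate records for positives ------------------------
  set.seed(substream_seed(config$seed, "events"))
  p <- which(pos)
  np <- length(p)
  fu <- truth$first_use_date[p]
  pend <- obs_end[p]
  span <- pmax(0, as.numeric(pend - fu))
  rdate <- function(from, width) from + floor(stats::runif(length(from)) *
                                                pmax(1, width))

  idx_clinical <- stats::runif(np) < config$clinical_index_prob
  def_codes <- c("OPI001", "OPI002", "OPI003", "OPI004")
  events <- list()
  rx <- list()

  events$index <- tibble(
    patient_id = patients$patient_id[p][idx_clinical],
    date = fu[idx_clinical],
    code_id = sample(def_codes, sum(idx_clinical), replace = TRUE),
    terminology = "READ")
  rx$index <- tibble(
    patient_id = patients$patient_id[p][!idx_clinical],
    date = fu[!idx_clinical],
    product_code = sample(c("OAT-METH-1MG-ML", "OAT-BUP-8MG-TAB"),
                          sum(!idx_clinical), replace = TRUE))

  n_extra <- stats::rpois(np, 0.8)
  rep_i <- rep.int(seq_len(np), n_extra)
  if (length(rep_i)) {
    events$extra <- tibble(
      patient_id = patients$patient_id[p][rep_i],
      date = rdate(fu[rep_i], span[rep_i]),
      code_id = sample(def_codes, length(rep_i), replace = TRUE),
      terminology = "READ")
  }
  has_oat <- stats::runif(np) < config$oat_rx_prob
  n_scripts <- 1L + stats::rpois(sum(has_oat), 2)
  rep_o <- rep.int(which(has_oat), n_scripts)
  if (length(rep_o)) {
    rx$oat <- tibble(
      patient_id = patients$patient_id[p][rep_o],
      date = rdate(fu[rep_o], span[rep_o]),
      product_code = sample(c("OAT-METH-1MG-ML", "OAT-BUP-8MG-TAB"),
                            length(rep_o), replace = TRUE))
  }
  has_prob <- stats::runif(np) < config$probable_code_prob
  if (any(has_prob)) {
    events$probable <- tibble(
      patient_id = patients$patient_id[p][has_prob],
      date = rdate(fu[has_prob], span[has_prob]),
      code_id = "INJ001", terminology = "READ")
  }

  # smoking: latest record carries the drawn status
  smk_status <- sample(names(config$smoking_dist_positive), np,
                       replace = TRUE, prob = config$smoking_dist_positive)
  has_smk <- smk_status != "NONE"
  smk_code <- c(CURRENT = "SMK-CUR", EX = "SMK-EX",
                NEVER = "SMK-NEV")[smk_status[has_smk]]
  ds <- patients$data_start[p]
  smk_span <- pmax(1, as.numeric(pend - ds))
  last_off <- 1 + floor(stats::runif(np) * (smk_span - 1))
  events$smoking <- tibble(
    patient_id = patients$patient_id[p][has_smk],
    date = ds[has_smk] + last_off[has_smk],
    code_id = unname(smk_code), terminology = "READ")
  earlier <- has_smk & stats::runif(np) < 0.3
  if (any(earlier)) {
    events$smoking_prior <- tibble(
      patient_id = patients$patient_id[p][earlier],
      date = ds[earlier] + floor(stats::runif(sum(earlier)) *
                                   last_off[earlier]),
      code_id = sample(c("SMK-CUR", "SMK-EX", "SMK-NEV"), sum(earlier),
                       replace = TRUE),
      terminology = "READ")
  }

  flag_codes <- c(homelessness = "HML001", prison = "PRS001",
                  alcohol_dependence = "ALC001")
  for (f in names(config$flag_probs)) {
    has_f <- stats::runif(np) < config$flag_probs[[f]]
    if (any(has_f)) {
      events[[f]] <- tibble(
        patient_id = patients$patient_id[p][has_f],
        date = rdate(ds[has_f], smk_span[has_f]),
        code_id = unname(flag_codes[[f]]), terminology = "READ")
    }
  }

  # -- planted analgesic product for background patients --------------------
  set.seed(substream_seed(config$seed, "confusable"))
  bg <- which(!pos)
  if (length(bg) && config$confusable_rx_prob > 0) {
    n_rx <- round(config$confusable_rx_prob * length(bg))
    bg_age <- year(patients$data_start[bg]) - patients$year_of_birth[bg]
    w <- stats::dnorm(bg_age, config$confusable_age_mean,
                      config$confusable_age_sd) + 1e-9
    pick_sex <- function(sx, size) {
      cand <- bg[patients$sex[bg] == sx]
      if (!length(cand) || size == 0) return(integer())
      sample(cand, min(size, length(cand)),
             prob = w[patients$sex[bg] == sx])
    }
    n_f <- round(config$confusable_female_fraction * n_rx)
    sel <- c(pick_sex("F", n_f), pick_sex("M", n_rx - n_f))
    if (length(sel)) {
      bspan <- pmax(1, as.numeric(patients$data_end[sel] -
                                    patients$data_start[sel]))
      rx$confusable <- tibble(
        patient_id = patients$patient_id[sel],
        date = rdate(patients$data_start[sel], bspan),
        product_code = "ANL-BUP-PATCH")
    }
  }

  events <- bind_rows(events)
  prescriptions <- bind_rows(rx)

  # -- hospital admissions --------------------------------------------------
  set.seed(substream_seed(config$seed, "admissions"))
  first_code <- bind_rows(
    events |> filter(.data$code_id %in% def_codes) |>
      select("patient_id", "date"),
    prescriptions |> filter(.data$product_code != "ANL-BUP-PATCH") |>
      select("patient_id", "date")) |>
    group_by(.data$patient_id) |>
    summarise(first_code = min(.data$date), .groups = "drop")

  n_cases <- config$n_hospital_cases %||% round(0.25 * np)
  n_cases <- min(n_cases, nrow(first_code) + length(bg))
  admissions <- tibble(patient_id = character(),
                       admission_date = as.Date(character()),
                       diagnosis_codes = character())
  if (n_cases > 0) {
    n_with <- stats::rbinom(1, n_cases, config$hospital_sensitivity)
    n_with <- min(n_with, nrow(first_code))
    n_without <- min(n_cases - n_with, length(bg))
    coded <- first_code[sample.int(nrow(first_code), n_with), ]
    cls <- sample(names(config$timing_dist), n_with, replace = TRUE,
                  prob = config$timing_dist)
    off <- integer(n_with)
    off[cls == "BEFORE"] <- sample(31:1500, sum(cls == "BEFORE"),
                                   replace = TRUE)
    off[cls == "WITHIN"] <- -sample(0:30, sum(cls == "WITHIN"),
                                    replace = TRUE)
    off[cls == "LATER"] <- -sample(31:1500, sum(cls == "LATER"),
                                   replace = TRUE)
    adm_with <- tibble(
      patient_id = coded$patient_id,
      admission_date = pmin(pmax(coded$first_code + off,
                                 config$study_start), config$study_end))
    uncoded_ids <- patients$patient_id[sample(bg, n_without)]
    bgi <- match(uncoded_ids, patients$patient_id)
    adm_without <- tibble(
      patient_id = uncoded_ids,
      admission_date = rdate(patients$data_start[bgi],
                             pmax(1, as.numeric(patients$data_end[bgi] -
                                                  patients$data_start[bgi]))))
    adm <- bind_rows(adm_with, adm_without)
    f11 <- sample(c("F11.2", "F11.0", "F112"), nrow(adm), replace = TRUE)
    lead <- ifelse(stats::runif(nrow(adm)) < 0.5,
                   paste0(sample(c("J18.9", "K70.3", "S06.0"), nrow(adm),
                                 replace = TRUE), ";"), "")
    admissions <- mutate(adm, diagnosis_codes = paste0(lead, f11))
  }

  list(patients = patients,
       events = arrange(events, .data$patient_id, .data$date),
       prescriptions = arrange(prescriptions, .data$patient_id, .data$date),
       admissions = admissions)
}

#' Generate a complete synthetic EHR extract
#'
#' Convenience wrapper: reference rates, population, and all record tables
#' from one config.
#'
#' @param config A [sim_config()] (or arguments forwarded to it).
#' @param ... Arguments forwarded to [sim_config()] when `config` is not
#'   supplied.
#' @return List: `patients`, `events`, `prescriptions`, `admissions`,
#'   `rates`, `truth`, `codelist`, `config`.
#' @examples
#' sim <- simulate_ehr(sim_config(seed = 1, n_patients = 200))
#' names(sim)
#' @export
simulate_ehr <- function(config = NULL, ...) {
  config <- config %||% sim_config(...)
  rates <- generate_reference_rates(config)
  population <- generate_population(config)
  gen <- generate_events(population, rates, config)
  list(patients = gen$patients, events = gen$events,
       prescriptions = gen$prescriptions, admissions = gen$admissions,
       rates = rates, truth = population$truth,
       codelist = example_codelist(), config = config)
}

#' Write a simulated extract as CSV files
#'
#' Emits the CSV dialects the pipeline consumes (`patients.csv`,
#' `events.csv`, `prescriptions.csv`, `admissions.csv`, `rates.csv`,
#' `ground_truth.csv`, `codelist.csv`).
#'
#' @param sim Output of [simulate_ehr()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$patients, file.path(dir, "patients.csv"),
                   progress = FALSE)
  readr::write_csv(sim$events, file.path(dir, "events.csv"),
                   progress = FALSE)
  readr::write_csv(sim$prescriptions, file.path(dir, "prescriptions.csv"),
                   progress = FALSE)
  readr::write_csv(sim$admissions, file.path(dir, "admissions.csv"),
                   progress = FALSE)
  readr::write_csv(sim$rates, file.path(dir, "rates.csv"), progress = FALSE)
  readr::write_csv(sim$truth, file.path(dir, "ground_truth.csv"),
                   progress = FALSE)
  write_codelist(sim$codelist, file.path(dir, "codelist.csv"))
  invisible(dir)
}
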