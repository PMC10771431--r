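## Synthetic national-register generator.
##
## Emulates the statistical structure of an inpatient injury register:
## age/sex-specific hip fracture incidence with a calendar-time decline,
## hospital transfers dated at most one day after discharge, later
## readmissions re-coded with the fracture ICD code, second fractures,
## death as a competing event, and a pre-study lookback window of
## non-fracture injury admissions. Every generated admission carries a
## ground-truth label (incident / transfer / readmission) so downstream
## classification can be scored.

#' Hip fracture ICD-10 case-definition codes
#' @return character vector c("S720", "S721", "S722")
#' @export
hip_fracture_codes <- function() c("S720", "S721", "S722")

default_base_population <- function() {
  bands <- hip_age_bands()
  data.table(
    sex = rep(c("F", "M"), each = length(bands)),
    age_band = rep(bands, 2L),
    count = c(
      800000, 220000, 190000, 160000, 120000, 75000, 30000, 7000,
      820000, 210000, 170000, 130000, 80000, 40000, 12000, 2000
    )
  )
}

default_base_rates <- function() {
  bands <- hip_age_bands()
  data.table(
    sex = rep(c("F", "M"), each = length(bands)),
    age_band = rep(bands, 2L),
    rate = c(
      0.0006, 0.0025, 0.0050, 0.0100, 0.0190, 0.0320, 0.0450, 0.0550,
      0.0005, 0.0017, 0.0033, 0.0065, 0.0130, 0.0240, 0.0370, 0.0500
    )
  )
}

## annual proportional population growth per stratum, observed period
default_pop_growth <- function() {
  bands <- hip_age_bands()
  old <- bands %in% c("75-79", "80-84", "85-89", "90-94", "95+")
  data.table(
    sex = rep(c("F", "M"), each = length(bands)),
    age_band = rep(bands, 2L),
    growth = c(
      ifelse(old, 0.006, 0.003),   # women 75+: ~13% over 21 years
      ifelse(old, 0.0165, 0.003)   # men 75+: ~41% over 21 years
    )
  )
}

## annual growth for the projected-population table (post-study horizon)
default_proj_growth <- function() {
  bands <- hip_age_bands()
  old <- bands %in% c("75-79", "80-84", "85-89", "90-94", "95+")
  data.table(
    sex = rep(c("F", "M"), each = length(bands)),
    age_band = rep(bands, 2L),
    growth = c(
      ifelse(old, 0.010, 0.002),
      ifelse(old, 0.015, 0.002)
    )
  )
}

## per-year post-fracture death hazard by sex and age band
default_death_hazard <- function() {
  bands <- hip_age_bands()
  f <- c(0.05, 0.08, 0.11, 0.15, 0.20, 0.28, 0.38, 0.50)
  data.table(
    sex = rep(c("F", "M"), each = length(bands)),
    age_band = rep(bands, 2L),
    hazard = c(f, 1.3 * f)
  )
}

#' Configuration for the synthetic register cohort
#'
#' Bundles every tunable of the generator with validation. The defaults
#' describe a register in which the age-standardized fracture rate
#' declines by about 1.64% per year, the 75+ population grows faster in
#' men than in women, roughly 80% of fracture patients die within ten
#' years of the index event while about 11% sustain a second fracture,
#' and transfers plus fracture-coded readmissions inflate a naive
#' admission count by roughly 56% (women) to 72% (men).
#'
#' @param seed integer seed; identical seed + config gives byte-identical
#'   output tables
#' @param start_year,end_year first and last calendar year of the study
#'   window (start_year < end_year)
#' @param lookback_years length of the pre-study injury history window
#' @param horizon_year last year of the projected-population table
#' @param scale multiplier applied to the base population counts (1 =
#'   country scale; the default 0.1 keeps desk-scale runs fast)
#' @param base_rates data.table (sex, age_band, rate): incident first
#'   fractures per person-year in start_year
#' @param annual_rate_change proportional change in fracture rates per
#'   calendar year (negative = decline)
#' @param base_population data.table (sex, age_band, count) in start_year
#' @param pop_growth,proj_growth data.tables (sex, age_band, growth):
#'   annual proportional population growth over the study period and the
#'   projection horizon
#' @param transfer_prob probability that an incident episode generates at
#'   least one onward transfer dated 0-1 days after discharge; scalar or
#'   named vector c(F = , M = )
#' @param transfer_continue_prob probability each transfer is followed by
#'   a further chained transfer
#' @param readmission_prob probability of a later fracture-coded
#'   readmission per incident episode; scalar or named c(F = , M = )
#' @param readmission_main_dx_prob probability the readmission carries the
#'   fracture code as main diagnosis (otherwise a complication code is
#'   main and the fracture code secondary)
#' @param readmission_gap_days c(min, mode, max) of the triangular
#'   distribution of days from episode end to readmission
#' @param second_fracture_hazard per-year hazard of a new true fracture
#'   after the first
#' @param death_hazard data.table (sex, age_band, hazard): per-year death
#'   hazard after a fracture
#' @param rehab_frac probability a readmission is coded to a
#'   rehabilitation department
#' @param acute_prob_incident,acute_prob_readmission probability the
#'   admission is coded acute (vs elective) for incident fractures and
#'   readmissions respectively
#' @param lookback_injury_prob probability a fracture patient has a prior
#'   non-fracture injury admission (in the lookback window or earlier in
#'   the study period)
#' @param surgery_missing list(F = c(start, end), M = c(start, end)):
#'   proportion of incident episodes without a hip surgery procedure
#'   code in start_year and end_year (geometric interpolation between)
#' @return a validated list of class "cohort_config"
#' @export
cohort_config <- function(seed = 1L,
                          start_year = 1998L,
                          end_year = 2019L,
                          lookback_years = 11L,
                          horizon_year = 2050L,
                          scale = 0.1,
                          base_rates = default_base_rates(),
                          annual_rate_change = -0.0164,
                          base_population = default_base_population(),
                          pop_growth = default_pop_growth(),
                          proj_growth = default_proj_growth(),
                          transfer_prob = c(F = 0.18, M = 0.24),
                          transfer_continue_prob = 0.62,
                          readmission_prob = c(F = 0.20, M = 0.24),
                          readmission_main_dx_prob = 0.5,
                          readmission_gap_days = c(min = 10, mode = 60, max = 540),
                          second_fracture_hazard = 0.030,
                          death_hazard = default_death_hazard(),
                          rehab_frac = 0.3,
                          acute_prob_incident = 0.98,
                          acute_prob_readmission = 0.05,
                          lookback_injury_prob = 0.35,
                          surgery_missing = list(
                            F = c(0.142, 0.053),
                            M = c(0.156, 0.069)
                          )) {
  cfg <- list(
    seed = as.integer(seed), start_year = as.integer(start_year),
    end_year = as.integer(end_year), lookback_years = as.integer(lookback_years),
    horizon_year = as.integer(horizon_year), scale = scale,
    base_rates = as.data.table(base_rates),
    annual_rate_change = annual_rate_change,
    base_population = as.data.table(base_population),
    pop_growth = as.data.table(pop_growth),
    proj_growth = as.data.table(proj_growth),
    transfer_prob = sex_prob(transfer_prob),
    transfer_continue_prob = transfer_continue_prob,
    readmission_prob = sex_prob(readmission_prob),
    readmission_main_dx_prob = readmission_main_dx_prob,
    readmission_gap_days = readmission_gap_days,
    second_fracture_hazard = second_fracture_hazard,
    death_hazard = as.data.table(death_hazard),
    rehab_frac = rehab_frac,
    acute_prob_incident = acute_prob_incident,
    acute_prob_readmission = acute_prob_readmission,
    lookback_injury_prob = lookback_injury_prob,
    surgery_missing = surgery_missing
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

sex_prob <- function(p) {
  if (length(p) == 1L && is.null(names(p))) p <- c(F = unname(p), M = unname(p))
  stopifnot(all(c("F", "M") %in% names(p)))
  p[c("F", "M")]
}

validate_cohort_config <- function(cfg) {
  if (cfg$start_year >= cfg$end_year) {
    stop("invalid year range: start_year must be before end_year", call. = FALSE)
  }
  probs <- c(
    cfg$transfer_prob, cfg$transfer_continue_prob, cfg$readmission_prob,
    cfg$readmission_main_dx_prob, cfg$rehab_frac, cfg$acute_prob_incident,
    cfg$acute_prob_readmission, cfg$lookback_injury_prob,
    unlist(cfg$surgery_missing)
  )
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]", call. = FALSE)
  if (any(cfg$base_rates$rate < 0) || cfg$second_fracture_hazard < 0 ||
    any(cfg$death_hazard$hazard < 0)) {
    stop("all rates and hazards must be nonnegative", call. = FALSE)
  }
  if (any(cfg$base_population$count <= 0)) stop("population counts must be positive", call. = FALSE)
  invisible(cfg)
}

#' Generate population and projected-population tables
#'
#' Builds one row per (year, sex, age_band): the observed table covers
#' `start_year..end_year`, the projected table `end_year+1..horizon_year`,
#' with stratum counts growing geometrically at the configured per-band
#' annual growth.
#'
#' @param config a [cohort_config()]
#' @return list with data.tables `observed` and `projected`, columns
#'   (year, sex, age_band, count)
#' @export
generate_population <- function(config) {
  validate_cohort_config(config)
  grow <- function(base, growth, years, from_year) {
    g <- merge(base, growth, by = c("sex", "age_band"))
    out <- g[CJ(year = years, sex = unique(g$sex), age_band = unique(g$age_band)),
      on = c("sex", "age_band"), allow.cartesian = TRUE
    ]
    out[, count := as.integer(pmax(1, round(count * (1 + growth)^(year - from_year))))]
    out[order(year, sex, age_band), .(year, sex, age_band, count)]
  }
  base <- copy(config$base_population)[, count := pmax(1, round(count * config$scale))]
  observed <- grow(base, config$pop_growth, config$start_year:config$end_year, config$start_year)
  end_counts <- observed[year == config$end_year, .(sex, age_band, count)]
  projected <- grow(
    end_counts, config$proj_growth,
    (config$end_year + 1L):config$horizon_year, config$end_year
  )
  list(observed = observed, projected = projected)
}

## proportion of incident episodes without a surgery code in a given year
## (geometric interpolation between the start- and end-year values)
surgery_missing_prop <- function(config, sex, year) {
  span <- config$end_year - config$start_year
  vapply(seq_along(sex), function(i) {
    se <- config$surgery_missing[[sex[i]]]
    se[1] * (se[2] / se[1])^((year[i] - config$start_year) / span)
  }, numeric(1))
}

#' Generate a synthetic admissions register with ground-truth labels
#'
#' Simulates incident hip fractures stratum by stratum from the population
#' table, then injects the register artifacts the counting methods must
#' disentangle: chained transfers dated 0-1 days after discharge,
#' fracture-coded readmissions weeks to months later, second (and later)
#' true fractures, death truncating each person's history, and pre-study
#' lookback injury admissions.
#'
#' @param config a [cohort_config()]
#' @param population the `observed` table from [generate_population()]
#' @return list of data.tables:
#'   * `admissions`: study-period admissions (admission_id, pin,
#'     admit_date, discharge_date, main_dx, secondary_dx, dept_rehab,
#'     admission_acute, procedure_codes, sex, birth_year)
#'   * `lookback`: pre-study injury admissions, same schema
#'   * `truth`: (admission_id, true_class) for every generated admission
#'   * `deaths`: (pin, death_date) for every fracture patient
#' @export
generate_admissions <- function(config, population) {
  validate_cohort_config(config)
  population <- as.data.table(population)
  if (nrow(population) == 0L) stop("empty population table", call. = FALSE)
  set.seed(config$seed)

  ## --- incident first fractures per stratum-year -----------------------
  ## The simulation starts at the beginning of the lookback window so the
  ## study years see a steady-state pool of earlier fracture patients
  ## (refractures, transfers and readmissions crossing into the window).
  ## Pre-study stratum counts and rates are geometric back-extrapolations
  ## of the configured start-year values.
  pre_years <- (config$start_year - config$lookback_years):(config$start_year - 1L)
  pre <- merge(
    copy(config$base_population)[, count := pmax(1, round(count * config$scale))],
    config$pop_growth,
    by = c("sex", "age_band")
  )
  pre <- pre[CJ(year = pre_years, sex = unique(pre$sex), age_band = unique(pre$age_band)),
    on = c("sex", "age_band"), allow.cartesian = TRUE
  ]
  pre[, count := as.integer(pmax(1, round(count * (1 + growth)^(year - config$start_year))))]
  pre[, growth := NULL]
  full_pop <- rbindlist(list(pre[, .(year, sex, age_band, count)], population), use.names = TRUE)
  strata <- merge(full_pop, config$base_rates, by = c("sex", "age_band"))
  setorder(strata, year, sex, age_band)
  strata[, rate_y := pmin(1, rate * (1 + config$annual_rate_change)^(year - config$start_year))]
  strata[, n_inc := rbinom(.N, count, rate_y)]

  first <- strata[rep(seq_len(.N), n_inc), .(year, sex, age_band)]
  n1 <- nrow(first)
  if (n1 == 0L) stop("configuration produced no incident fractures", call. = FALSE)
  first[, pin := sprintf("P%07d", seq_len(.N))]
  ## age uniform within band (51+ in the opening band: study is age > 50)
  lo <- c("50-64" = 51, "65-69" = 65, "70-74" = 70, "75-79" = 75,
          "80-84" = 80, "85-89" = 85, "90-94" = 90, "95+" = 95)
  hi <- c("50-64" = 64, "65-69" = 69, "70-74" = 74, "75-79" = 79,
          "80-84" = 84, "85-89" = 89, "90-94" = 94, "95+" = 104)
  b <- as.character(first$age_band)
  first[, age := lo[b] + floor(runif(.N) * (hi[b] - lo[b] + 1))]
  first[, admit_date := year_start_day(year) + floor(runif(.N) * days_in_year(year))]

  ## death: competing exponential clock started at the first fracture
  dh <- config$death_hazard
  haz <- dh[first, on = c("sex", "age_band"), hazard]
  death_years <- rexp(n1, pmax(haz, 1e-12))
  first[, death_date := admit_date + as.integer(round(death_years * 365.25))]

  ## --- waves of true fractures (first, second, ...) --------------------
  events <- first[, .(pin, sex, age, year, admit_date, death_date, wave = 1L)]
  all_events <- list(events)
  w <- 1L
  while (nrow(events) > 0L && w < 6L) {
    t2 <- rexp(nrow(events), pmax(config$second_fracture_hazard, 1e-12))
    d2 <- events$admit_date + as.integer(round(t2 * 365.25))
    ok <- d2 < events$death_date & year_of_day(d2) <= config$end_year &
      config$second_fracture_hazard > 0
    events <- events[ok]
    if (nrow(events) == 0L) break
    d2ok <- d2[ok]
    elapsed <- as.integer((d2ok - events$admit_date) %/% 365.25)
    events[, `:=`(
      admit_date = d2ok,
      age = age + elapsed,
      year = year_of_day(d2ok),
      wave = wave + 1L
    )]
    w <- w + 1L
    all_events[[length(all_events) + 1L]] <- copy(events)
  }
  ev <- rbindlist(all_events)
  setorder(ev, pin, admit_date)
  ev[, event_id := seq_len(.N)]

  ## --- index admissions ------------------------------------------------
  frac_codes <- paste0(
    sample(hip_fracture_codes(), nrow(ev), replace = TRUE, prob = c(0.55, 0.35, 0.10)),
    sample(0:1, nrow(ev), replace = TRUE)
  )
  ev[, main_dx := frac_codes]
  ev[, los := 4L + as.integer(floor(runif(.N) * 9))]  # 4-12 days acute stay
  idx <- ev[, .(
    event_id, pin, sex, age, year, admit_date,
    discharge_date = admit_date + los, main_dx, death_date,
    dept_rehab = 0L,
    admission_acute = as.integer(runif(.N) < config$acute_prob_incident),
    true_class = "incident"
  )]
  ## surgery codes on incident admissions, missingness declining over time
  p_miss <- surgery_missing_prop(config, idx$sex, idx$year)
  has_surg <- runif(nrow(idx)) >= p_miss
  surg_pool <- c("NFB09", "NFB19", "NFB29", "NFB39", "NFB99",
                 "NFJ09", "NFJ29", "NFJ59", "NFJ89", "TNX40")
  idx[, procedure_codes := ifelse(has_surg, sample(surg_pool, .N, replace = TRUE), "")]

  ## --- transfers (0-1 day gaps, possibly chained) ----------------------
  tp <- config$transfer_prob[idx$sex]
  active <- idx[runif(nrow(idx)) < tp]
  transfers <- list()
  hop <- 0L
  while (nrow(active) > 0L && hop < 6L) {
    hop <- hop + 1L
    tr <- active[, .(
      event_id, pin, sex, age, year, main_dx, death_date,
      admit_date = discharge_date + sample(0:1, .N, replace = TRUE)
    )]
    tr[, discharge_date := admit_date + 7L + as.integer(floor(runif(.N) * 24))]
    tr[, `:=`(
      dept_rehab = as.integer(runif(.N) < 0.6),
      admission_acute = 0L,
      procedure_codes = "",
      true_class = "transfer"
    )]
    transfers[[hop]] <- tr
    active <- tr[runif(nrow(tr)) < config$transfer_continue_prob]
  }
  transfers <- if (length(transfers)) rbindlist(transfers, use.names = TRUE) else idx[0]

  ## chain end per event (for the readmission gap origin)
  chain_end <- idx[, .(event_id, end = discharge_date)]
  if (nrow(transfers) > 0L) {
    te <- transfers[, .(end = max(discharge_date)), by = event_id]
    chain_end[te, on = "event_id", end := pmax(end, i.end)]
  }

  ## --- readmissions re-coded with the fracture code --------------------
  rp <- config$readmission_prob[idx$sex]
  rd <- idx[runif(nrow(idx)) < rp]
  rd <- chain_end[rd, on = "event_id"]
  g <- config$readmission_gap_days
  comp_pool <- c("T840", "T845", "T933")
  if (nrow(rd) > 0L) {
    rd[, admit_date := end + as.integer(round(rtriangular(.N, g["min"], g["mode"], g["max"])))]
    rd[, discharge_date := admit_date + 3L + as.integer(floor(runif(.N) * 18))]
    main_is_frac <- runif(nrow(rd)) < config$readmission_main_dx_prob
    frac <- rd$main_dx
    rd[, main_dx := ifelse(main_is_frac, frac, sample(comp_pool, .N, replace = TRUE))]
    rd[, secondary_dx := ifelse(main_is_frac, "", frac)]
    rd[, `:=`(
      year = year_of_day(admit_date),
      dept_rehab = as.integer(runif(.N) < config$rehab_frac),
      admission_acute = as.integer(runif(.N) < config$acute_prob_readmission),
      procedure_codes = ifelse(runif(.N) < 0.2, "NFC29", ""),
      true_class = "readmission"
    )]
    rd <- rd[, .(event_id, pin, sex, age, year, admit_date, discharge_date,
                 main_dx, secondary_dx, death_date, dept_rehab,
                 admission_acute, procedure_codes, true_class)]
  }

  ## --- prior (non-fracture) injury admissions --------------------------
  persons <- ev[wave == 1L, .(pin, sex, age, admit_date, death_date)]
  lb <- persons[runif(nrow(persons)) < config$lookback_injury_prob]
  if (nrow(lb) > 0L) {
    window_start <- year_start_day(config$start_year - config$lookback_years)
    lb[, index_date := admit_date]
    lb[, admit_date := pmax(window_start, index_date - as.integer(round(runif(.N, 400, 4000))))]
    lb[, discharge_date := admit_date + 2L + as.integer(floor(runif(.N) * 9))]
    injury_pool <- c("S4200", "S5250", "S8250", "S0600", "S3200")
    lb[, `:=`(
      year = year_of_day(admit_date),
      main_dx = sample(injury_pool, .N, replace = TRUE),
      secondary_dx = "",
      dept_rehab = 0L, admission_acute = 1L, procedure_codes = "",
      true_class = "incident",
      age = pmax(35L, age - as.integer((index_date - admit_date) %/% 365L))
    )]
  }

  ## --- assemble, truncate at death and register end --------------------
  idx[, secondary_dx := ""]
  cols <- c("pin", "sex", "age", "year", "admit_date", "discharge_date",
            "main_dx", "secondary_dx", "dept_rehab", "admission_acute",
            "procedure_codes", "death_date", "true_class")
  adm <- rbindlist(list(
    idx[, .SD, .SDcols = cols],
    if (nrow(transfers) > 0L) copy(transfers)[, secondary_dx := ""][, .SD, .SDcols = cols] else NULL,
    if (nrow(rd) > 0L) rd[, .SD, .SDcols = cols] else NULL
  ), use.names = TRUE)
  adm <- adm[admit_date <= death_date & year_of_day(admit_date) <= config$end_year]
  adm[, discharge_date := pmin(discharge_date, death_date)]
  adm[, year := year_of_day(admit_date)]

  if (nrow(lb) > 0L) {
    adm <- rbindlist(list(adm, lb[, .SD, .SDcols = cols]), use.names = TRUE)
  }

  ## comorbidity secondary diagnoses (0-2 per admission)
  comorb_pool <- c("I109", "E119", "N390", "F039", "J449")
  k <- sample(0:2, nrow(adm), replace = TRUE, prob = c(0.5, 0.35, 0.15))
  extra <- vapply(k, function(n) paste(sample(comorb_pool, n), collapse = ";"), character(1))
  adm[, secondary_dx := ifelse(secondary_dx == "", extra,
    ifelse(extra == "", secondary_dx, paste(secondary_dx, extra, sep = ";"))
  )]

  setorder(adm, pin, admit_date, discharge_date, main_dx)
  adm[, admission_id := sprintf("A%08d", seq_len(.N))]
  adm[, birth_year := year - age]

  schema <- c("admission_id", "pin", "admit_date", "discharge_date", "main_dx",
              "secondary_dx", "dept_rehab", "admission_acute",
              "procedure_codes", "sex", "birth_year")
  in_study <- adm$admit_date >= year_start_day(config$start_year)
  truth <- adm[, .(admission_id, true_class)]
  deaths <- persons[, .(pin, death_date)]

  list(
    admissions = adm[in_study, .SD, .SDcols = schema],
    lookback = adm[!in_study, .SD, .SDcols = schema],
    truth = truth,
    deaths = deaths
  )
}

#' Write the synthetic register tables as CSV files
#'
#' @param register list from [generate_admissions()]
#' @param population list from [generate_population()]
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
write_register <- function(register, population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    admissions = "admissions.csv", lookback = "lookback.csv",
    truth = "truth.csv", deaths = "deaths.csv"
  )
  for (nm in names(files)) {
    fwrite(register[[nm]], file.path(dir, files[[nm]]))
  }
  fwrite(population$observed, file.path(dir, "population.csv"))
  fwrite(population$projected, file.path(dir, "projected_population.csv"))
  invisible(file.path(dir, c(files, "population.csv", "projected_population.csv")))
}
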