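## Scenario projections of annual fracture counts.
##
## Three scenarios: (1) the observed average annual percent change in
## rates continues through the horizon; (2) rates frozen at the base
## year; (3) the decline continues through a breakpoint year and rates
## are constant thereafter. Scenario rates are applied to projected
## population counts stratum by stratum.

#' Average annual percent change of stratum rates
#'
#' AAPC is `exp(slope) - 1` from an ordinary least-squares fit of
#' log(rate) on calendar year, per (sex, age_band) stratum — exact for a
#' geometric rate series. Strata with any zero-rate year fall back to the
#' pooled-sex estimate for that age band (events and denominators summed
#' over sex); if the pooled stratum is also degenerate the AAPC is 0.
#'
#' @param counts stratified counts from [tabulate_cases()] with at least
#'   3 observed years per stratum
#' @return data.table (sex, age_band, aapc, pooled) where `pooled` flags
#'   fallback strata
#' @export
estimate_aapc <- function(counts) {
  counts <- as.data.table(counts)
  if (length(unique(counts$year)) < 3L) {
    stop("need at least 3 observed years to estimate an AAPC", call. = FALSE)
  }
  aapc_of <- function(year, rate) {
    if (any(rate <= 0)) {
      return(NA_real_)
    }
    exp(unname(coef(lm(log(rate) ~ year))[2L])) - 1
  }
  own <- counts[, .(aapc = aapc_of(year, rate)), by = .(sex, age_band)]
  pooled_counts <- counts[, .(
    rate = sum(events) / sum(person_denominator)
  ), by = .(year, age_band)]
  pool <- pooled_counts[, .(pooled_aapc = aapc_of(year, rate)), by = age_band]
  out <- own[pool, on = "age_band"]
  out[, pooled := is.na(aapc)]
  n_fallback <- sum(out$pooled)
  out[pooled == TRUE, aapc := pooled_aapc]
  if (any(is.na(out$aapc))) {
    message("AAPC undefined even after pooling for some strata; set to 0")
    out[is.na(aapc), aapc := 0]
  }
  if (n_fallback > 0L) {
    message(sprintf("%d stratum/strata fell back to the pooled-sex AAPC", n_fallback))
  }
  out[, pooled_aapc := NULL]
  strip_key(out)
  setorder(out, sex, age_band)
  out[]
}

#' Project annual fracture counts under a scenario
#'
#' The stratum rate in year y is
#' `rate(base_year) * (1 + aapc)^(min(y, stop_year) - base_year)` where
#' stop_year is the horizon (scenario "continued_decline"), the base year
#' (scenario "constant_rates") or the breakpoint year (scenario
#' "decline_then_constant"). Projected counts are the rates applied to
#' the projected population.
#'
#' @param counts observed stratified counts (supplies base-year rates)
#' @param projected_pop projected population table covering
#'   base_year+1..horizon_year for every stratum with a nonzero rate
#' @param scenario one of "continued_decline", "constant_rates",
#'   "decline_then_constant"
#' @param horizon_year last projected year
#' @param aapc data.table (sex, age_band, aapc), normally from
#'   [estimate_aapc()]; ignored by the constant-rates scenario
#' @param base_year last observed year (default: max year in `counts`)
#' @param breakpoint_year year the decline stops under
#'   "decline_then_constant" (default 2029)
#' @return data.table (year, sex, scenario, projected_count) with per-sex
#'   rows plus sex = "All" totals
#' @export
project_counts <- function(counts, projected_pop, scenario, horizon_year,
                           aapc = NULL, base_year = NULL,
                           breakpoint_year = 2029L) {
  scenario <- match.arg(scenario, c(
    "continued_decline", "constant_rates", "decline_then_constant"
  ))
  counts <- as.data.table(counts)
  pop <- as.data.table(projected_pop)
  if (is.null(base_year)) base_year <- max(counts$year)
  if (scenario == "decline_then_constant" && breakpoint_year <= base_year) {
    stop("breakpoint_year must be after base_year", call. = FALSE)
  }
  base <- counts[year == base_year, .(sex, age_band = as.character(age_band), base_rate = rate)]
  if (nrow(base) == 0L) stop("base year absent from counts", call. = FALSE)

  years <- (base_year + 1L):horizon_year
  grid <- pop[year %in% years]
  miss <- base[!grid[, .(sex, age_band = as.character(age_band))], on = c("sex", "age_band")]
  if (nrow(grid) == 0L || nrow(miss) > 0L) {
    nm <- if (nrow(grid) == 0L) "all years" else paste(miss$sex[1L], miss$age_band[1L])
    stop(sprintf("projected population missing stratum: %s", nm), call. = FALSE)
  }
  grid <- grid[base, on = c("sex", "age_band"), nomatch = NULL]
  if (scenario == "constant_rates") {
    grid[, y_rel := 0]
  } else {
    if (is.null(aapc)) stop("scenario requires an aapc table", call. = FALSE)
    stop_year <- if (scenario == "continued_decline") horizon_year else breakpoint_year
    grid <- grid[as.data.table(aapc)[, .(sex, age_band = as.character(age_band), aapc)],
      on = c("sex", "age_band"), nomatch = NULL
    ]
    grid[, y_rel := pmin(year, stop_year) - base_year]
  }
  if (scenario == "constant_rates") grid[, aapc := 0]
  grid[, proj_count := base_rate * (1 + aapc)^y_rel * count]
  by_sex <- grid[, .(projected_count = sum(proj_count)), by = .(year, sex)]
  all <- by_sex[, .(sex = "All", projected_count = sum(projected_count)), by = year]
  out <- rbindlist(list(by_sex, all), use.names = TRUE)
  out[, scenario := scenario]
  strip_key(out)
  setorder(out, sex, year)
  out[, .(year, sex, scenario, projected_count)]
}
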