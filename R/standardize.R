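## Stratified counts, direct age-standardization and bootstrap CIs.

#' Tabulate cases into year x sex x age-band strata
#'
#' @param cases a case table (from any counting method)
#' @param population population table (year, sex, age_band, count)
#' @param age_bands ordered band labels (default [hip_age_bands()])
#' @return data.table (year, sex, age_band, events, person_denominator,
#'   rate), one row per populated stratum of the population table
#' @export
tabulate_cases <- function(cases, population, age_bands = hip_age_bands()) {
  cases <- as.data.table(cases)
  pop <- as.data.table(population)
  cs <- copy(cases)
  strip_key(cs)
  cs[, age_band := as.character(age_band_of(age))]
  miss <- cs[!pop, on = c("year", "sex", "age_band")]
  if (nrow(miss) > 0L) {
    m <- miss[1L]
    stop(sprintf(
      "case stratum missing from population table: year %s, sex %s, band %s",
      m$year, m$sex, m$age_band
    ), call. = FALSE)
  }
  ev <- cs[, .(events = .N), by = .(year, sex, age_band)]
  out <- ev[pop, on = c("year", "sex", "age_band")]
  out[is.na(events), events := 0L]
  if (any(out$count <= 0)) stop("nonpositive person denominator", call. = FALSE)
  strip_key(out)
  setnames(out, "count", "person_denominator")
  out[, rate := events / person_denominator]
  out[, age_band := factor(age_band, levels = age_bands)]
  setorder(out, year, sex, age_band)
  out[, .(year, sex, age_band, events, person_denominator, rate)]
}

#' Direct age-standardization of annual counts
#'
#' For each (year, sex), the standardized count is the sum over age bands
#' of the observed stratum rate times the reference population count of
#' that band in the reference year. With the reference equal to a year's
#' own population, the standardized count equals the observed count.
#'
#' @param counts stratified counts from [tabulate_cases()]
#' @param reference population table providing the reference year
#' @param reference_year year whose population structure is the standard
#' @param base_year optional base for the percent-change series (default:
#'   earliest year in `counts`)
#' @return data.table (year, sex, std_count, pct_change_vs_base) with
#'   per-sex rows plus sex = "All" totals
#' @export
standardize_counts <- function(counts, reference, reference_year,
                               base_year = NULL) {
  counts <- as.data.table(counts)
  ref <- as.data.table(reference)[year == reference_year]
  if (nrow(ref) == 0L) stop("reference year absent from reference table", call. = FALSE)
  if (is.null(base_year)) base_year <- min(counts$year)
  x <- copy(counts)[, age_band := as.character(age_band)]
  x <- x[ref[, .(sex, age_band, pop_ref = count)], on = c("sex", "age_band"), nomatch = NULL]
  by_sex <- x[, .(std_count = sum(rate * pop_ref)), by = .(year, sex)]
  all <- by_sex[, .(sex = "All", std_count = sum(std_count)), by = year]
  out <- rbindlist(list(by_sex, all), use.names = TRUE)
  base <- out[year == base_year, .(sex, base = std_count)]
  out <- out[base, on = "sex"]
  ## a sex with no base-year events has no defined relative change
  out[, pct_change_vs_base := fifelse(base > 0, 100 * (std_count - base) / base, NA_real_)]
  out[, base := NULL]
  strip_key(out)
  setorder(out, sex, year)
  out[]
}

#' Bootstrap percentile CI for the standardized percent change
#'
#' Resamples persons (each person's full case history moves as a unit)
#' with replacement, recomputes the standardized percent change between
#' the base and final observed year per replicate, and returns percentile
#' intervals. The population denominators are fixed.
#'
#' @param cases case table
#' @param population population table
#' @param reference_year standardization reference year
#' @param base_year baseline year of the change
#' @param target_year comparison year (default: reference_year)
#' @param reps bootstrap replications (default 1000)
#' @param seed integer seed
#' @param conf confidence level (default 0.95, percentile method)
#' @return data.table (sex, pct_change, ci_low, ci_high, n_dropped);
#'   `n_dropped` counts degenerate replicates (zero base-year count)
#' @export
bootstrap_change <- function(cases, population, reference_year, base_year,
                             target_year = reference_year, reps = 1000L,
                             seed = 1L, conf = 0.95) {
  stopifnot(reps >= 2L)
  cases <- as.data.table(cases)
  pop <- as.data.table(population)

  ## point estimate through the ordinary tabulation/standardization path
  counts <- tabulate_cases(cases, pop)
  std <- standardize_counts(counts, pop, reference_year, base_year = base_year)
  b0 <- std[year == base_year, setNames(std_count, sex)]
  t0 <- std[year == target_year, setNames(std_count, sex)]
  sexes <- names(b0)
  if (any(b0 == 0)) stop("zero base-year count in the observed data", call. = FALSE)
  point <- setNames(percent_change(b0[sexes], t0[sexes]), sexes)

  ## person x stratum incidence matrix: resampling persons with
  ## replacement is then a weighted column sum per replicate
  cs <- copy(cases)
  strip_key(cs)
  cs <- cs[year %in% c(base_year, target_year)]
  cs[, age_band := as.character(age_band_of(age))]
  cs[, stratum := paste(year, sex, age_band, sep = "|")]
  pins <- sort(unique(cases$pin)) # all persons, incl. those without
  strata <- sort(unique(cs$stratum)) # cases in the two compared years
  M <- Matrix::sparseMatrix(
    i = match(cs$pin, pins), j = match(cs$stratum, strata),
    x = 1, dims = c(length(pins), length(strata))
  )
  ## standardization weight of each stratum: reference count / denominator
  meta <- data.table(stratum = strata)
  meta[, c("year", "sex", "age_band") := tstrsplit(stratum, "|", fixed = TRUE)]
  meta[, year := as.integer(year)]
  denom <- pop[meta, on = c("year", "sex", "age_band"), count]
  refpop <- pop[year == reference_year][
    meta[, .(sex, age_band)],
    on = c("sex", "age_band"), count
  ]
  wgt <- refpop / denom

  std_by_sex <- function(ev, yr) {
    rows <- which(meta$year == yr)
    v <- vapply(sexes[sexes != "All"], function(s) {
      r <- rows[meta$sex[rows] == s]
      sum(ev[r] * wgt[r])
    }, numeric(1))
    c(v, All = sum(v))[sexes]
  }

  set.seed(seed)
  npers <- length(pins)
  draws <- matrix(NA_real_,
    nrow = reps, ncol = length(point),
    dimnames = list(NULL, sexes)
  )
  dropped <- 0L
  for (r in seq_len(reps)) {
    w <- tabulate(sample.int(npers, npers, replace = TRUE), npers)
    ev <- as.numeric(Matrix::crossprod(M, w))
    b <- std_by_sex(ev, base_year)
    if (any(b == 0)) {
      dropped <- dropped + 1L
      next
    }
    draws[r, ] <- percent_change(b, std_by_sex(ev, target_year))
  }
  if (dropped > 0L) {
    warning(sprintf("%d degenerate bootstrap replicate(s) dropped", dropped), call. = FALSE)
  }
  alpha <- (1 - conf) / 2
  out <- data.table(
    sex = sexes,
    pct_change = unname(point),
    ci_low = apply(draws, 2L, quantile, probs = alpha, na.rm = TRUE),
    ci_high = apply(draws, 2L, quantile, probs = 1 - alpha, na.rm = TRUE),
    n_dropped = dropped
  )
  out[]
}
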