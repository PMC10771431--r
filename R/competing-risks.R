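## Second hip fracture with death as a competing event.
##
## Follow-up runs from each person's first in-window case to the first of
## a second case (per the same counting method's definition), death, the
## follow-up horizon, or the administrative end of the register. The
## cause-specific cumulative incidence functions are estimated with the
## Aalen-Johansen estimator; with no covariates this coincides with the
## subdistribution cumulative incidence.

#' Build second-fracture follow-up records
#'
#' @param cases case table from one counting method
#' @param deaths data.table (pin, death_date)
#' @param window c(start_year, end_year): index events are each person's
#'   first case in this calendar window
#' @param horizon_years maximum follow-up in years (default 10)
#' @param admin_end_date administrative censoring day (default: Dec 31 of
#'   the last case year); deaths recorded after it are treated as
#'   censored there
#' @return data.table (pin, index_date, event, time_days, event_date)
#'   with event in {"second_fracture", "death", "censored"}; records with
#'   a death before the index are rejected with a warning
#' @export
build_followup <- function(cases, deaths, window, horizon_years = 10,
                           admin_end_date = NULL) {
  cases <- as.data.table(cases)
  deaths <- as.data.table(deaths)
  if (is.null(admin_end_date)) admin_end_date <- year_end_day(max(cases$year))
  cs <- cases[year >= window[1] & year <= window[2]]
  strip_key(cs)
  setorder(cs, pin, event_date)
  idx <- cs[, .(index_date = event_date[1L]), by = pin]
  ## first case strictly after the index, any calendar year (all cases,
  ## not only in-window ones, can be the second event)
  nxt <- as.data.table(cases)[idx, on = "pin"][event_date > index_date,
    .(second_date = sort(event_date)[1L]),
    by = pin
  ]
  fu <- idx[nxt, on = "pin", second_date := i.second_date]
  fu[deaths, on = "pin", death_date := i.death_date]
  bad <- fu[!is.na(death_date) & death_date < index_date]
  if (nrow(bad) > 0L) {
    warning(sprintf("%d record(s) with death before index rejected", nrow(bad)),
      call. = FALSE
    )
    fu <- fu[is.na(death_date) | death_date >= index_date]
  }
  horizon_day <- fu$index_date + as.integer(round(horizon_years * 365.25))
  cens_day <- pmin(horizon_day, admin_end_date)
  fu[, `:=`(
    event = "censored",
    event_date = cens_day
  )]
  fu[!is.na(death_date) & death_date <= event_date, `:=`(
    event = "death", event_date = death_date
  )]
  fu[!is.na(second_date) & second_date <= event_date, `:=`(
    event = "second_fracture", event_date = second_date
  )]
  fu[, time_days := as.integer(event_date - index_date)]
  out <- fu[, .(pin, index_date, event, time_days, event_date)]
  strip_key(out)
  out[]
}

#' Aalen-Johansen cause-specific cumulative incidence
#'
#' Nonparametric estimator: at each event time t the increment of the
#' cause-k cumulative incidence is `S(t-) * d_k / n(t)`, with S the
#' all-cause Kaplan-Meier survival. Ties between events and censorings at
#' the same time treat events as occurring first.
#'
#' @param followups table from [build_followup()]
#' @return object of class "cuminc_curve": data.table (time, at_risk,
#'   cif_fracture, cif_death, surv) over the distinct event times
#' @export
aalen_johansen <- function(followups) {
  fu <- as.data.table(followups)
  if (nrow(fu) == 0L) stop("no follow-up records", call. = FALSE)
  if (any(fu$time_days < 0)) stop("negative follow-up time", call. = FALSE)
  if (all(fu$event == "censored" & fu$time_days == 0)) {
    stop("all subjects censored at time zero", call. = FALSE)
  }
  times <- sort(unique(fu$time_days[fu$event != "censored"]))
  n <- nrow(fu)
  sorted_all <- sort(fu$time_days)
  n_before <- findInterval(times - 0.5, sorted_all) # subjects leaving before t
  at_risk <- n - n_before
  count_at <- function(ev) {
    tt <- fu$time_days[fu$event == ev]
    if (length(tt) == 0L) {
      return(integer(length(times)))
    }
    as.integer(table(factor(tt, levels = times)))
  }
  d_f <- count_at("second_fracture")
  d_d <- count_at("death")
  surv <- cumprod(1 - (d_f + d_d) / at_risk)
  s_minus <- c(1, head(surv, -1L)) # S(t-)
  out <- data.table(
    time = times,
    at_risk = at_risk,
    cif_fracture = cumsum(s_minus * d_f / at_risk),
    cif_death = cumsum(s_minus * d_d / at_risk),
    surv = surv
  )
  structure(out[], class = c("cuminc_curve", class(out)))
}

#' Evaluate a cumulative incidence curve at a time point
#'
#' Right-continuous step-function evaluation. Times beyond the last
#' observed event time return the final value with attribute
#' `extrapolated = TRUE`.
#'
#' @param curve a "cuminc_curve" from [aalen_johansen()]
#' @param t_years time since index, in years (365.25-day years)
#' @param cause "fracture" or "death"
#' @return probability; attribute `extrapolated` flags evaluation past
#'   the observed range
#' @export
risk_at <- function(curve, t_years, cause = c("fracture", "death")) {
  cause <- match.arg(cause)
  t_days <- t_years * 365.25
  col <- if (cause == "fracture") curve$cif_fracture else curve$cif_death
  i <- findInterval(t_days, curve$time)
  val <- if (i == 0L) 0 else col[i]
  attr(val, "extrapolated") <- t_days > max(curve$time)
  val
}
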