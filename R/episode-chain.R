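## Care-episode construction.
##
## Admissions of one person whose gap (next admit - previous discharge)
## is at most one day are chained into a single care episode: a new
## admission the same day or the next day is a transfer between
## departments or hospitals, not a new injury. The rule is applied as a
## transitive closure, so a chain of transfers each within one day forms
## one episode.

#' Assign care-episode identifiers to raw admissions
#'
#' Partitions each person's admissions into maximal chains under the
#' one-day transfer rule: a new episode starts when
#' `admit_date - max(previous discharge dates) > 1`. Admissions that
#' overlap in time for one person are chained (treated as transfers) and
#' reported as a data-quality warning. Within a chain, admissions sharing
#' an admit date are ordered by discharge date, then admission id.
#'
#' @param admissions data.table with at least (admission_id, pin,
#'   admit_date, discharge_date); row order is irrelevant
#' @return a copy, sorted by (pin, admit_date, discharge_date,
#'   admission_id), with an integer `episode_id` column (globally unique,
#'   chronological within person)
#' @export
assign_episodes <- function(admissions) {
  adm <- as.data.table(admissions)
  if (nrow(adm) == 0L) {
    return(copy(adm)[, episode_id := integer(0)])
  }
  if (any(adm$discharge_date < adm$admit_date)) {
    stop("discharge_date before admit_date", call. = FALSE)
  }
  adm <- copy(adm)
  strip_key(adm)
  setorder(adm, pin, admit_date, discharge_date, admission_id)
  adm[, prev_end := shift(cummax(discharge_date)), by = pin]
  adm[, gap := admit_date - prev_end]
  n_overlap <- adm[!is.na(gap) & gap < 0, .N]
  if (n_overlap > 0L) {
    warning(sprintf(
      "%d admission(s) overlap a previous admission for the same person; chained as transfers",
      n_overlap
    ), call. = FALSE)
  }
  adm[, new_chain := is.na(gap) | gap > 1L]
  adm[, episode_id := cumsum(new_chain)]
  adm[, c("prev_end", "gap", "new_chain") := NULL]
  adm[]
}

#' Collapse chained admissions into care episodes
#'
#' @param admissions raw admission table (see [assign_episodes()]); extra
#'   columns (main_dx, secondary_dx, dept_rehab, admission_acute,
#'   procedure_codes, sex, birth_year) are summarized when present
#' @return data.table, one row per episode: episode_id, pin, start_date,
#'   end_date, year (of start_date), n_admissions, main_dx (first
#'   admission's), all_main_dx / all_secondary_dx / procedure_codes
#'   (semicolon-joined over the chain), acute and rehab_dept (first
#'   admission's flags), sex, age (at start)
#' @export
chain_admissions <- function(admissions) {
  adm <- assign_episodes(admissions)
  ep <- adm[, .(
    pin = pin[1L],
    start_date = admit_date[1L],
    end_date = max(discharge_date),
    n_admissions = .N,
    main_dx = main_dx[1L],
    all_main_dx = paste(main_dx, collapse = ";"),
    all_secondary_dx = paste(secondary_dx[secondary_dx != ""], collapse = ";"),
    procedure_codes = paste(procedure_codes[procedure_codes != ""], collapse = ";"),
    acute = admission_acute[1L] == 1L,
    rehab_dept = dept_rehab[1L] == 1L,
    sex = sex[1L],
    birth_year = birth_year[1L],
    admission_ids = list(admission_id)
  ), by = episode_id]
  ep[, year := year_of_day(start_date)]
  ep[, age := year - birth_year]
  strip_key(ep)
  setorder(ep, pin, start_date)
  ep[]
}

## band the previous-injury gap; register readmission risk is strongly
## nonlinear in time, so the classifier uses categories by default
#' Band the days-since-previous-injury covariate
#' @param days integer days (NA = no previous injury admission)
#' @return factor with levels none, d1_90, d91_365, gt365
#' @export
days_band <- function(days) {
  out <- ifelse(is.na(days), "none",
    ifelse(days <= 90, "d1_90", ifelse(days <= 365, "d91_365", "gt365"))
  )
  factor(out, levels = c("none", "d1_90", "d91_365", "gt365"))
}

#' Compute per-episode classifier covariates
#'
#' For every episode, finds the person's most recent previous injury
#' episode — within the study period or the pre-study lookback window —
#' and derives the time interval since it and whether the first four
#' positions of the two main diagnoses coincide.
#'
#' @param episodes episode table from [chain_admissions()]
#' @param lookback optional raw admission table of pre-study injury
#'   admissions; chained internally and used only as covariate history
#' @param gap_from `"end"` (default) measures the interval from the
#'   previous episode's end date to the current start date; `"start"`
#'   measures start to start
#' @return a copy of `episodes` with columns `days_since_prev_injury`
#'   (integer, NA when no previous injury exists), `same_dx4_as_prev`
#'   (logical, FALSE when no previous injury exists) and `days_cat`
#'   (see [days_band()])
#' @export
compute_covariates <- function(episodes, lookback = NULL, gap_from = c("end", "start")) {
  gap_from <- match.arg(gap_from)
  ep <- copy(as.data.table(episodes))
  strip_key(ep)
  ep[, episode_id := as.character(episode_id)]
  hist <- ep[, .(episode_id, pin, start_date, end_date, main_dx)]
  if (!is.null(lookback) && nrow(lookback) > 0L) {
    lbep <- chain_admissions(lookback)
    hist <- rbindlist(list(
      hist,
      lbep[, .(episode_id = paste0("L", episode_id), pin, start_date, end_date, main_dx)]
    ), use.names = TRUE)
  }
  strip_key(hist)
  setorder(hist, pin, start_date, end_date)
  hist[, prev_end := shift(if (gap_from == "end") end_date else start_date), by = pin]
  hist[, prev_dx4 := shift(dx4_of(main_dx)), by = pin]
  ep[hist, on = "episode_id", `:=`(
    days_since_prev_injury = as.integer(pmax(0L, start_date - i.prev_end)),
    same_dx4_as_prev = !is.na(i.prev_dx4) & dx4_of(main_dx) == i.prev_dx4
  )]
  ep[, days_cat := days_band(days_since_prev_injury)]
  ep[]
}
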