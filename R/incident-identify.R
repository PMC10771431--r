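## Incident vs readmission classification and the comparison counters.
##
## The probability model scores each fracture-coded care episode's
## probability of being a readmission from age, sex, admission type,
## time since the previous injury admission, main-diagnosis similarity
## and rehabilitation department, with configurable interactions. An
## episode is accepted as an incident fracture when that probability is
## below the fixed cut-off of 0.4932; an episode with no previous injury
## admission is always incident.

#' Construct a readmission probability model
#'
#' @param coefficients named numeric vector. Recognized base terms:
#'   `intercept`, `age`, `sexM`, `acute`, `rehab`, `same_dx4`,
#'   `days_d1_90`, `days_d91_365`, `days_gt365` (indicator contrasts of
#'   the banded previous-injury interval; the model is fitted on episodes
#'   with a previous injury, reference band `gt365`) and `days_linear`
#'   (raw days) / `days_log` (log(1 + days)) for alternative transforms.
#'   Pairwise interactions are written `"a:b"`.
#' @param threshold probability cut-off in (0, 1); an episode is
#'   classified incident when P(readmission) < threshold (ties go to
#'   readmission)
#' @return object of class "readmission_model"
#' @export
readmission_model <- function(coefficients, threshold = 0.4932) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must be strictly inside (0, 1)", call. = FALSE)
  }
  structure(
    list(coefficients = coefficients, threshold = threshold),
    class = "readmission_model"
  )
}

## episode covariates -> named design columns for the scorer/fitter
episode_design <- function(episodes) {
  ep <- as.data.table(episodes)
  d <- data.table(
    intercept = rep(1, nrow(ep)),
    age = as.numeric(ep$age),
    sexM = as.numeric(ep$sex == "M"),
    acute = as.numeric(ep$acute),
    rehab = as.numeric(ep$rehab_dept),
    same_dx4 = as.numeric(ep$same_dx4_as_prev),
    days_d1_90 = as.numeric(ep$days_cat == "d1_90"),
    days_d91_365 = as.numeric(ep$days_cat == "d91_365"),
    days_gt365 = as.numeric(ep$days_cat == "gt365"),
    days_linear = ifelse(is.na(ep$days_since_prev_injury), 0,
      as.numeric(ep$days_since_prev_injury)
    ),
    days_log = ifelse(is.na(ep$days_since_prev_injury), 0,
      log1p(as.numeric(ep$days_since_prev_injury))
    )
  )
  d
}

#' Score the probability that an episode is a readmission
#'
#' Computes `plogis(eta)` with `eta` the sum of coefficient times term
#' value over the model's named terms; interaction terms (`"a:b"`) are
#' products of base terms.
#'
#' @param episodes episode table with covariates ([compute_covariates()])
#' @param model a [readmission_model()]
#' @return numeric vector of probabilities in `[0, 1]`
#' @export
score_readmission_probability <- function(episodes, model) {
  stopifnot(inherits(model, "readmission_model"))
  d <- episode_design(episodes)
  eta <- rep(0, nrow(d))
  for (term in names(model$coefficients)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% names(d))) {
      stop(sprintf("unresolvable model term '%s'", term), call. = FALSE)
    }
    val <- Reduce(`*`, lapply(parts, function(p) d[[p]]))
    eta <- eta + model$coefficients[[term]] * val
  }
  plogis(eta)
}

## default fitting formula over the stated covariates; the published
## interaction set is not enumerated anywhere, so interactions are left
## to the `formula` argument (the scorer resolves "a:b" terms as
## products) and the default is additive, which is stable under the
## near-separated covariate cells register data produce
default_model_formula <- function() {
  readmission ~ age + sexM + acute + rehab + same_dx4 +
    days_d1_90 + days_d91_365
}

#' Fit the readmission model on labelled episodes
#'
#' Maximum-likelihood logistic regression of the readmission label on
#' the episode covariates. Only episodes with a previous injury admission
#' enter the fit — episodes without one are incident by rule and carry no
#' readmission signal. Transfer-labelled admissions never appear here:
#' chaining has already merged them into their episodes.
#'
#' @param episodes episode table with covariates
#' @param truth ground-truth table (admission_id, true_class); an episode
#'   is a readmission iff its first admission is labelled "readmission"
#' @param formula model formula over design-column names (default
#'   [default_model_formula()])
#' @param threshold cut-off stored on the returned model (kept at its
#'   configured value, not re-optimized)
#' @param min_n minimum number of episodes in the fit
#' @return a [readmission_model()] with a `fit` attribute (the glm)
#' @export
fit_readmission_model <- function(episodes, truth, formula = NULL,
                                  threshold = 0.4932, min_n = 50L) {
  ep <- as.data.table(episodes)
  truth <- as.data.table(truth)
  lab <- episode_truth(ep, truth)
  use <- !is.na(ep$days_since_prev_injury)
  d <- episode_design(ep[use])
  d[, readmission := as.numeric(lab[use] == "readmission")]
  if (nrow(d) < min_n) {
    stop(sprintf("too few labelled episodes to fit (%d < %d)", nrow(d), min_n),
      call. = FALSE
    )
  }
  if (length(unique(d$readmission)) < 2L) {
    stop("labels contain a single class; logistic fit undefined", call. = FALSE)
  }
  if (is.null(formula)) formula <- default_model_formula()
  fit <- glm(formula, data = d, family = binomial())
  if (!fit$converged) stop("logistic fit did not converge", call. = FALSE)
  p <- fit$fitted.values
  if (all(p < 1e-8 | p > 1 - 1e-8)) {
    stop("perfect separation: all fitted probabilities are 0 or 1", call. = FALSE)
  }
  co <- coef(fit)
  names(co)[names(co) == "(Intercept)"] <- "intercept"
  co <- co[!is.na(co)]
  m <- readmission_model(co, threshold = threshold)
  attr(m, "fit") <- fit
  m
}

## episode-level truth: label of the first admission in the chain
episode_truth <- function(episodes, truth) {
  first_id <- vapply(episodes$admission_ids, function(x) x[[1L]], character(1))
  truth_map <- setNames(truth$true_class, truth$admission_id)
  unname(truth_map[first_id])
}

## which episodes carry a qualifying fracture diagnosis, per dx mode
episode_qualifies <- function(episodes, icd, dx_mode) {
  ep <- as.data.table(episodes)
  switch(dx_mode,
    "first-main" = dx4_of(ep$main_dx) %in% icd,
    "any-main" = dx_matches(ep$all_main_dx, icd),
    "main-or-secondary" = dx_matches(ep$all_main_dx, icd) |
      dx_matches(ep$all_secondary_dx, icd),
    stop(sprintf("unknown dx_mode '%s'", dx_mode), call. = FALSE)
  )
}

case_set <- function(dt, method) {
  out <- dt[, .(method = method, pin, event_date, year = year_of_day(event_date),
                sex, age, id)]
  strip_key(out)
  setorder(out, pin, event_date)
  out[]
}

#' Algorithm-based incident fracture cases
#'
#' Restricts episodes to qualifying fracture diagnoses and age above the
#' minimum, scores each against the readmission model, and accepts an
#' episode as an incident case iff P(readmission) < threshold. Episodes
#' with no previous injury admission are always incident.
#'
#' @param episodes episode table with covariates
#' @param model a [readmission_model()]
#' @param icd qualifying 4-position ICD-10 codes
#' @param min_age cases must have age strictly above this
#' @param dx_mode diagnosis-position mode: "first-main" (default),
#'   "any-main" or "main-or-secondary"
#' @return case table (method, pin, event_date, year, sex, age, id);
#'   `id` is the episode id
#' @export
classify_algorithm <- function(episodes, model,
                               icd = hip_fracture_codes(), min_age = 50,
                               dx_mode = "first-main") {
  ep <- as.data.table(episodes)
  ep <- ep[episode_qualifies(ep, icd, dx_mode) & age > min_age]
  if (nrow(ep) == 0L) {
    return(case_set(data.table(
      pin = character(0), event_date = integer(0),
      sex = character(0), age = integer(0), id = character(0)
    ), "algorithm"))
  }
  p <- score_readmission_probability(ep, model)
  incident <- is.na(ep$days_since_prev_injury) | p < model$threshold
  case_set(
    ep[incident, .(pin, event_date = start_date, sex, age, id = as.character(episode_id))],
    "algorithm"
  )
}

#' Naive incident fracture counting
#'
#' Accepts every admission carrying a qualifying fracture code (main
#' diagnosis; optionally also secondary diagnoses) at age above the
#' minimum as an incident case.
#'
#' @param admissions raw admission table
#' @inheritParams classify_algorithm
#' @param include_secondary also accept codes in the secondary-diagnosis
#'   field
#' @return case table; `id` is the admission id
#' @export
count_naive <- function(admissions, icd = hip_fracture_codes(), min_age = 50,
                        include_secondary = FALSE) {
  adm <- as.data.table(admissions)
  q <- dx4_of(adm$main_dx) %in% icd
  if (include_secondary) q <- q | dx_matches(adm$secondary_dx, icd)
  adm <- adm[q]
  adm[, age := year_of_day(admit_date) - birth_year]
  adm <- adm[age > min_age]
  case_set(
    adm[, .(pin, event_date = admit_date, sex, age, id = as.character(admission_id))],
    "naive"
  )
}

#' Official-statistics incident fracture counting
#'
#' One incident fracture per person and calendar year: any care event in
#' a year that includes a qualifying fracture code (main or secondary
#' diagnosis) makes that person a case for that year, dated at the first
#' such event. The annual series is additionally returned as a centered
#' 3-year moving average (endpoints: 2-year mean), the form in which the
#' official numbers are presented.
#'
#' @param admissions raw admission table
#' @inheritParams classify_algorithm
#' @param include_secondary include secondary diagnoses (default TRUE)
#' @return list: `cases` (case table; at most one row per pin-year) and
#'   `smoothed` (year, sex, n, ma3)
#' @export
count_official <- function(admissions, icd = hip_fracture_codes(), min_age = 50,
                           include_secondary = TRUE) {
  naive <- count_naive(admissions, icd, min_age, include_secondary = include_secondary)
  cases <- naive[, .SD[which.min(event_date)], by = .(pin, year)]
  cases <- case_set(
    cases[, .(pin, event_date, sex, age, id)],
    "official"
  )
  annual <- cases[, .(n = .N), by = .(year, sex)]
  setorder(annual, sex, year)
  annual[, ma3 := {
    k <- .N
    v <- as.numeric(n)
    sm <- v
    if (k >= 2L) {
      for (i in seq_len(k)) {
        sm[i] <- mean(v[max(1L, i - 1L):min(k, i + 1L)])
      }
    }
    sm
  }, by = sex]
  list(cases = cases, smoothed = annual[])
}

#' Naive counting excluding admissions adjacent to a prior case
#'
#' The naive count, but a fracture-coded admission starting at most one
#' day after the discharge of the person's previous retained case
#' admission is excluded (so a chain of day-adjacent transfers is removed
#' while later readmissions are retained as spurious cases).
#'
#' @inheritParams count_naive
#' @return case table
#' @export
count_naive_excl_adjacent <- function(admissions, icd = hip_fracture_codes(),
                                      min_age = 50, include_secondary = FALSE) {
  adm <- as.data.table(admissions)
  naive <- count_naive(adm, icd, min_age, include_secondary = include_secondary)
  disch <- setNames(adm$discharge_date, as.character(adm$admission_id))
  keep_rows <- naive[, {
    d <- disch[id]
    k <- logical(.N)
    last_end <- -Inf
    for (i in seq_len(.N)) {
      if (event_date[i] - last_end > 1) {
        k[i] <- TRUE
        last_end <- d[i]
      } else {
        last_end <- max(last_end, d[i])
      }
    }
    .(event_date = event_date, sex = sex, age = age, id = id, keep = k)
  }, by = pin]
  case_set(
    keep_rows[keep == TRUE, .(pin, event_date, sex, age, id)],
    "naive_excl_adjacent"
  )
}

## ---- surgical procedure codes ---------------------------------------

#' Is a procedure code a hip fracture surgery code?
#'
#' Valid codes are external traction TNX40, reposition/fixation/
#' osteosynthesis NFJ09-NFJ99, and primary arthroplasty NFB09-NFB99.
#' Range matching is lexicographic on the 3-letter prefix plus 2-digit
#' suffix, inclusive at both ends.
#'
#' @param codes character vector of single procedure codes
#' @return logical vector
#' @export
is_hip_surgery_code <- function(codes) {
  codes <- toupper(trimws(codes))
  well_formed <- grepl("^[A-Z]{3}[0-9]{2}$", codes)
  if (any(!well_formed & codes != "")) {
    warning(sprintf("%d malformed procedure code(s) skipped", sum(!well_formed & codes != "")),
      call. = FALSE
    )
  }
  prefix <- substr(codes, 1L, 3L)
  num <- suppressWarnings(as.integer(substr(codes, 4L, 5L)))
  well_formed & (
    codes == "TNX40" |
      (prefix == "NFJ" & num >= 9L & num <= 99L) |
      (prefix == "NFB" & num >= 9L & num <= 99L)
  )
}

#' Proportion of incident cases without a hip surgery code
#'
#' For each case year and sex, the fraction of incident episodes whose
#' chained admissions contain no valid hip fracture surgery code.
#'
#' @param cases algorithm case table (ids are episode ids)
#' @param episodes episode table from [chain_admissions()] (carries the
#'   chain's pooled `procedure_codes`)
#' @return data.table (year, sex, n_cases, prop_no_surgery)
#' @export
check_surgical_codes <- function(cases, episodes) {
  ep <- as.data.table(episodes)[, .(id = as.character(episode_id), procedure_codes)]
  x <- as.data.table(cases)[ep, on = "id", nomatch = NULL]
  x[, has_surgery := vapply(strsplit(procedure_codes, ";", fixed = TRUE), function(cds) {
    any(is_hip_surgery_code(cds))
  }, logical(1))]
  out <- x[, .(n_cases = .N, prop_no_surgery = mean(!has_surgery)), by = .(year, sex)]
  setorder(out, year, sex)
  out[]
}
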