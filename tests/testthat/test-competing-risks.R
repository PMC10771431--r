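followup_fixture <- function(times, events, pin = NULL) {
  data.table(
    pin = if (is.null(pin)) sprintf("P%d", seq_along(times)) else pin,
    index_date = 0L, event = events,
    time_days = as.integer(times), event_date = as.integer(times)
  )
}

test_that("the four-subject fixture reproduces the hand-enumerated estimate", {
  ## fracture at 1, death at 2, censoring at 3, fracture at 4:
  ##  t=1: n=4, CIF_f = 1/4;               S -> 3/4
  ##  t=2: n=3, CIF_d = 3/4 * 1/3 = 1/4;   S -> 1/2
  ##  t=4: n=1, CIF_f = 1/4 + 1/2 = 3/4
  fu <- followup_fixture(
    c(1, 2, 3, 4),
    c("second_fracture", "death", "censored", "second_fracture")
  )
  curve <- aalen_johansen(fu)
  expect_equal(curve$time, c(1L, 2L, 4L))
  expect_equal(curve$cif_fracture, c(0.25, 0.25, 0.75))
  expect_equal(curve$cif_death, c(0, 0.25, 0.25))
  expect_equal(curve$at_risk, c(4L, 3L, 1L))
})

test_that("cumulative incidences and event-free survival sum to one", {
  set.seed(42)
  n <- 400
  fu <- followup_fixture(
    times = sample(1:500, n, replace = TRUE),
    events = sample(c("second_fracture", "death", "censored"), n,
      replace = TRUE, prob = c(0.3, 0.4, 0.3)
    )
  )
  curve <- aalen_johansen(fu)
  expect_equal(
    curve$cif_fracture + curve$cif_death + curve$surv,
    rep(1, nrow(curve))
  )
  expect_true(all(diff(curve$cif_fracture) >= 0))
  expect_true(all(diff(curve$cif_death) >= 0))
  expect_true(all(curve$cif_fracture + curve$cif_death <= 1 + 1e-12))
})

test_that("with no competing events the estimate equals one minus Kaplan-Meier", {
  skip_if_not_installed("survival")
  set.seed(11)
  n <- 300
  times <- sample(1:365, n, replace = TRUE)
  status <- sample(0:1, n, replace = TRUE)
  fu <- followup_fixture(times, ifelse(status == 1, "second_fracture", "censored"))
  curve <- aalen_johansen(fu)
  km <- survival::survfit(survival::Surv(times, status) ~ 1)
  km_at <- summary(km, times = curve$time)
  expect_equal(curve$cif_fracture, 1 - km_at$surv, tolerance = 1e-12)
})

test_that("the estimator agrees with an independent competing-risks implementation", {
  skip_if_not_installed("cmprsk")
  set.seed(33)
  n <- 250
  times <- sample(1:400, n, replace = TRUE)
  code <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.4, 0.35))
  fu <- followup_fixture(
    times,
    c("censored", "second_fracture", "death")[code + 1]
  )
  curve <- aalen_johansen(fu)
  ci <- cmprsk::cuminc(times, code, cencode = 0)
  ref_f <- cmprsk::timepoints(ci, curve$time)$est["1 1", ]
  ref_d <- cmprsk::timepoints(ci, curve$time)$est["1 2", ]
  expect_equal(unname(curve$cif_fracture), unname(ref_f), tolerance = 1e-8)
  expect_equal(unname(curve$cif_death), unname(ref_d), tolerance = 1e-8)
})

test_that("degenerate follow-up inputs are rejected", {
  expect_error(aalen_johansen(followup_fixture(integer(0), character(0))), "no follow-up")
  expect_error(
    aalen_johansen(followup_fixture(0, "censored")),
    "censored at time zero"
  )
  expect_error(
    aalen_johansen(followup_fixture(-1, "death")),
    "negative"
  )
  ## everyone dying at t = 1 saturates the death curve
  fu <- followup_fixture(rep(1, 5), rep("death", 5))
  curve <- aalen_johansen(fu)
  expect_equal(curve$cif_death, 1)
  expect_equal(curve$cif_fracture, 0)
})

test_that("follow-up construction applies the first-event rule", {
  mkcases <- function(dates, pin = "P1") {
    data.table(
      method = "m", pin = pin, event_date = as.integer(dates),
      year = year_of_day(dates), sex = "F", age = 80L,
      id = sprintf("%s_%d", pin, seq_along(dates))
    )
  }
  deaths <- data.table(pin = "P1", death_date = d("2001-01-01") + 900L)
  window <- c(2000L, 2010L)

  ## one fracture, alive at horizon: censored at the horizon
  fu1 <- build_followup(
    mkcases(d("2001-01-01")), data.table(pin = "X", death_date = 1L),
    window,
    horizon_years = 10, admin_end_date = d("2030-12-31")
  )
  expect_equal(fu1$event, "censored")
  expect_equal(fu1$time_days, as.integer(round(10 * 365.25)))

  ## second case at 400 days beats death at 900 days
  fu2 <- build_followup(
    mkcases(d("2001-01-01") + c(0, 400)), deaths, window,
    admin_end_date = d("2030-12-31")
  )
  expect_equal(fu2$event, "second_fracture")
  expect_equal(fu2$time_days, 400L)

  ## death before any second case
  fu3 <- build_followup(mkcases(d("2001-01-01")), deaths, window,
    admin_end_date = d("2030-12-31")
  )
  expect_equal(fu3$event, "death")
  expect_equal(fu3$time_days, 900L)

  ## administrative end censors short-followup index events
  fu4 <- build_followup(
    mkcases(d("2009-06-01")), data.table(pin = "X", death_date = 1L),
    window,
    horizon_years = 10, admin_end_date = d("2010-12-31")
  )
  expect_equal(fu4$event, "censored")
  expect_equal(fu4$event_date, d("2010-12-31"))

  ## a death recorded before the index is rejected with a warning
  bad_death <- data.table(pin = "P1", death_date = d("2000-01-01"))
  expect_warning(
    fu5 <- build_followup(mkcases(d("2001-01-01")), bad_death, window,
      admin_end_date = d("2030-12-31")
    ),
    "death before index"
  )
  expect_equal(nrow(fu5), 0L)
})

test_that("method definitions diverge on a next-day transfer", {
  ## the same person under naive counting has a day-1 "second fracture";
  ## the algorithm set records the true second event at day 400
  naive_cases <- data.table(
    method = "naive", pin = "P1",
    event_date = d("2001-01-01") + c(0L, 6L, 400L),
    sex = "F", age = 80L, id = c("a", "b", "c")
  )
  naive_cases[, year := year_of_day(event_date)]
  alg_cases <- naive_cases[c(1, 3)][, method := "algorithm"]
  no_deaths <- data.table(pin = "X", death_date = 1L)
  fu_naive <- build_followup(naive_cases, no_deaths, c(2000, 2010),
    admin_end_date = d("2030-12-31")
  )
  fu_alg <- build_followup(alg_cases, no_deaths, c(2000, 2010),
    admin_end_date = d("2030-12-31")
  )
  expect_equal(fu_naive$time_days, 6L)
  expect_equal(fu_alg$time_days, 400L)
})

test_that("step evaluation is right-continuous and flags extrapolation", {
  fu <- followup_fixture(c(100, 200), c("second_fracture", "death"))
  curve <- aalen_johansen(fu)
  expect_equal(as.numeric(risk_at(curve, 0)), 0)
  expect_equal(as.numeric(risk_at(curve, 100 / 365.25)), 0.5)
  expect_equal(as.numeric(risk_at(curve, 150 / 365.25)), 0.5)
  out <- risk_at(curve, 30)
  expect_true(attr(out, "extrapolated"))
  expect_false(attr(risk_at(curve, 100 / 365.25), "extrapolated"))
})

test_that("constant competing hazards match the closed-form incidence", {
  ## with constant cause hazards lf and ld,
  ## CIF_f(t) = lf/(lf+ld) * (1 - exp(-(lf+ld) t))
  set.seed(77)
  n <- 4000
  lf <- 0.03
  ld <- 0.20
  tf <- rexp(n, lf)
  td <- rexp(n, ld)
  t_obs <- pmin(tf, td, 10)
  ev <- ifelse(tf <= t_obs & tf <= td, "second_fracture",
    ifelse(td <= t_obs, "death", "censored")
  )
  fu <- followup_fixture(round(t_obs * 365.25), ev)
  curve <- aalen_johansen(fu)
  p10 <- as.numeric(risk_at(curve, 10))
  truth <- lf / (lf + ld) * (1 - exp(-(lf + ld) * 10))
  mc_se <- sqrt(truth * (1 - truth) / n)
  expect_lt(abs(p10 - truth), 3 * mc_se)
  d10 <- as.numeric(risk_at(curve, 10, "death"))
  truth_d <- ld / (lf + ld) * (1 - exp(-(lf + ld) * 10))
  expect_lt(abs(d10 - truth_d), 3 * sqrt(truth_d * (1 - truth_d) / n))
})
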