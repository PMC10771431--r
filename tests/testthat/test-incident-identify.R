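covariate_episode <- function(days = 30L, same_dx4 = TRUE, acute = TRUE,
                              rehab = FALSE, age = 80L, sex = "F") {
  data.table(
    episode_id = "E1", pin = "P1", start_date = 1000L, end_date = 1010L,
    main_dx = "S7200", all_main_dx = "S7200", all_secondary_dx = "",
    procedure_codes = "", acute = acute, rehab_dept = rehab, sex = sex,
    birth_year = 1920L, year = 2000L, age = age,
    days_since_prev_injury = days,
    same_dx4_as_prev = same_dx4, days_cat = days_band(days)
  )
}

test_that("the readmission score is the logistic of the linear predictor", {
  ep <- covariate_episode()
  ## all-zero coefficients: probability one half
  m0 <- readmission_model(c(intercept = 0))
  expect_equal(score_readmission_probability(ep, m0), 0.5)
  ## strongly negative intercept drives the probability to zero
  expect_lt(score_readmission_probability(ep, readmission_model(c(intercept = -30))), 1e-12)
  ## toy model: intercept -1, same_dx4 2, episode with similarity TRUE
  m <- readmission_model(c(intercept = -1, same_dx4 = 2))
  expect_equal(score_readmission_probability(ep, m), plogis(1), tolerance = 1e-12)
  expect_equal(round(plogis(1), 4), 0.7311)
  ## interaction terms multiply their base columns
  mi <- readmission_model(c(intercept = -1, "acute:same_dx4" = 2))
  expect_equal(score_readmission_probability(ep, mi), plogis(1))
  expect_error(
    score_readmission_probability(ep, readmission_model(c(no_such_term = 1))),
    "unresolvable"
  )
  expect_error(readmission_model(c(intercept = 0), threshold = 1), "threshold")
})

test_that("classification applies the cut-off with ties to readmission", {
  ## probability exactly at the threshold: readmission (not counted)
  at <- readmission_model(c(intercept = qlogis(0.4932)))
  below <- readmission_model(c(intercept = qlogis(0.4931)))
  ep <- covariate_episode()
  expect_equal(nrow(classify_algorithm(ep, at)), 0L)
  expect_equal(nrow(classify_algorithm(ep, below)), 1L)

  ## no previous injury admission: incident regardless of the score
  ep_first <- covariate_episode(days = NA_integer_, same_dx4 = FALSE)
  always_readm <- readmission_model(c(intercept = 30))
  expect_equal(nrow(classify_algorithm(ep_first, always_readm)), 1L)

  ## age restriction and diagnosis restriction
  ep_young <- covariate_episode(age = 45L)
  expect_equal(nrow(classify_algorithm(ep_young, below)), 0L)
  ep_other <- covariate_episode()[, `:=`(main_dx = "S8250", all_main_dx = "S8250")]
  expect_equal(nrow(classify_algorithm(ep_other, below)), 0L)
})

test_that("diagnosis-position modes qualify episodes differently", {
  ep <- covariate_episode(days = NA_integer_)
  ep[, `:=`(main_dx = "T840", all_main_dx = "T840;S7200", all_secondary_dx = "S7201")]
  m <- readmission_model(c(intercept = -5))
  expect_equal(nrow(classify_algorithm(ep, m, dx_mode = "first-main")), 0L)
  expect_equal(nrow(classify_algorithm(ep, m, dx_mode = "any-main")), 1L)
  expect_equal(nrow(classify_algorithm(ep, m, dx_mode = "main-or-secondary")), 1L)
})

test_that("model fitting recovers known coefficients and guards degeneracy", {
  set.seed(99)
  n <- 20000
  sim <- data.table(
    episode_id = as.character(seq_len(n)), pin = as.character(seq_len(n)),
    start_date = 0L, end_date = 1L, main_dx = "S7200",
    all_main_dx = "S7200", all_secondary_dx = "", procedure_codes = "",
    sex = sample(c("F", "M"), n, TRUE),
    acute = runif(n) < 0.6, rehab_dept = runif(n) < 0.3,
    same_dx4_as_prev = runif(n) < 0.5,
    days_since_prev_injury = sample(c(30L, 200L, 1000L), n, TRUE),
    age = sample(60:95, n, TRUE), birth_year = 1930L, year = 2000L
  )
  sim[, days_cat := days_band(days_since_prev_injury)]
  truth_coef <- c(
    intercept = -1.5, age = 0.02, sexM = -0.3, acute = -1, rehab = 1.2,
    same_dx4 = 1.5, days_d1_90 = 1, days_d91_365 = 0.5
  )
  p <- score_readmission_probability(sim, readmission_model(truth_coef))
  labels <- data.table(
    admission_id = sim$episode_id,
    true_class = ifelse(runif(n) < p, "readmission", "incident")
  )
  sim[, admission_ids := as.list(episode_id)]
  m <- fit_readmission_model(sim, labels)
  fit <- attr(m, "fit")
  se <- sqrt(diag(vcov(fit)))
  names(se)[names(se) == "(Intercept)"] <- "intercept"
  for (term in names(truth_coef)) {
    expect_lt(abs(m$coefficients[[term]] - truth_coef[[term]]), 3 * se[[term]])
  }
  expect_equal(m$threshold, 0.4932)

  ## single-class labels are rejected
  one_class <- copy(labels)[, true_class := "incident"]
  expect_error(fit_readmission_model(sim, one_class), "single class")
  ## too few episodes are rejected
  expect_error(
    fit_readmission_model(sim[1:10], labels[1:10], min_n = 50),
    "too few"
  )
})

test_that("naive counting accepts every qualifying admission", {
  adm <- mk_adm("P1",
    admit = c(0, 6, 40), discharge = c(5, 20, 45),
    main_dx = c("S7200", "S7200", "S7201")
  )
  expect_equal(nrow(count_naive(adm)), 3L)
  none <- mk_adm("P1", 0, 5, main_dx = "S4200")
  expect_equal(nrow(count_naive(none)), 0L)
  ## age restriction: born 1935, admitted 1985 (day offsets in 1985)
  young <- mk_adm("P1", d("1985-06-01"), d("1985-06-10"), birth_year = 1940L)
  expect_equal(nrow(count_naive(young)), 0L)
  ## secondary diagnoses only count when enabled
  sec <- mk_adm("P1", 0, 5, main_dx = "T840", secondary_dx = "S7200")
  expect_equal(nrow(count_naive(sec)), 0L)
  expect_equal(nrow(count_naive(sec, include_secondary = TRUE)), 1L)
})

test_that("official counting takes one case per person and calendar year", {
  ## three fracture-coded admissions in one year: one case
  three <- mk_adm("P1",
    admit = d("2003-02-01") + c(0, 40, 200),
    discharge = d("2003-02-01") + c(5, 50, 210)
  )
  off <- count_official(three)
  expect_equal(nrow(off$cases), 1L)
  expect_equal(off$cases$event_date, d("2003-02-01"))

  ## index in December with a transfer in January: two cases, one per year
  turn <- mk_adm("P1",
    admit = c(d("2003-12-28"), d("2004-01-03")),
    discharge = c(d("2004-01-02"), d("2004-01-20"))
  )
  expect_equal(nrow(count_official(turn)$cases), 2L)

  ## two true fractures in one year still collapse to one case
  twice <- mk_adm("P1",
    admit = c(d("2003-02-01"), d("2003-09-01")),
    discharge = c(d("2003-02-10"), d("2003-09-10"))
  )
  expect_equal(nrow(count_official(twice)$cases), 1L)
})

test_that("the official annual series is smoothed with a centered 3-year window", {
  adm <- rbindlist(lapply(2000:2004, function(y) {
    k <- y - 1999 # 1, 2, 3, 4, 5 cases
    mk_adm(sprintf("P%d_%d", y, 1:k),
      admit = year_start_day(y) + 30L, discharge = year_start_day(y) + 35L,
      admission_id = sprintf("A%d_%d", y, 1:k)
    )
  }))
  sm <- count_official(adm)$smoothed
  expect_equal(sm$n, 1:5)
  expect_equal(sm$ma3, c(1.5, 2, 3, 4, 4.5)) # endpoints: 2-year means
})

test_that("excluding adjacent admissions removes transfer chains but keeps readmissions", {
  ## index, next-day transfer, chained transfer, then a 30-day readmission
  adm <- mk_adm("P1",
    admit = c(0, 6, 13, 50), discharge = c(5, 12, 20, 55)
  )
  kept <- count_naive_excl_adjacent(adm)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$event_date, c(0L, 50L))

  ## with no adjacent admissions the result equals the naive set
  spread <- mk_adm("P1", admit = c(0, 50, 100), discharge = c(5, 55, 105))
  expect_equal(
    count_naive_excl_adjacent(spread)$event_date,
    count_naive(spread)$event_date
  )
})

test_that("counting methods are nested on any input", {
  for (s in c(3, 14, 27)) {
    cfg <- small_config(seed = s)
    reg <- suppressWarnings(generate_admissions(cfg, generate_population(cfg)$observed))
    ep <- compute_covariates(chain_admissions(reg$admissions), reg$lookback)
    m <- fit_readmission_model(ep[substr(main_dx, 1, 4) %in% hip_fracture_codes() & age > 50],
      reg$truth,
      min_n = 20
    )
    n_alg <- nrow(classify_algorithm(ep, m))
    n_excl <- nrow(count_naive_excl_adjacent(reg$admissions))
    n_naive <- nrow(count_naive(reg$admissions))
    expect_lte(n_alg, n_excl)
    expect_lte(n_excl, n_naive)
  }
})

test_that("classification against ground truth is accurate on synthetic data", {
  cfg <- small_config(seed = 21, scale = 0.05)
  reg <- suppressWarnings(generate_admissions(cfg, generate_population(cfg)$observed))
  ep <- compute_covariates(chain_admissions(reg$admissions), reg$lookback)
  frac <- ep[substr(main_dx, 1, 4) %in% hip_fracture_codes() & age > 50]
  m <- fit_readmission_model(frac, reg$truth)
  perf <- classifier_performance(frac, reg$truth, m)
  ## episodes anchored by a turn-of-window transfer add a third truth row
  expect_true(all(c("incident", "readmission") %in% rownames(perf$confusion)))
  expect_gt(perf$sensitivity, 0.95)
  expect_gt(perf$specificity, 0.90)
})

test_that("hip surgery codes match the documented ranges", {
  expect_true(is_hip_surgery_code("NFB29")) # inside NFB09-NFB99
  expect_true(is_hip_surgery_code("NFJ09")) # inclusive lower bound
  expect_true(is_hip_surgery_code("NFJ99")) # inclusive upper bound
  expect_true(is_hip_surgery_code("TNX40")) # exact-match code
  expect_false(is_hip_surgery_code("TNX41"))
  expect_false(is_hip_surgery_code("NFB08")) # below the range
  expect_false(is_hip_surgery_code("NFC29")) # revision, not primary
  expect_warning(out <- is_hip_surgery_code(c("NFB2", "NFB29")), "malformed")
  expect_equal(out, c(FALSE, TRUE))
})

test_that("surgery check reports the fraction of cases without a valid code", {
  cases <- data.table(
    method = "algorithm", pin = c("P1", "P2"), event_date = c(0L, 10L),
    year = 2000L, sex = "F", age = 80L, id = c("1", "2")
  )
  episodes <- data.table(
    episode_id = c(1L, 2L),
    procedure_codes = c("NFB29;XYZ11", "")
  )
  out <- check_surgical_codes(cases, episodes)
  expect_equal(out$n_cases, 2L)
  expect_equal(out$prop_no_surgery, 0.5)
})
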