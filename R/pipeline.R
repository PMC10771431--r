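## End-to-end pipeline driver: generate -> chain -> identify (all four
## methods) -> trends -> competing risks -> projections, plus a manifest
## with seeds and row-count accounting. All randomness fans out from the
## single config seed (generator stream = seed, bootstrap stream =
## seed + 1000).

#' Classifier performance against ground truth
#'
#' Sensitivity is the proportion of true incident fracture episodes
#' classified incident; specificity the proportion of true readmission
#' episodes classified readmission.
#'
#' @param episodes fracture episode table with covariates
#' @param truth ground-truth table (admission_id, true_class)
#' @param model a [readmission_model()]
#' @param icd,min_age,dx_mode case-definition settings (see
#'   [classify_algorithm()])
#' @return list(sensitivity, specificity, confusion) where confusion is a
#'   2x2 table of truth vs classification
#' @export
classifier_performance <- function(episodes, truth, model,
                                   icd = hip_fracture_codes(), min_age = 50,
                                   dx_mode = "first-main") {
  ep <- as.data.table(episodes)
  ep <- ep[episode_qualifies(ep, icd, dx_mode) & age > min_age]
  lab <- episode_truth(ep, truth)
  p <- score_readmission_probability(ep, model)
  pred <- ifelse(is.na(ep$days_since_prev_injury) | p < model$threshold,
    "incident", "readmission"
  )
  confusion <- table(truth = lab, predicted = pred)
  list(
    sensitivity = mean(pred[lab == "incident"] == "incident"),
    specificity = mean(pred[lab == "readmission"] == "readmission"),
    confusion = confusion
  )
}

#' Run the full synthetic-register analysis pipeline
#'
#' @param config a [cohort_config()]
#' @param bootstrap_reps replications for the standardized-change CI
#' @param horizon_year last projected year (default: config horizon)
#' @param breakpoint_year decline stop for the combined scenario
#' @param cif_horizon_years follow-up horizon for the second-fracture
#'   cumulative incidence
#' @param out_dir optional directory; when given, all tables are written
#'   as CSV files there
#' @return list with elements population, register, episodes, model,
#'   performance, cases (list by method), counts, standardized,
#'   boot_change, cif (list by method), risks10 (10-year second-fracture
#'   and death risks by method), aapc, projections, summary, manifest
#' @export
run_pipeline <- function(config = cohort_config(),
                         bootstrap_reps = 1000L,
                         horizon_year = config$horizon_year,
                         breakpoint_year = 2029L,
                         cif_horizon_years = 10,
                         out_dir = NULL) {
  ## ---- generate -------------------------------------------------------
  population <- generate_population(config)
  register <- generate_admissions(config, population$observed)

  ## ---- chain + covariates --------------------------------------------
  episodes <- chain_admissions(register$admissions)
  episodes <- compute_covariates(episodes, lookback = register$lookback)

  ## ---- fit classifier on a person-split training half ----------------
  frac_ep <- episodes[episode_qualifies(episodes, hip_fracture_codes(), "first-main") &
    age > 50]
  train_pins <- unique(frac_ep$pin)
  train_pins <- train_pins[seq_along(train_pins) %% 2L == 1L]
  model <- tryCatch(
    fit_readmission_model(frac_ep[pin %in% train_pins], register$truth),
    error = function(e) {
      if (!grepl("single class", conditionMessage(e))) stop(e)
      ## register without readmissions: score everything (near) zero
      message("no readmission labels; using a degenerate all-incident model")
      readmission_model(c(intercept = -20), threshold = 0.4932)
    }
  )
  performance <- classifier_performance(
    frac_ep[!pin %in% train_pins], register$truth, model
  )

  ## ---- the four counting methods -------------------------------------
  official <- count_official(register$admissions)
  cases <- list(
    algorithm = classify_algorithm(episodes, model),
    naive = count_naive(register$admissions),
    official = official$cases,
    naive_excl_adjacent = count_naive_excl_adjacent(register$admissions)
  )
  surgery <- check_surgical_codes(cases$algorithm, episodes)

  ## ---- trends ---------------------------------------------------------
  counts <- tabulate_cases(cases$algorithm, population$observed)
  standardized <- standardize_counts(
    counts, population$observed,
    reference_year = config$end_year, base_year = config$start_year
  )
  boot <- bootstrap_change(
    cases$algorithm, population$observed,
    reference_year = config$end_year, base_year = config$start_year,
    reps = bootstrap_reps, seed = config$seed + 1000L
  )

  ## ---- competing risks ------------------------------------------------
  window <- c(config$start_year, config$end_year)
  cif <- lapply(cases[c("algorithm", "naive", "naive_excl_adjacent")], function(cs) {
    aalen_johansen(build_followup(cs, register$deaths, window,
      horizon_years = cif_horizon_years
    ))
  })
  risks10 <- rbindlist(lapply(names(cif), function(m) {
    data.table(
      method = m,
      risk_fracture_10y = as.numeric(risk_at(cif[[m]], cif_horizon_years, "fracture")),
      risk_death_10y = as.numeric(risk_at(cif[[m]], cif_horizon_years, "death"))
    )
  }))

  ## ---- projections ----------------------------------------------------
  aapc <- estimate_aapc(counts)
  projections <- rbindlist(lapply(
    c("continued_decline", "constant_rates", "decline_then_constant"),
    function(sc) {
      project_counts(counts, population$projected, sc, horizon_year,
        aapc = aapc, base_year = config$end_year,
        breakpoint_year = breakpoint_year
      )
    }
  ))

  ## ---- summary + manifest --------------------------------------------
  n_by <- function(m, s) nrow(cases[[m]][sex == s])
  summary <- list(
    naive_excess_pct = c(
      F = percent_change(n_by("algorithm", "F"), n_by("naive", "F")),
      M = percent_change(n_by("algorithm", "M"), n_by("naive", "M"))
    ),
    official_vs_algorithm_pct = c(
      F = percent_change(n_by("algorithm", "F"), n_by("official", "F")),
      M = percent_change(n_by("algorithm", "M"), n_by("official", "M"))
    ),
    algorithm_total = nrow(cases$algorithm),
    naive_total = nrow(cases$naive),
    official_total = nrow(cases$official),
    count_change_pct = percent_change(
      nrow(cases$algorithm[year == config$start_year]),
      nrow(cases$algorithm[year == config$end_year])
    ),
    standardized_change_pct = boot,
    risks10 = risks10,
    sensitivity = performance$sensitivity,
    specificity = performance$specificity
  )
  manifest <- list(
    seed = config$seed,
    bootstrap_seed = config$seed + 1000L,
    package_version = as.character(utils::packageVersion("fractrace")),
    n_admissions = nrow(register$admissions),
    n_lookback = nrow(register$lookback),
    n_episodes = nrow(episodes),
    n_fracture_episodes = nrow(frac_ep),
    n_cases = vapply(cases, nrow, integer(1))
  )

  result <- list(
    population = population, register = register, episodes = episodes,
    model = model, performance = performance, cases = cases,
    surgery = surgery, counts = counts, standardized = standardized,
    boot_change = boot, cif = cif, risks10 = risks10, aapc = aapc,
    projections = projections, summary = summary, manifest = manifest
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write every pipeline table under an output directory
#' @param result list from [run_pipeline()]
#' @param out_dir directory (created if needed)
#' @return invisibly, the directory
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_register(result$register, result$population, out_dir)
  fwrite(rbindlist(result$cases), file.path(out_dir, "cases.csv"))
  fwrite(result$counts, file.path(out_dir, "stratified_counts.csv"))
  fwrite(result$standardized, file.path(out_dir, "standardized.csv"))
  fwrite(result$boot_change, file.path(out_dir, "standardized_change_ci.csv"))
  fwrite(result$surgery, file.path(out_dir, "surgery_check.csv"))
  for (m in names(result$cif)) {
    fwrite(as.data.table(result$cif[[m]]), file.path(out_dir, paste0("cif_", m, ".csv")))
  }
  fwrite(result$risks10, file.path(out_dir, "risks_10y.csv"))
  fwrite(result$aapc, file.path(out_dir, "aapc.csv"))
  fwrite(result$projections, file.path(out_dir, "projections.csv"))
  write_model_coefficients(result$model, file.path(out_dir, "model_coefficients.yaml"))
  manifest <- result$manifest
  manifest$n_cases <- as.list(manifest$n_cases)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
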