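library(data.table)

## admission-row builder for hand-made fixtures; dates are day offsets
mk_adm <- function(pin, admit, discharge,
                   main_dx = "S7200", secondary_dx = "",
                   dept_rehab = 0L, admission_acute = 1L,
                   procedure_codes = "", sex = "F", birth_year = 1900L,
                   admission_id = NULL) {
  n <- max(length(pin), length(admit))
  dt <- data.table(
    pin = rep_len(pin, n),
    admit_date = as.integer(rep_len(admit, n)),
    discharge_date = as.integer(rep_len(discharge, n)),
    main_dx = rep_len(main_dx, n),
    secondary_dx = rep_len(secondary_dx, n),
    dept_rehab = rep_len(as.integer(dept_rehab), n),
    admission_acute = rep_len(as.integer(admission_acute), n),
    procedure_codes = rep_len(procedure_codes, n),
    sex = rep_len(sex, n),
    birth_year = rep_len(as.integer(birth_year), n)
  )
  dt[, admission_id := if (is.null(admission_id)) sprintf("A%04d", seq_len(n)) else rep_len(admission_id, n)]
  dt[]
}

## a small, fast cohort configuration for property tests
small_config <- function(seed = 1L, scale = 0.02, ...) {
  cohort_config(seed = seed, scale = scale, ...)
}

## day offset helper for readable fixture dates
d <- function(date_string) as.integer(as.IDate(date_string))

## incident truth cases (first + later true fractures) as a case table,
## the generator's ground-truth analogue of a counting method's output
truth_cases <- function(register, icd = hip_fracture_codes(), min_age = 50) {
  adm <- merge(register$admissions, register$truth, by = "admission_id")
  adm <- adm[true_class == "incident" & substr(toupper(main_dx), 1, 4) %in% icd]
  adm[, age := year_of_day(admit_date) - birth_year]
  adm <- adm[age > min_age]
  out <- adm[, .(
    method = "truth", pin, event_date = admit_date,
    year = year_of_day(admit_date), sex, age, id = admission_id
  )]
  data.table::setattr(out, "sorted", NULL)
  setorder(out, pin, event_date)
  out[]
}
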