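## Delimited-text readers and writers (CSV, UTF-8, header row) with
## schema validation. Malformed rows are rejected and reported with
## their file line numbers.

admissions_schema <- c(
  "admission_id", "pin", "admit_date", "discharge_date", "main_dx",
  "secondary_dx", "dept_rehab", "admission_acute", "procedure_codes",
  "sex", "birth_year"
)

read_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dt <- fread(path)
  char_cols <- intersect(
    c("admission_id", "pin", "main_dx", "secondary_dx", "procedure_codes", "sex", "age_band"),
    names(dt)
  )
  for (cc in char_cols) set(dt, j = cc, value = as.character(dt[[cc]]))
  if (nrow(dt) == 0L) stop(sprintf("empty input file: %s", path), call. = FALSE)
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0L) {
    stop(sprintf(
      "%s: missing column(s) %s", path, paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  dt
}

#' Read and validate an admissions table
#'
#' Rows with a discharge date before the admit date, unparseable dates or
#' a sex outside {F, M} are rejected; the rejected line numbers (1-based,
#' excluding the header) are reported in a warning.
#'
#' @param path CSV file with the admissions schema
#' @return validated data.table
#' @export
read_admissions <- function(path) {
  dt <- read_checked(path, admissions_schema)
  bad <- !is.finite(dt$admit_date) | !is.finite(dt$discharge_date) |
    dt$discharge_date < dt$admit_date | !(dt$sex %in% c("F", "M"))
  if (any(bad)) {
    warning(sprintf(
      "%s: rejected %d malformed row(s) at line(s) %s",
      path, sum(bad), paste(head(which(bad), 10L), collapse = ", ")
    ), call. = FALSE)
    dt <- dt[!bad]
  }
  if (nrow(dt) == 0L) stop(sprintf("no valid rows in %s", path), call. = FALSE)
  dt
}

#' Read and validate a population table
#' @param path CSV with columns (year, sex, age_band, count)
#' @return validated data.table
#' @export
read_population <- function(path) {
  dt <- read_checked(path, c("year", "sex", "age_band", "count"))
  if (any(dt$count <= 0)) stop(sprintf("%s: nonpositive population counts", path), call. = FALSE)
  dt
}

#' Read a deaths table
#' @param path CSV with columns (pin, death_date)
#' @return data.table
#' @export
read_deaths <- function(path) {
  read_checked(path, c("pin", "death_date"))
}

#' Read readmission-model coefficients from a YAML file
#'
#' Expected layout: a `coefficients` mapping of term name to value and an
#' optional `threshold` scalar.
#'
#' @param path YAML file
#' @return a [readmission_model()]
#' @export
read_model_coefficients <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$coefficients)) stop("no 'coefficients' mapping in file", call. = FALSE)
  readmission_model(
    unlist(spec$coefficients),
    threshold = if (is.null(spec$threshold)) 0.4932 else spec$threshold
  )
}

#' Write readmission-model coefficients to YAML
#' @param model a [readmission_model()]
#' @param path output file
#' @return invisibly, the path
#' @export
write_model_coefficients <- function(model, path) {
  yaml::write_yaml(
    list(coefficients = as.list(model$coefficients), threshold = model$threshold),
    path
  )
  invisible(path)
}
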