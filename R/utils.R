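## Dates are integer day offsets from 1970-01-01 throughout the package.
## Calendar years are derived arithmetically via data.table's IDate support;
## no timezone semantics are involved (whole days only).

#' Day offset of the first of January of a year
#' @param year integer calendar year
#' @return integer day offset from 1970-01-01
#' @export
year_start_day <- function(year) {
  as.integer(as.IDate(paste0(year, "-01-01")))
}

#' Day offset of the last of December of a year
#' @param year integer calendar year
#' @return integer day offset from 1970-01-01
#' @export
year_end_day <- function(year) {
  as.integer(as.IDate(paste0(year, "-12-31")))
}

#' Calendar year of a day offset
#' @param day integer day offset(s) from 1970-01-01
#' @return integer calendar year(s)
#' @export
year_of_day <- function(day) {
  data.table::year(as.IDate(day, origin = "1970-01-01"))
}

#' Number of days in a calendar year
#' @param year integer calendar year
#' @return 365 or 366
#' @keywords internal
days_in_year <- function(year) {
  year_end_day(year) - year_start_day(year) + 1L
}

## Triangular(min, mode, max) sampler via inverse CDF; used for the
## readmission gap distribution.
rtriangular <- function(n, min, mode, max) {
  stopifnot(min <= mode, mode <= max, min < max)
  u <- runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
    min + sqrt(u * (max - min) * (mode - min)),
    max - sqrt((1 - u) * (max - min) * (max - mode))
  )
}

#' Percent change between two counts
#'
#' Returns `100 * (b - a) / a`, the relative change from `a` to `b` in
#' percent. Rounding to a reporting precision is left to callers.
#'
#' @param a baseline count (> 0)
#' @param b comparison count
#' @return numeric percent change (negative = decrease)
#' @examples
#' percent_change(16180, 13929) # about -13.9
#' @export
percent_change <- function(a, b) {
  if (any(a == 0)) stop("percent change undefined for a zero baseline")
  100 * (b - a) / a
}

## drop a (possibly stale) sortedness marker before reordering a result;
## column projections of keyed tables can carry a wrong key over
strip_key <- function(dt) {
  setattr(dt, "sorted", NULL)
  invisible(dt)
}

## normalize an ICD code string: uppercase, dots stripped
norm_dx <- function(x) {
  gsub(".", "", toupper(x), fixed = TRUE)
}

## first 4 positions of an ICD-10 code, normalized
dx4_of <- function(x) {
  substr(norm_dx(x), 1L, 4L)
}

## does a (possibly semicolon-joined) dx string contain a qualifying code?
dx_matches <- function(x, icd) {
  vapply(strsplit(norm_dx(x), ";", fixed = TRUE), function(codes) {
    any(substr(codes, 1L, 4L) %in% icd)
  }, logical(1))
}
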