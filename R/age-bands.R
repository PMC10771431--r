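#' Standard age bands for hip fracture tabulation
#'
#' The default stratification partitions ages above 50 into
#' 50-64, 65-69, 70-74, 75-79, 80-84, 85-89, 90-94 and 95+ years.
#' The opening band is implemented as 50-64 so that the bands are a
#' disjoint partition of \eqn{[50, \infty)}.
#'
#' @return character vector of band labels, in increasing age order
#' @export
hip_age_bands <- function() {
  c("50-64", "65-69", "70-74", "75-79", "80-84", "85-89", "90-94", "95+")
}

## lower bounds of the default bands (used for sampling ages and cutting)
age_band_breaks <- function() {
  c(50, 65, 70, 75, 80, 85, 90, 95, Inf)
}

#' Assign ages to the standard age bands
#'
#' @param age numeric vector of ages in whole years (age at admission)
#' @return factor with levels [hip_age_bands()]; ages of 50 or below map
#'   to the opening band (cases themselves are restricted to age > 50
#'   by the counting functions)
#' @export
age_band_of <- function(age) {
  cut(age,
    breaks = age_band_breaks(), labels = hip_age_bands(),
    right = FALSE, include.lowest = TRUE
  )
}
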