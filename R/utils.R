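#' Round half away from zero
#'
#' Printed workforce tables round halves up (e.g. 27.4948 -> 27.5), whereas
#' [base::round()] rounds half to even. Used only when formatting reported
#' tables; all internal arithmetic stays in double precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.5)      # 3, not 2
#' round_half_up(27.4948, 1)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Provider types distinguished by the visit survey
#'
#' The person-level survey records annual visit counts separately for primary
#' care physicians, sub-specialists, the combined nurse/nurse-practitioner
#' category (not separable in the source), and physician assistants.
#'
#' @return character vector of the four provider type codes.
#' @export
provider_types <- function() {
  c("pcp", "specialist", "np_nurse", "pa")
}

#' Primary care physician specialty set
#'
#' The six generalist specialty categories counted as primary care:
#' general family medicine, general practice, general internal medicine,
#' internal medicine-pediatrics, geriatrics, and general pediatrics.
#'
#' @return character vector of specialty labels.
#' @export
pcp_specialties <- function() {
  c("general family medicine", "general practice",
    "general internal medicine", "internal medicine-pediatrics",
    "geriatrics", "general pediatrics")
}

#' Age binning used for visit rates and population projections
#'
#' Bins 0-4, 5-13, 14-17, 18-24, 25-44, 45-64, 65-84, 85+ partition ages as
#' half-open intervals; the penultimate bin is [65, 85) so every age falls in
#' exactly one bin.
#'
#' @return a list with `breaks` (length 9, last `Inf`) and `labels` (length 8).
#' @export
age_bins <- function() {
  list(
    breaks = c(0, 5, 14, 18, 25, 45, 65, 85, Inf),
    labels = c("0-4", "5-13", "14-17", "18-24", "25-44", "45-64",
               "65-84", "85+")
  )
}

#' Assign ages to bins
#'
#' @param age numeric vector of ages in years (>= 0).
#' @param binning a binning as returned by [age_bins()].
#' @return factor of bin labels, one per age.
#' @export
#' @examples
#' assign_age_bin(c(0, 4, 5, 64, 65, 85, 99))
assign_age_bin <- function(age, binning = age_bins()) {
  if (any(!is.finite(age)) || any(age < 0)) {
    stop("ages must be finite and non-negative")
  }
  cut(age, breaks = binning$breaks, labels = binning$labels,
      right = FALSE, include.lowest = TRUE)
}

# internal: stop unless all named columns present
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# internal: fraction validator
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single number in [0, 1]", name))
  }
  invisible(x)
}
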