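#' Build an age-activity schedule
#'
#' Piecewise-constant probability of being active in direct patient care as a
#' function of age, used to deflate raw roster headcounts for likely retirees.
#' `breaks` are the ages at which the probability steps down; `probs` has one
#' more element than `breaks` (the value below the first break, then one per
#' interval). Probabilities must lie in [0, 1] and be non-increasing.
#'
#' @param breaks increasing ages where the activity probability changes.
#' @param probs activity probabilities, length `length(breaks) + 1`.
#' @return object of class `pcw_activity_schedule`.
#' @seealso [default_activity_schedule()]
#' @export
activity_schedule <- function(breaks, probs) {
  if (length(probs) != length(breaks) + 1) {
    stop("'probs' must have one more element than 'breaks'")
  }
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("'breaks' must be strictly increasing")
  }
  if (any(probs < 0 | probs > 1)) stop("activity probabilities must be in [0, 1]")
  if (is.unsorted(rev(probs))) {
    stop("activity probabilities must be non-increasing with age")
  }
  structure(list(breaks = breaks, probs = probs),
            class = "pcw_activity_schedule")
}

#' Default age-activity schedule
#'
#' Full activity below age 55, stepping down by decade (0.75, 0.50, 0.25) to
#' zero at 85 and above. This is a documented package default, not an
#' empirically estimated schedule; supply your own via [activity_schedule()]
#' for substantive work.
#'
#' @return a `pcw_activity_schedule`.
#' @export
default_activity_schedule <- function() {
  activity_schedule(breaks = c(55, 65, 75, 85),
                    probs = c(1.00, 0.75, 0.50, 0.25, 0.00))
}

#' @export
print.pcw_activity_schedule <- function(x, ...) {
  lo <- c(0, x$breaks)
  hi <- c(x$breaks, Inf)
  cat("Age-activity schedule (P[active in direct patient care]):\n")
  for (i in seq_along(x$probs)) {
    cat(sprintf("  [%3s, %3s): %.2f\n", lo[i],
                ifelse(is.finite(hi[i]), hi[i], "Inf"), x$probs[i]))
  }
  invisible(x)
}

#' Activity probability at given ages
#'
#' @param schedule a `pcw_activity_schedule`.
#' @param age numeric vector of ages (>= 0).
#' @return numeric vector of activity probabilities.
#' @export
schedule_prob <- function(schedule, age) {
  stopifnot(inherits(schedule, "pcw_activity_schedule"))
  if (any(!is.finite(age)) || any(age < 0)) {
    stop("ages must be finite and non-negative")
  }
  schedule$probs[findInterval(age, schedule$breaks) + 1]
}

#' Classify physician records as primary care by specialty
#'
#' True when the record's specialty is in the configured primary care set
#' (default: the six generalist categories of [pcp_specialties()]).
#'
#' @param record data.frame of provider records with `profession` and
#'   `specialty` columns (physicians only).
#' @param pcp_codes character vector of primary care specialty labels.
#' @return logical vector, one element per record.
#' @export
classify_pcp_specialty <- function(record, pcp_codes = pcp_specialties()) {
  check_columns(record, c("profession", "specialty"), "record")
  if (any(record$profession != "physician")) {
    stop("classify_pcp_specialty() applies to physician records only")
  }
  !is.na(record$specialty) & record$specialty %in% pcp_codes
}

#' Fill missing roster fields from a fallback source
#'
#' Field-wise precedence merge: the primary source wins whenever its value is
#' present; missing `specialty` or `activity_status` is filled from the
#' fallback record. Provenance columns (`specialty_source`,
#' `activity_source`) record whether each field came from the primary source,
#' the fallback, or is still missing.
#'
#' @param primary,fallback data.frames with `provider_id`, `year`,
#'   `specialty`, `activity_status`; rows are matched positionally and must
#'   agree on `provider_id` and `year`.
#' @return the primary data.frame with gaps filled and provenance columns.
#' @export
resolve_with_fallback <- function(primary, fallback) {
  cols <- c("provider_id", "year", "specialty", "activity_status")
  check_columns(primary, cols, "primary")
  check_columns(fallback, cols, "fallback")
  if (nrow(primary) != nrow(fallback) ||
      any(primary$provider_id != fallback$provider_id) ||
      any(primary$year != fallback$year)) {
    stop("primary and fallback records must match on provider_id and year")
  }
  out <- primary
  fill_spec <- is.na(out$specialty) & !is.na(fallback$specialty)
  out$specialty[fill_spec] <- fallback$specialty[fill_spec]
  fill_act <- is.na(out$activity_status) & !is.na(fallback$activity_status)
  out$activity_status[fill_act] <- fallback$activity_status[fill_act]
  out$specialty_source <- ifelse(!is.na(primary$specialty), "primary",
                          ifelse(fill_spec, "fallback", "missing"))
  out$activity_source <- ifelse(!is.na(primary$activity_status), "primary",
                         ifelse(fill_act, "fallback", "missing"))
  out
}

#' Age-activity adjusted headcount
#'
#' Sum over records of the schedule's activity probability at each age: the
#' expected number active in direct patient care. With a schedule identically
#' 1 this equals the raw count.
#'
#' @param ages numeric vector of ages, or a data.frame with an `age` column.
#' @param schedule a `pcw_activity_schedule`.
#' @return single numeric (possibly fractional) adjusted count.
#' @export
#' @examples
#' s <- default_activity_schedule()
#' apply_age_activity_adjustment(c(40, 70, 70), s)  # 1 + 0.5 + 0.5
apply_age_activity_adjustment <- function(ages, schedule) {
  if (is.data.frame(ages)) {
    check_columns(ages, "age", "records")
    ages <- ages$age
  }
  sum(schedule_prob(schedule, ages))
}

#' Flag hospitalists from E&M place-of-service billing
#'
#' A provider-year is flagged when strictly more than `threshold` (default
#' 90%) of its evaluation & management services carry a hospital place of
#' service. Profiles with zero total E&M services cannot be assessed: they
#' are not flagged and their indices are attached as the `"indeterminate"`
#' attribute.
#'
#' @param em_hospital,em_office,em_other non-negative service counts
#'   (vectorised).
#' @param threshold strict lower bound on the hospital share, in [0, 1].
#' @return logical vector; attribute `indeterminate` lists zero-total rows.
#' @export
#' @examples
#' flag_hospitalist(95, 5, 0)    # TRUE  (0.95 > 0.90)
#' flag_hospitalist(90, 10, 0)   # FALSE (exactly 0.90 is not "more than")
flag_hospitalist <- function(em_hospital, em_office, em_other,
                             threshold = 0.90) {
  check_fraction(threshold, "threshold")
  if (any(c(em_hospital, em_office, em_other) < 0)) {
    stop("E&M counts must be non-negative")
  }
  total <- em_hospital + em_office + em_other
  flagged <- total > 0 & em_hospital > threshold * total
  indeterminate <- which(total == 0)
  if (length(indeterminate)) {
    attr(flagged, "indeterminate") <- indeterminate
  }
  flagged
}

#' Enumerate physicians and primary care physicians by year
#'
#' Produces the physician trend table: per year, the raw and age-activity
#' adjusted counts of all physicians and of primary care physicians, the
#' (age-adjusted) count of hospitalists among PCPs, and the PCP count
#' excluding hospitalists. Hospitalists are identified from linked billing
#' profiles by the more-than-`threshold` hospital E&M share rule, restricted
#' to PCPs. Counts are expected (fractional) headcounts; rounding happens
#' only in report rendering.
#'
#' @param roster provider roster data.frame.
#' @param billing billing profile data.frame (`provider_id`, `year`,
#'   `em_hospital`, `em_office`, `em_other`).
#' @param schedule a `pcw_activity_schedule`.
#' @param pcp_codes primary care specialty set.
#' @param years years to report; default all years in the roster. Requested
#'   years absent from the roster are dropped with a warning.
#' @param threshold hospitalist hospital-share threshold (strict).
#' @return data.frame of class `pcw_table1` with columns `year`, `all_raw`,
#'   `all_age_adjusted`, `pcp_raw`, `pcp_age_adjusted`, `hospitalists`,
#'   `pcp_excl_hospitalists`, plus attribute `hospitalist_ids` (the flagged
#'   `provider_id:year` keys).
#' @export
enumerate_physicians <- function(roster, billing,
                                 schedule = default_activity_schedule(),
                                 pcp_codes = pcp_specialties(),
                                 years = NULL, threshold = 0.90) {
  check_columns(roster, c("provider_id", "year", "profession", "specialty",
                          "age"), "roster")
  check_columns(billing, c("provider_id", "year", "em_hospital", "em_office",
                           "em_other"), "billing")
  phys <- roster[roster$profession == "physician", , drop = FALSE]
  if (is.null(years)) years <- sort(unique(phys$year))
  missing_years <- setdiff(years, unique(phys$year))
  if (length(missing_years)) {
    warning("no physician records for year(s): ",
            paste(missing_years, collapse = ", "), "; omitted")
    years <- setdiff(years, missing_years)
  }

  key <- function(id, yr) paste(id, yr, sep = ":")
  bflag <- flag_hospitalist(billing$em_hospital, billing$em_office,
                            billing$em_other, threshold)
  hosp_keys <- key(billing$provider_id, billing$year)[bflag]

  rows <- lapply(years, function(yr) {
    ry <- phys[phys$year == yr, , drop = FALSE]
    is_pcp <- classify_pcp_specialty(ry, pcp_codes)
    pcp <- ry[is_pcp, , drop = FALSE]
    w_all <- schedule_prob(schedule, ry$age)
    w_pcp <- schedule_prob(schedule, pcp$age)
    is_hosp <- key(pcp$provider_id, pcp$year) %in% hosp_keys
    hosp_adj <- sum(w_pcp[is_hosp])
    data.frame(year = yr,
               all_raw = nrow(ry),
               all_age_adjusted = sum(w_all),
               pcp_raw = nrow(pcp),
               pcp_age_adjusted = sum(w_pcp),
               hospitalists = hosp_adj,
               pcp_excl_hospitalists = sum(w_pcp) - hosp_adj)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pcw_table1", "data.frame")
  attr(out, "hospitalist_ids") <- hosp_keys
  out
}
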