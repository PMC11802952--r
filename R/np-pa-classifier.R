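.facility_types <- c("RHC", "FQHC", "retail_clinic", "critical_access_hospital",
                     "skilled_nursing_facility", "none")
.nonoffice_setting_cols <- c("share_hospital", "share_ed", "share_nursing_home",
                             "share_assisted_living", "share_home_health")

#' Classifier configuration for NP/PA primary care attribution
#'
#' The attribution rules have no published precedence; the package default
#' applies administrative facility designations before inferential
#' composition rules: setting override, then RHC/FQHC (rule 3), then retail
#' clinic / critical access hospital / skilled nursing facility (rule 5),
#' then behavioral-health dominance (rule 4), then physician composition
#' (rules 1-2), then the solo-practice rule (6). "Primarily" working in a
#' setting and behavioral-health "dominance" both mean strictly more than
#' `majority_threshold` (default 0.5).
#'
#' @param precedence character vector ordering of
#'   `c("setting_override", "rule3", "rule5", "rule4", "rule12", "rule6")`.
#' @param majority_threshold strict threshold for "primarily"/"dominated".
#' @return object of class `pcw_classifier_config`.
#' @export
classifier_config <- function(precedence = c("setting_override", "rule3",
                                             "rule5", "rule4", "rule12",
                                             "rule6"),
                              majority_threshold = 0.5) {
  valid <- c("setting_override", "rule3", "rule5", "rule4", "rule12", "rule6")
  if (!setequal(precedence, valid)) {
    stop("'precedence' must be a permutation of: ",
         paste(valid, collapse = ", "))
  }
  check_fraction(majority_threshold, "majority_threshold")
  structure(list(precedence = precedence,
                 majority_threshold = majority_threshold),
            class = "pcw_classifier_config")
}

# evaluate a single rule on one linkage row; NULL means the rule does not fire
.apply_rule <- function(rule, row, thr) {
  n_phys <- row$n_pcp_physicians + row$n_nonpcp_physicians
  members <- n_phys + row$n_social_workers + row$n_psychologists +
    row$n_other_clinicians
  switch(rule,
    setting_override = {
      nonoffice <- sum(unlist(row[.nonoffice_setting_cols]))
      if (nonoffice > thr) list(pc = 0, rule = "setting_override") else NULL
    },
    rule3 = if (row$facility_type %in% c("RHC", "FQHC")) {
      list(pc = 1, rule = "rule3")
    } else NULL,
    rule5 = if (row$facility_type %in% c("retail_clinic",
                                         "critical_access_hospital",
                                         "skilled_nursing_facility")) {
      list(pc = 0, rule = "rule5")
    } else NULL,
    rule4 = {
      bh <- row$n_social_workers + row$n_psychologists
      if (members > 0 && bh > thr * members) list(pc = 0, rule = "rule4")
      else NULL
    },
    rule12 = {
      if (n_phys > 0) {
        pc <- row$n_pcp_physicians / n_phys
        list(pc = pc, rule = if (pc == 0) "rule1" else "rule2")
      } else if (members > 0) {
        # non-physician colleagues, no physicians: no PCPs present (rule 1)
        list(pc = 0, rule = "rule1")
      } else NULL
    },
    rule6 = if (members == 0) list(pc = 1, rule = "rule6") else NULL,
    stop("unknown rule: ", rule)
  )
}

#' Attribute NPs and PAs to primary care
#'
#' Applies the six practice-linkage assumptions in the configured precedence
#' to each NP/PA-year: providers primarily working in hospital, emergency
#' department, nursing home, assisted living or home health settings are not
#' primary care; NPs/PAs in rural health clinics and federally qualified
#' health centers are primary care; those in retail clinics, critical access
#' hospitals and skilled nursing facilities are not; organisations dominated
#' by social workers and psychologists are not; in physician practices the
#' primary care fraction equals the PCP share of the practice's physicians
#' (zero when the practice has no PCPs); and solo practices with no other
#' clinicians are primary care. The first rule that fires decides, and its
#' label is recorded. Providers linked to several organisations are
#' attributed through the one with the largest `org_service_share` (ties:
#' the higher resulting primary care fraction).
#'
#' @param links data.frame with one row per provider-organisation-year:
#'   `provider_id`, `year`, `profession`, `facility_type`, composition counts
#'   (`n_pcp_physicians`, `n_nonpcp_physicians`, `n_social_workers`,
#'   `n_psychologists`, `n_other_clinicians`), setting share columns
#'   (`share_hospital`, `share_ed`, `share_nursing_home`,
#'   `share_assisted_living`, `share_home_health`, `share_office`), and
#'   optionally `org_service_share` (default 1).
#' @param config a [classifier_config()].
#' @return data.frame of class `pcw_attribution`: `provider_id`, `year`,
#'   `profession`, `pc_fraction` in [0, 1], `rule` (deciding rule label).
#' @export
#' @examples
#' link <- data.frame(provider_id = "NP1", year = 2020, profession = "NP",
#'   facility_type = "FQHC", n_pcp_physicians = 2, n_nonpcp_physicians = 0,
#'   n_social_workers = 0, n_psychologists = 0, n_other_clinicians = 0,
#'   share_hospital = 0, share_ed = 0, share_nursing_home = 0,
#'   share_assisted_living = 0, share_home_health = 0, share_office = 1)
#' classify_np_pa(link)  # pc_fraction 1, rule3
classify_np_pa <- function(links, config = classifier_config()) {
  stopifnot(inherits(config, "pcw_classifier_config"))
  need <- c("provider_id", "year", "profession", "facility_type",
            "n_pcp_physicians", "n_nonpcp_physicians", "n_social_workers",
            "n_psychologists", "n_other_clinicians", .nonoffice_setting_cols,
            "share_office")
  check_columns(links, need, "links")
  if (any(!links$profession %in% c("NP", "PA"))) {
    stop("classify_np_pa() applies to NP and PA records only")
  }
  bad <- setdiff(unique(links$facility_type), .facility_types)
  if (length(bad)) {
    stop("unknown facility type(s): ", paste(bad, collapse = ", "))
  }
  if (!"org_service_share" %in% names(links)) links$org_service_share <- 1

  classify_row <- function(row) {
    for (rule in config$precedence) {
      hit <- .apply_rule(rule, row, config$majority_threshold)
      if (!is.null(hit)) return(hit)
    }
    list(pc = NA_real_, rule = "unclassified")
  }

  res <- lapply(seq_len(nrow(links)), function(i) classify_row(links[i, ]))
  out <- data.frame(provider_id = links$provider_id, year = links$year,
                    profession = links$profession,
                    pc_fraction = vapply(res, `[[`, numeric(1), "pc"),
                    rule = vapply(res, `[[`, character(1), "rule"),
                    stringsAsFactors = FALSE)

  # multi-organisation providers: keep the largest-service-share attribution
  keykey <- paste(out$provider_id, out$year, sep = ":")
  if (anyDuplicated(keykey)) {
    ord <- order(keykey, -links$org_service_share, -out$pc_fraction)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(paste(out$provider_id, out$year, sep = ":")), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("pcw_attribution", "data.frame")
  out
}

#' Tabulate NP/PA primary care counts by year and profession
#'
#' Per year and profession: total headcount, primary care headcount (sum of
#' fractional attributions) and the percent in primary care (one decimal,
#' half-up). The fractional sum makes the partition exact: primary care plus
#' non-primary-care counts equal the total.
#'
#' @param attributions a [classify_np_pa()] result.
#' @param years optional years filter.
#' @return data.frame of class `pcw_table2`: `year`, `profession`, `n_all`,
#'   `n_primary_care`, `percent`.
#' @export
enumerate_np_pa <- function(attributions, years = NULL) {
  check_columns(attributions, c("provider_id", "year", "profession",
                                "pc_fraction"), "attributions")
  a <- attributions
  if (!is.null(years)) a <- a[a$year %in% years, , drop = FALSE]
  split_key <- interaction(a$year, a$profession, drop = TRUE)
  rows <- lapply(split(a, split_key), function(g) {
    pc <- sum(g$pc_fraction, na.rm = TRUE)
    data.frame(year = g$year[1], profession = g$profession[1],
               n_all = nrow(g), n_primary_care = pc,
               percent = if (nrow(g) > 0) {
                 round_half_up(100 * pc / nrow(g), 1)
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$year, out$profession), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pcw_table2", "data.frame")
  out
}

#' Office-setting and primary-care-among-office shares by profession
#'
#' For each profession: the share of providers working predominantly in an
#' office setting (office service share strictly above `office_threshold`),
#' and among those, the mean primary care fraction. The product of the two is
#' the visit multiplier that converts survey visit counts for a provider type
#' into primary care visit counts. A profession with no office-based
#' providers gets an `NA` primary-care share and is flagged in the
#' `degenerate` column.
#'
#' @param attributions a [classify_np_pa()] result.
#' @param links the linkage table with `share_office` (the setting profile).
#' @param office_threshold strict office-share threshold, default 0.5.
#' @return data.frame: `profession`, `office_share`, `pc_share_office`,
#'   `multiplier`, `degenerate`.
#' @export
office_and_pc_shares <- function(attributions, links, office_threshold = 0.5) {
  check_columns(links, c("provider_id", "year", "share_office"), "links")
  key <- function(d) paste(d$provider_id, d$year, sep = ":")
  office <- links$share_office > office_threshold
  office_by_key <- stats::setNames(office, key(links))
  a <- attributions
  a$office <- office_by_key[key(a)]
  rows <- lapply(split(a, a$profession), function(g) {
    off_share <- mean(g$office, na.rm = TRUE)
    n_off <- sum(g$office, na.rm = TRUE)
    pc_off <- if (n_off > 0) {
      sum(g$pc_fraction[g$office], na.rm = TRUE) / n_off
    } else NA_real_
    data.frame(profession = g$profession[1], office_share = off_share,
               pc_share_office = pc_off,
               multiplier = if (is.na(pc_off)) NA_real_ else pc_off,
               degenerate = n_off == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
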