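#' Survey-weighted mean annual visit rates by age bin, sex and provider type
#'
#' Cell means are weighted means over the full sample in the cell —
#' zero-visit persons included — i.e. `sum(w * visits) / sum(w)`. The
#' estimator is invariant to rescaling all weights. Cells with no
#' respondents are returned with an `NA` mean (and `n = 0`); the projection
#' engine refuses incomplete grids.
#'
#' @param survey person-level survey data.frame with `age`, `sex`, `weight`
#'   and `visits_<type>` columns.
#' @param year optional single year to restrict to (requires a `year`
#'   column).
#' @param binning an [age_bins()] binning.
#' @param types provider types to estimate, default [provider_types()].
#' @return data.frame of class `pcw_rates`: `age_bin`, `sex`,
#'   `provider_type`, `mean_visits`, `n`, `weight_sum`; attribute
#'   `reference_year`.
#' @export
#' @examples
#' s <- data.frame(age = c(30, 30, 30), sex = "female",
#'                 weight = c(1, 1, 1), visits_pcp = c(0, 0, 4))
#' r <- weighted_visit_rates(s, types = "pcp")
#' r$mean_visits[r$age_bin == "25-44" & r$sex == "female"]  # 4/3
weighted_visit_rates <- function(survey, year = NULL, binning = age_bins(),
                                 types = provider_types()) {
  check_columns(survey, c("age", "sex", "weight"), "survey")
  vcols <- paste0("visits_", types)
  check_columns(survey, vcols, "survey")
  if (!is.null(year)) {
    check_columns(survey, "year", "survey")
    survey <- survey[survey$year == year, , drop = FALSE]
  }
  if (any(survey$weight <= 0)) stop("survey weights must be positive")
  survey$age_bin <- as.character(assign_age_bin(survey$age, binning))

  grid <- expand.grid(age_bin = binning$labels, sex = c("female", "male"),
                      provider_type = types, stringsAsFactors = FALSE)
  cellkey <- paste(survey$age_bin, survey$sex)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- cellkey == paste(grid$age_bin[i], grid$sex[i])
    w <- survey$weight[sel]
    v <- survey[[paste0("visits_", grid$provider_type[i])]][sel]
    data.frame(grid[i, , drop = FALSE],
               mean_visits = if (length(w)) sum(w * v) / sum(w) else NA_real_,
               n = length(w), weight_sum = sum(w))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("pcw_rates", "data.frame")
  attr(out, "reference_year") <- year
  out
}

#' Adjust NP/nurse and PA visit counts to primary care visits
#'
#' The survey does not separate primary care from other NP/nurse and PA
#' visits; counts are scaled by the share of office-based NPs and PAs
#' attributed to primary care. The published multipliers are 0.456 (NP) and
#' 0.358 (PA); pipeline runs derive them from [office_and_pc_shares()].
#'
#' @param raw_np_visits,raw_pa_visits non-negative visit counts (vectorised).
#' @param multipliers named numeric `c(np = , pa = )`, each in [0, 1].
#' @return list with adjusted `np` and `pa` counts.
#' @export
#' @examples
#' adjust_np_pa_visits(100, 100)  # np 45.6, pa 35.8
adjust_np_pa_visits <- function(raw_np_visits, raw_pa_visits,
                                multipliers = c(np = 0.456, pa = 0.358)) {
  if (any(raw_np_visits < 0) || any(raw_pa_visits < 0)) {
    stop("visit counts must be non-negative")
  }
  if (!all(c("np", "pa") %in% names(multipliers))) {
    stop("'multipliers' must be named c(np = , pa = )")
  }
  check_fraction(unname(multipliers[["np"]]), "multipliers['np']")
  check_fraction(unname(multipliers[["pa"]]), "multipliers['pa']")
  list(np = multipliers[["np"]] * raw_np_visits,
       pa = multipliers[["pa"]] * raw_pa_visits)
}

#' Weighted national visit totals by provider type and year
#'
#' Per survey year: the weighted total of visits to sub-specialists and
#' PCPs, the NP/nurse and PA totals scaled to primary care by the
#' multipliers, the all-primary-care total (PCP + adjusted NP + adjusted
#' PA), and the population estimate (sum of weights).
#'
#' @param survey person-level survey data.frame (may span several years).
#' @param multipliers NP/PA primary care multipliers as in
#'   [adjust_np_pa_visits()].
#' @return data.frame of class `pcw_table3`: `year`, `subspecialist_visits`,
#'   `pcp_visits`, `np_nurse_visits_adj`, `pa_visits_adj`,
#'   `total_primary_care_visits`, `population`.
#' @export
visit_totals_by_year <- function(survey,
                                 multipliers = c(np = 0.456, pa = 0.358)) {
  check_columns(survey, c("year", "weight", "visits_pcp", "visits_specialist",
                          "visits_np_nurse", "visits_pa"), "survey")
  rows <- lapply(split(survey, survey$year), function(g) {
    w <- g$weight
    adj <- adjust_np_pa_visits(sum(w * g$visits_np_nurse),
                               sum(w * g$visits_pa), multipliers)
    pcp <- sum(w * g$visits_pcp)
    data.frame(year = g$year[1],
               subspecialist_visits = sum(w * g$visits_specialist),
               pcp_visits = pcp,
               np_nurse_visits_adj = adj$np,
               pa_visits_adj = adj$pa,
               total_primary_care_visits = pcp + adj$np + adj$pa,
               population = sum(w))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$year), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pcw_table3", "data.frame")
  out
}

#' Visits per capita by provider type and year
#'
#' Divides each visit total by the year's population estimate (the sum of
#' survey weights), giving mean annual visits per person; reported to two
#' decimals (half-up). Because the denominator is the weight total, each
#' per-capita rate equals the corresponding weighted mean visit count.
#'
#' @param totals a [visit_totals_by_year()] table.
#' @return data.frame of class `pcw_table4`: `year`, `subspecialist`, `pcp`,
#'   `np_nurse`, `pa`, `total_primary_care` (visits per person).
#' @export
per_capita_rates <- function(totals) {
  check_columns(totals, c("year", "subspecialist_visits", "pcp_visits",
                          "np_nurse_visits_adj", "pa_visits_adj",
                          "total_primary_care_visits", "population"),
                "totals")
  if (any(totals$population <= 0)) {
    stop("population denominators must be positive")
  }
  out <- data.frame(
    year = totals$year,
    subspecialist = round_half_up(totals$subspecialist_visits /
                                    totals$population, 2),
    pcp = round_half_up(totals$pcp_visits / totals$population, 2),
    np_nurse = round_half_up(totals$np_nurse_visits_adj / totals$population, 2),
    pa = round_half_up(totals$pa_visits_adj / totals$population, 2),
    total_primary_care = round_half_up(totals$total_primary_care_visits /
                                         totals$population, 2)
  )
  class(out) <- c("pcw_table4", "data.frame")
  out
}

#' Share of primary care visits delivered by PCPs
#'
#' @param pcp_visits visits to primary care physicians.
#' @param total_pc_visits all primary care visits (must be positive).
#' @return percent, one decimal (half-up).
#' @export
#' @examples
#' pcp_visit_share(515747034, 565235078)  # 91.2
pcp_visit_share <- function(pcp_visits, total_pc_visits) {
  if (any(total_pc_visits <= 0)) stop("total visits must be positive")
  round_half_up(100 * pcp_visits / total_pc_visits, 1)
}

#' Combine provider-type rates into an all-primary-care rate grid
#'
#' For each age bin and sex: PCP rate plus multiplier-adjusted NP/nurse and
#' PA rates. This is the rate grid the need projection applies to projected
#' populations.
#'
#' @param rates a [weighted_visit_rates()] grid containing the `pcp`,
#'   `np_nurse` and `pa` provider types.
#' @param multipliers NP/PA primary care multipliers.
#' @return data.frame: `age_bin`, `sex`, `mean_visits`.
#' @export
primary_care_rate_table <- function(rates,
                                    multipliers = c(np = 0.456, pa = 0.358)) {
  check_columns(rates, c("age_bin", "sex", "provider_type", "mean_visits"),
                "rates")
  pick <- function(tp) {
    r <- rates[rates$provider_type == tp, c("age_bin", "sex", "mean_visits")]
    stats::setNames(r$mean_visits, paste(r$age_bin, r$sex))
  }
  pcp <- pick("pcp"); np <- pick("np_nurse"); pa <- pick("pa")
  keys <- names(pcp)
  out <- data.frame(
    age_bin = sub(" (female|male)$", "", keys),
    sex = sub("^.* ", "", keys),
    mean_visits = unname(pcp + multipliers[["np"]] * np[keys] +
                           multipliers[["pa"]] * pa[keys]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
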