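#' Default physician age distribution
#'
#' A stylised age distribution for a clinician roster: roughly flat through
#' mid-career with a declining right tail into the 80s, so the age-activity
#' adjustment has something to bite on. Not estimated from any roster; it is
#' a testability stand-in.
#'
#' @return named numeric vector: names are ages (27-85), values sum to 1.
#' @export
default_physician_ages <- function() {
  ages <- 27:85
  w <- ifelse(ages < 35, 0.8,
       ifelse(ages < 55, 1.0,
       ifelse(ages < 65, 0.8,
       ifelse(ages < 75, 0.45, 0.15))))
  stats::setNames(w / sum(w), ages)
}

#' Default mean annual visit rates by age bin, sex and provider type
#'
#' Cell means for the synthetic visit survey. The primary care physician
#' profile is U-shaped in age (highest for the youngest and oldest), boys
#' exceed girls through age 13, and women exceed men from 18 to 64 —
#' the qualitative pattern reported for US office-based primary care
#' utilisation. Sub-specialist rates rise with age; the nurse/NP and PA
#' columns are unadjusted (pre-multiplier) rates. Levels are chosen so the
#' population-weighted PCP mean lands near 1.6 visits/person/year.
#'
#' @return data.frame with columns `age_bin`, `sex`, `provider_type`, `mean`.
#' @export
default_visit_rate_params <- function() {
  labs <- age_bins()$labels
  # rows: age bins in order; columns: female, male
  m <- list(
    pcp        = cbind(female = c(2.6, 1.2, 1.0, 0.95, 1.3, 1.9, 3.1, 3.8),
                       male   = c(2.8, 1.3, 0.9, 0.55, 0.75, 1.5, 2.9, 3.6)),
    specialist = cbind(female = c(0.5, 0.45, 0.6, 0.8, 1.3, 2.3, 4.2, 4.5),
                       male   = c(0.5, 0.5, 0.55, 0.5, 0.8, 1.9, 4.0, 4.3)),
    np_nurse   = cbind(female = c(0.55, 0.30, 0.35, 0.50, 0.55, 0.60, 0.80, 0.90),
                       male   = c(0.60, 0.32, 0.30, 0.30, 0.35, 0.50, 0.70, 0.85)),
    pa         = cbind(female = c(0.10, 0.08, 0.12, 0.18, 0.20, 0.22, 0.25, 0.22),
                       male   = c(0.11, 0.09, 0.12, 0.12, 0.14, 0.18, 0.22, 0.20))
  )
  out <- do.call(rbind, lapply(names(m), function(tp) {
    data.frame(
      age_bin = rep(labs, 2),
      sex = rep(c("female", "male"), each = length(labs)),
      provider_type = tp,
      mean = c(m[[tp]][, "female"], m[[tp]][, "male"]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Default baseline population grid (2020-like, in persons)
#'
#' Age-bin by sex counts summing to about 331 million, matching the broad
#' shape of the 2020 US resident population (larger female shares at older
#' ages). Used as the base year of the synthetic population projection.
#'
#' @return data.frame with columns `age_bin`, `sex`, `population`.
#' @export
default_population_base <- function() {
  labs <- age_bins()$labels
  total_m <- c(19.0, 36.5, 16.7, 30.2, 88.3, 83.3, 50.9, 6.5) * 1e6
  female_share <- c(0.489, 0.489, 0.489, 0.492, 0.499, 0.508, 0.538, 0.640)
  data.frame(
    age_bin = rep(labs, 2),
    sex = rep(c("female", "male"), each = length(labs)),
    population = c(total_m * female_share, total_m * (1 - female_share)),
    stringsAsFactors = FALSE
  )
}

#' Default aging-scenario target bin shares for 2040
#'
#' End-of-horizon age-bin shares with the older bins grown (65+ near 23% of
#' the population), toward which the projection interpolates linearly.
#'
#' @return named numeric vector over age bins, summing to 1.
#' @export
default_aging_target_shares <- function() {
  stats::setNames(
    c(0.052, 0.098, 0.047, 0.085, 0.252, 0.235, 0.193, 0.038),
    age_bins()$labels
  )
}

#' Configuration for the synthetic data generator
#'
#' Bundles every ground-truth parameter of the five synthetic sources:
#' provider roster, billing profiles, practice linkage, visit survey and
#' population projection. Defaults reflect published 2020 US aggregates where
#' those exist (PCP specialty share ~34.5%, hospitalist share ~14% of
#' age-adjusted PCPs, NP/PA primary care shares 32.1%/27.5%, office shares
#' 81.5%/85.3%, ~12.6% population growth to 2040); the distributional forms
#' are stand-ins chosen for testability.
#'
#' @param seed integer RNG seed; every generator stage derives its stream
#'   from it, so identical configs yield byte-identical bundles.
#' @param years roster/billing years to generate.
#' @param survey_years visit survey years to generate (reference year for
#'   rate estimation).
#' @param n_physicians,n_nps,n_pas roster sizes per year.
#' @param pcp_specialty_share fraction of physicians in the six primary care
#'   specialty categories.
#' @param hospitalist_share fraction of PCPs billing more than 90% of
#'   evaluation & management services from a hospital.
#' @param np_pc_share,pa_pc_share target overall primary-care fractions among
#'   NPs and PAs. Must not exceed the corresponding office share (the
#'   classification rules place all primary-care NPs/PAs in office settings).
#' @param np_office_share,pa_office_share fraction working predominantly in
#'   an office setting.
#' @param multispecialty_share fraction of office-based NPs/PAs placed in
#'   multi-specialty practices, where the primary-care fraction is the PCP
#'   share of the practice's physicians (mean 1/2 by construction).
#' @param age_distribution named numeric vector age -> probability, summing
#'   to 1, for roster ages.
#' @param n_survey_persons survey respondents per survey year.
#' @param visit_rate_params data.frame (`age_bin`, `sex`, `provider_type`,
#'   `mean`) covering the full grid; cell means of the visit count model.
#' @param weight_sdlog log-normal sd of survey weight noise (0 gives equal
#'   weights).
#' @param population_base baseline `age_bin` x `sex` population grid.
#' @param projection_years span of the population projection.
#' @param growth_path named numeric vector year -> total-population
#'   multiplier relative to the base year; default linear to 1.126 at the
#'   horizon. All values must be positive.
#' @param aging_strength scalar in [0, 1+]; 0 freezes the age structure
#'   (pure growth), 1 reaches `aging_target_shares` at the horizon.
#' @param aging_target_shares named bin-share vector at full aging.
#'
#' @return an object of class `pcw_config` (a validated list).
#' @seealso [simulate_bundle()]
#' @export
gen_config <- function(seed = 1L,
                       years = 2020L,
                       survey_years = 2019L,
                       n_physicians = 20000L,
                       n_nps = 6000L,
                       n_pas = 3000L,
                       pcp_specialty_share = 0.345,
                       hospitalist_share = 0.14,
                       np_pc_share = 0.321,
                       pa_pc_share = 0.275,
                       np_office_share = 0.815,
                       pa_office_share = 0.853,
                       multispecialty_share = 0.20,
                       age_distribution = default_physician_ages(),
                       n_survey_persons = 20000L,
                       visit_rate_params = default_visit_rate_params(),
                       weight_sdlog = 0.5,
                       population_base = default_population_base(),
                       projection_years = 2020:2040,
                       growth_path = NULL,
                       aging_strength = 1,
                       aging_target_shares = default_aging_target_shares()) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      abs(seed) >= 2^31 - 1000) {
    stop("'seed' must be a single integer below 2^31 - 1000")
  }
  seed <- as.integer(seed)
  for (nm in c("n_physicians", "n_nps", "n_pas", "n_survey_persons")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 ||
        v != floor(v)) {
      stop(sprintf("'%s' must be a single non-negative integer", nm))
    }
  }
  for (nm in c("pcp_specialty_share", "hospitalist_share", "np_pc_share",
               "pa_pc_share", "np_office_share", "pa_office_share",
               "multispecialty_share")) {
    check_fraction(get(nm), nm)
  }
  if (np_pc_share > np_office_share) {
    stop("np_pc_share must not exceed np_office_share")
  }
  if (pa_pc_share > pa_office_share) {
    stop("pa_pc_share must not exceed pa_office_share")
  }
  if (is.null(names(age_distribution)) ||
      abs(sum(age_distribution) - 1) > 1e-8 || any(age_distribution < 0)) {
    stop("'age_distribution' must be a named non-negative vector summing to 1")
  }
  check_columns(visit_rate_params, c("age_bin", "sex", "provider_type", "mean"),
                "visit_rate_params")
  grid <- expand.grid(age_bin = age_bins()$labels,
                      sex = c("female", "male"),
                      provider_type = provider_types(),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$age_bin, d$sex, d$provider_type)
  if (!all(key(grid) %in% key(visit_rate_params))) {
    stop("visit_rate_params must cover every (age bin, sex, provider type) cell")
  }
  if (any(visit_rate_params$mean < 0)) {
    stop("visit rate means must be non-negative")
  }
  check_columns(population_base, c("age_bin", "sex", "population"),
                "population_base")
  if (any(population_base$population < 0)) {
    stop("population counts must be non-negative")
  }
  if (is.null(growth_path)) {
    span <- range(projection_years)
    f <- if (span[2] > span[1]) {
      (projection_years - span[1]) / (span[2] - span[1])
    } else {
      rep(0, length(projection_years))
    }
    growth_path <- stats::setNames(1 + 0.126 * f, projection_years)
  }
  if (is.null(names(growth_path)) ||
      !all(as.character(projection_years) %in% names(growth_path))) {
    stop("'growth_path' must be named by every projection year")
  }
  if (any(growth_path <= 0)) stop("growth multipliers must be positive")
  if (aging_strength < 0) stop("'aging_strength' must be non-negative")
  if (abs(sum(aging_target_shares) - 1) > 1e-8 ||
      !all(age_bins()$labels %in% names(aging_target_shares))) {
    stop("'aging_target_shares' must cover all age bins and sum to 1")
  }

  structure(list(
    seed = seed, years = as.integer(years),
    survey_years = as.integer(survey_years),
    n_physicians = as.integer(n_physicians), n_nps = as.integer(n_nps),
    n_pas = as.integer(n_pas),
    pcp_specialty_share = pcp_specialty_share,
    hospitalist_share = hospitalist_share,
    np_pc_share = np_pc_share, pa_pc_share = pa_pc_share,
    np_office_share = np_office_share, pa_office_share = pa_office_share,
    multispecialty_share = multispecialty_share,
    age_distribution = age_distribution,
    n_survey_persons = as.integer(n_survey_persons),
    visit_rate_params = visit_rate_params,
    weight_sdlog = weight_sdlog,
    population_base = population_base,
    projection_years = as.integer(projection_years),
    growth_path = growth_path,
    aging_strength = aging_strength,
    aging_target_shares = aging_target_shares
  ), class = "pcw_config")
}

#' @export
print.pcw_config <- function(x, ...) {
  cat("Synthetic workforce generator configuration\n")
  cat(sprintf("  seed: %d | roster years: %s | survey years: %s\n",
              x$seed, paste(x$years, collapse = ","),
              paste(x$survey_years, collapse = ",")))
  cat(sprintf("  physicians: %d (PCP share %.3f, hospitalist share %.3f)\n",
              x$n_physicians, x$pcp_specialty_share, x$hospitalist_share))
  cat(sprintf("  NPs: %d (pc %.3f, office %.3f) | PAs: %d (pc %.3f, office %.3f)\n",
              x$n_nps, x$np_pc_share, x$np_office_share,
              x$n_pas, x$pa_pc_share, x$pa_office_share))
  cat(sprintf("  survey persons/year: %d | projection %d-%d (growth to %.3f, aging %.2f)\n",
              x$n_survey_persons, min(x$projection_years),
              max(x$projection_years),
              unname(x$growth_path[as.character(max(x$projection_years))]),
              x$aging_strength))
  invisible(x)
}
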