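# Each stage seeds its own RNG stream from config$seed plus a fixed offset, so
# stages are individually deterministic and a bundle is reproducible whether
# stages are called one by one or through simulate_bundle().
.stage_offsets <- c(roster = 11L, billing = 23L, links = 37L,
                    survey = 53L, population = 71L)

.stage_seed <- function(config, stage) {
  set.seed(config$seed + .stage_offsets[[stage]])
}

# non-primary-care specialties for the synthetic roster
.non_pcp_specialties <- c(
  "cardiology", "dermatology", "orthopedic surgery", "psychiatry",
  "anesthesiology", "neurology", "obstetrics and gynecology",
  "emergency medicine", "general surgery", "radiology"
)

#' Generate a synthetic provider roster
#'
#' One row per provider-year with profession (physician, NP, PA), specialty
#' (physicians only), and age drawn from the configured age distribution.
#' Physician specialties are primary care with probability
#' `pcp_specialty_share`, spread uniformly over the six generalist
#' categories.
#'
#' @param config a [gen_config()] object.
#' @return data.frame with columns `provider_id`, `year`, `profession`,
#'   `specialty`, `age`, `activity_status`.
#' @export
gen_provider_roster <- function(config) {
  stopifnot(inherits(config, "pcw_config"))
  .stage_seed(config, "roster")
  ages_pool <- as.integer(names(config$age_distribution))
  one_year <- function(year) {
    n <- c(config$n_physicians, config$n_nps, config$n_pas)
    prof <- rep(c("physician", "NP", "PA"), times = n)
    ntot <- sum(n)
    if (ntot == 0) {
      return(data.frame(provider_id = character(), year = integer(),
                        profession = character(), specialty = character(),
                        age = integer(), activity_status = logical(),
                        stringsAsFactors = FALSE))
    }
    id <- sprintf("%s%06d", c("MD", "NP", "PA")[rep(1:3, times = n)],
                  unlist(lapply(n, seq_len)))
    age <- sample(ages_pool, ntot, replace = TRUE,
                  prob = config$age_distribution)
    specialty <- rep(NA_character_, ntot)
    if (config$n_physicians > 0) {
      is_pcp <- stats::runif(config$n_physicians) < config$pcp_specialty_share
      spec <- ifelse(
        is_pcp,
        sample(pcp_specialties(), config$n_physicians, replace = TRUE),
        sample(.non_pcp_specialties, config$n_physicians, replace = TRUE)
      )
      specialty[prof == "physician"] <- spec
    }
    data.frame(provider_id = id, year = as.integer(year), profession = prof,
               specialty = specialty, age = as.integer(age),
               activity_status = TRUE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(config$years, one_year))
  rownames(out) <- NULL
  out
}

#' Generate synthetic billing profiles
#'
#' Evaluation & management (E&M) service counts by place of service for every
#' physician-year in the roster. A configured `hospitalist_share` of primary
#' care physicians is generated with a hospital E&M share strictly above 0.90
#' (drawn in 0.92-0.99); everyone else strictly below (0.02-0.60), so the
#' downstream >90% flag recovers the generated hospitalist set exactly.
#'
#' @param roster a provider roster from [gen_provider_roster()].
#' @param config a [gen_config()] object.
#' @return list with `billing` (data.frame `provider_id`, `year`,
#'   `em_hospital`, `em_office`, `em_other`) and `hospitalist_ids`
#'   (character vector of `provider_id:year` keys generated as hospitalists).
#' @export
gen_billing_profiles <- function(roster, config) {
  stopifnot(inherits(config, "pcw_config"))
  if (nrow(roster) == 0) stop("roster must be non-empty")
  .stage_seed(config, "billing")
  phys <- roster[roster$profession == "physician", , drop = FALSE]
  n <- nrow(phys)
  if (n == 0) {
    return(list(billing = data.frame(provider_id = character(),
                                     year = integer(), em_hospital = integer(),
                                     em_office = integer(),
                                     em_other = integer(),
                                     stringsAsFactors = FALSE),
                hospitalist_ids = character()))
  }
  is_pcp <- phys$specialty %in% pcp_specialties()
  hosp <- is_pcp & stats::runif(n) < config$hospitalist_share
  total <- sample(200:3000, n, replace = TRUE)
  h_share <- ifelse(hosp, stats::runif(n, 0.92, 0.99),
                    stats::runif(n, 0.02, 0.60))
  em_hospital <- round(h_share * total)
  rest <- total - em_hospital
  em_office <- round(rest * 0.9)
  em_other <- rest - em_office
  billing <- data.frame(provider_id = phys$provider_id, year = phys$year,
                        em_hospital = as.integer(em_hospital),
                        em_office = as.integer(em_office),
                        em_other = as.integer(em_other),
                        stringsAsFactors = FALSE)
  rownames(billing) <- NULL
  list(billing = billing,
       hospitalist_ids = paste(phys$provider_id, phys$year, sep = ":")[hosp])
}

# organisation mechanisms and what they imply for the classifier
.pc_mechanisms <- c("fqhc", "rhc", "pcp_practice", "solo")
.npc_office_mechanisms <- c("no_pcp_practice", "retail_clinic",
                            "skilled_nursing_facility",
                            "critical_access_hospital", "behavioral")

# build one organisation row per provider given its mechanism
.build_org <- function(mech, n) {
  f <- function(x) rep_len(x, n)
  out <- data.frame(
    facility_type = f("none"), n_pcp_physicians = f(0L),
    n_nonpcp_physicians = f(0L), n_social_workers = f(0L),
    n_psychologists = f(0L), n_other_clinicians = f(0L),
    stringsAsFactors = FALSE
  )
  ri <- function(lo, hi) sample(lo:hi, n, replace = TRUE)
  switch(mech,
    fqhc = { out$facility_type <- f("FQHC")
             out$n_pcp_physicians <- ri(1, 4)
             out$n_other_clinicians <- ri(0, 3) },
    rhc = { out$facility_type <- f("RHC")
            out$n_pcp_physicians <- ri(0, 2)
            out$n_other_clinicians <- ri(0, 2) },
    pcp_practice = { out$n_pcp_physicians <- ri(2, 10)
                     out$n_other_clinicians <- ri(0, 3) },
    solo = { },
    multispecialty = {
      n_phys <- sample(4:20, n, replace = TRUE)
      # symmetric truncation at 1..n-1 keeps the expected PCP share at 1/2
      n_pcp <- stats::rbinom(n, n_phys, 0.5)
      n_pcp <- pmax(1L, pmin(n_phys - 1L, n_pcp))
      out$n_pcp_physicians <- n_pcp
      out$n_nonpcp_physicians <- n_phys - n_pcp
      out$n_other_clinicians <- ri(0, 4)
    },
    no_pcp_practice = { out$n_nonpcp_physicians <- ri(2, 15)
                        out$n_other_clinicians <- ri(0, 3) },
    retail_clinic = { out$facility_type <- f("retail_clinic")
                      out$n_other_clinicians <- ri(0, 4) },
    skilled_nursing_facility = {
      out$facility_type <- f("skilled_nursing_facility")
      out$n_nonpcp_physicians <- ri(0, 2)
      out$n_other_clinicians <- ri(1, 6) },
    critical_access_hospital = {
      out$facility_type <- f("critical_access_hospital")
      out$n_pcp_physicians <- ri(0, 2)
      out$n_nonpcp_physicians <- ri(1, 8) },
    behavioral = {
      out$n_social_workers <- ri(3, 10)
      out$n_psychologists <- ri(2, 6)
      out$n_other_clinicians <- ri(0, 2) },
    nonoffice = {
      out$n_nonpcp_physicians <- ri(2, 20)
      out$n_other_clinicians <- ri(0, 6)
      # a tenth sit in FQHCs to exercise the setting-override precedence
      out$facility_type <- ifelse(stats::runif(n) < 0.10, "FQHC", "none")
    },
    stop("unknown mechanism: ", mech)
  )
  out
}

# setting-of-care share columns for office vs non-office providers
.build_settings <- function(office, n) {
  share_office <- numeric(n)
  hosp <- ed <- nh <- al <- hh <- numeric(n)
  n_off <- sum(office)
  if (n_off) {
    so <- stats::runif(n_off, 0.70, 1.00)
    rem <- 1 - so
    share_office[office] <- so
    hosp[office] <- rem * 0.4; ed[office] <- rem * 0.1
    nh[office] <- rem * 0.2; al[office] <- rem * 0.1; hh[office] <- rem * 0.2
  }
  n_non <- sum(!office)
  if (n_non) {
    dom <- sample(c("hospital", "ed", "nursing_home", "assisted_living",
                    "home_health"), n_non, replace = TRUE,
                  prob = c(0.45, 0.15, 0.2, 0.08, 0.12))
    ds <- stats::runif(n_non, 0.60, 0.95)
    rem <- 1 - ds
    off <- rem * 0.6
    spread <- rem * 0.4 / 4
    m <- matrix(spread, nrow = n_non, ncol = 5)
    colnames(m) <- c("hospital", "ed", "nursing_home", "assisted_living",
                     "home_health")
    m[cbind(seq_len(n_non), match(dom, colnames(m)))] <- ds
    share_office[!office] <- off
    hosp[!office] <- m[, "hospital"]; ed[!office] <- m[, "ed"]
    nh[!office] <- m[, "nursing_home"]; al[!office] <- m[, "assisted_living"]
    hh[!office] <- m[, "home_health"]
  }
  data.frame(share_hospital = hosp, share_ed = ed, share_nursing_home = nh,
             share_assisted_living = al, share_home_health = hh,
             share_office = share_office)
}

#' Generate synthetic practice-linkage records for NPs and PAs
#'
#' Assigns each NP/PA-year an organisation whose facility type, clinician
#' composition and setting-of-care shares are constructed so that the
#' six-rule classifier reaches a known intended primary-care fraction.
#' Intended primary-care providers are all office-based (split across
#' FQHC/RHC placements, PCP-only practices and solo practices);
#' multi-specialty placements carry a fractional truth equal to the PCP share
#' of the practice's physicians; non-primary-care providers split between
#' office mechanisms (no-PCP practices, retail clinics, skilled nursing
#' facilities, critical access hospitals, behavioral-health organisations)
#' and predominantly non-office settings.
#'
#' @param roster a provider roster containing NPs and/or PAs.
#' @param config a [gen_config()] object.
#' @return list with `links` (one row per provider-year: linkage, facility,
#'   composition and setting-share columns) and `truth` (data.frame
#'   `provider_id`, `year`, `profession`, `pc_fraction_truth`, `mechanism`).
#' @export
gen_practice_links <- function(roster, config) {
  stopifnot(inherits(config, "pcw_config"))
  app <- roster[roster$profession %in% c("NP", "PA"), , drop = FALSE]
  if (nrow(app) == 0) stop("roster contains no NPs or PAs")
  .stage_seed(config, "links")
  n <- nrow(app)

  pc_share <- ifelse(app$profession == "NP", config$np_pc_share,
                     config$pa_pc_share)
  office_share <- ifelse(app$profession == "NP", config$np_office_share,
                         config$pa_office_share)
  m <- config$multispecialty_share
  q_pc_office <- ifelse(office_share > 0, pc_share / office_share, 0)
  p_det1 <- q_pc_office - 0.5 * m
  if (any(p_det1 < 0 & office_share > 0)) {
    stop("multispecialty_share too large for the configured pc/office shares")
  }
  p_det0 <- pmax(0, 1 - m - p_det1)

  u <- stats::runif(n)
  office <- u < office_share
  v <- stats::runif(n)
  mech <- character(n)
  mech[!office] <- "nonoffice"
  idx <- which(office)
  for (i in idx) {
    if (v[i] < m) {
      mech[i] <- "multispecialty"
    } else if (v[i] < m + p_det1[i]) {
      mech[i] <- sample(.pc_mechanisms, 1,
                        prob = c(0.35, 0.15, 0.30, 0.20))
    } else {
      mech[i] <- sample(.npc_office_mechanisms, 1,
                        prob = c(0.40, 0.20, 0.10, 0.10, 0.20))
    }
  }

  org <- do.call(rbind, lapply(split(seq_len(n), mech), function(ix) {
    o <- .build_org(mech[ix[1]], length(ix))
    o$.row <- ix
    o
  }))
  org <- org[order(org$.row), ]
  org$.row <- NULL
  settings <- .build_settings(office, n)

  pc_truth <- numeric(n)
  pc_truth[mech %in% .pc_mechanisms] <- 1
  ms <- mech == "multispecialty"
  if (any(ms)) {
    pc_truth[ms] <- org$n_pcp_physicians[ms] /
      (org$n_pcp_physicians[ms] + org$n_nonpcp_physicians[ms])
  }

  links <- data.frame(
    provider_id = app$provider_id, year = app$year,
    profession = app$profession,
    organization_id = sprintf("ORG%06d", seq_len(n)),
    org_service_share = 1,
    org, settings, stringsAsFactors = FALSE
  )
  rownames(links) <- NULL
  truth <- data.frame(provider_id = app$provider_id, year = app$year,
                      profession = app$profession,
                      pc_fraction_truth = pc_truth, mechanism = mech,
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(links = links, truth = truth)
}

#' Generate a synthetic person-level visit survey
#'
#' Respondent-years with age, sex, a positive survey weight and annual visit
#' counts to each provider type. Ages and sexes follow the configured
#' baseline population composition; visit counts are Poisson with the
#' configured cell means (so zero-visit persons occur naturally); weights are
#' log-normal noise around `total population / n`, making weighted and
#' unweighted estimates differ while the weight total estimates the
#' population.
#'
#' @param config a [gen_config()] object.
#' @return data.frame with columns `person_id`, `year`, `age`, `sex`,
#'   `weight`, `visits_pcp`, `visits_specialist`, `visits_np_nurse`,
#'   `visits_pa`.
#' @export
gen_visit_survey <- function(config) {
  stopifnot(inherits(config, "pcw_config"))
  .stage_seed(config, "survey")
  base <- config$population_base
  labs <- age_bins()$labels
  bin_pop <- tapply(base$population, base$age_bin, sum)[labs]
  female_prop <- vapply(labs, function(b) {
    f <- base$population[base$age_bin == b & base$sex == "female"]
    tot <- sum(base$population[base$age_bin == b])
    if (tot > 0) sum(f) / tot else 0.5
  }, numeric(1))
  lo <- c(0, 5, 14, 18, 25, 45, 65, 85)
  hi <- c(4, 13, 17, 24, 44, 64, 84, 99)

  rp <- config$visit_rate_params
  rate_of <- function(bin, sex, type) {
    rp$mean[match(paste(bin, sex, type), paste(rp$age_bin, rp$sex,
                                               rp$provider_type))]
  }

  one_year <- function(year) {
    n <- config$n_survey_persons
    if (n == 0) {
      return(data.frame(person_id = character(), year = integer(),
                        age = integer(), sex = character(), weight = numeric(),
                        visits_pcp = integer(), visits_specialist = integer(),
                        visits_np_nurse = integer(), visits_pa = integer(),
                        stringsAsFactors = FALSE))
    }
    bi <- sample(seq_along(labs), n, replace = TRUE, prob = bin_pop)
    age <- lo[bi] + floor(stats::runif(n) * (hi[bi] - lo[bi] + 1))
    sex <- ifelse(stats::runif(n) < female_prop[bi], "female", "male")
    bin <- labs[bi]
    rates <- vapply(provider_types(), function(tp) rate_of(bin, sex, tp),
                    numeric(n))
    visits <- apply(rates, 2, function(mu) stats::rpois(n, mu))
    w0 <- sum(base$population) / n
    weight <- w0 * stats::rlnorm(n, meanlog = -config$weight_sdlog^2 / 2,
                                 sdlog = config$weight_sdlog)
    data.frame(person_id = sprintf("SP%04d%06d", year %% 10000, seq_len(n)),
               year = as.integer(year), age = as.integer(age), sex = sex,
               weight = weight,
               visits_pcp = as.integer(visits[, "pcp"]),
               visits_specialist = as.integer(visits[, "specialist"]),
               visits_np_nurse = as.integer(visits[, "np_nurse"]),
               visits_pa = as.integer(visits[, "pa"]),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(config$survey_years, one_year))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic population projection
#'
#' Year by age-bin by sex counts over the projection span. The total
#' population follows `growth_path` exactly; the age-bin shares interpolate
#' linearly from the baseline composition toward `aging_target_shares`,
#' scaled by `aging_strength` (0 = pure growth, no compositional change).
#' Within each bin the baseline female/male split is retained. Yearly totals
#' therefore equal `base total x growth multiplier` exactly (conservation),
#' and with all multipliers 1 a pure-aging scenario conserves the total.
#'
#' @param config a [gen_config()] object.
#' @return data.frame with columns `year`, `age_bin`, `sex`, `population`.
#' @export
gen_population_projection <- function(config) {
  stopifnot(inherits(config, "pcw_config"))
  base <- config$population_base
  labs <- age_bins()$labels
  total0 <- sum(base$population)
  bin0 <- tapply(base$population, base$age_bin, sum)[labs]
  s0 <- bin0 / total0
  s1 <- config$aging_target_shares[labs]
  fem <- vapply(labs, function(b) {
    tot <- sum(base$population[base$age_bin == b])
    if (tot > 0) {
      sum(base$population[base$age_bin == b & base$sex == "female"]) / tot
    } else 0.5
  }, numeric(1))

  yrs <- config$projection_years
  span <- range(yrs)
  out <- do.call(rbind, lapply(yrs, function(t) {
    f <- if (span[2] > span[1]) (t - span[1]) / (span[2] - span[1]) else 0
    # shares interpolate s0 -> s1, at rate f scaled by aging_strength
    w <- min(1, f * config$aging_strength)
    s <- (1 - w) * s0 + w * s1
    s <- s / sum(s)
    total_t <- total0 * config$growth_path[[as.character(t)]]
    bins <- total_t * s
    data.frame(year = as.integer(t), age_bin = rep(labs, 2),
               sex = rep(c("female", "male"), each = length(labs)),
               population = c(bins * fem, bins * (1 - fem)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a full synthetic data bundle
#'
#' Runs all five generator stages under a single configuration and returns
#' the roster, billing, linkage, survey and population tables together with a
#' `truth` record (the config plus generated hospitalist ids and NP/PA
#' primary-care fractions). Truth is held only here, outside the data tables,
#' so no pipeline stage can read it.
#'
#' @param config a [gen_config()] object.
#' @return an object of class `pcw_bundle`: a list with elements `roster`,
#'   `billing`, `links`, `survey`, `population`, `truth`.
#' @export
#' @examples
#' b <- simulate_bundle(gen_config(seed = 7, n_physicians = 500,
#'                                 n_nps = 200, n_pas = 100,
#'                                 n_survey_persons = 500))
#' sapply(b[c("roster", "billing", "links", "survey", "population")], nrow)
simulate_bundle <- function(config) {
  stopifnot(inherits(config, "pcw_config"))
  roster <- gen_provider_roster(config)
  bill <- gen_billing_profiles(roster, config)
  lk <- gen_practice_links(roster, config)
  survey <- gen_visit_survey(config)
  population <- gen_population_projection(config)
  structure(list(
    roster = roster, billing = bill$billing, links = lk$links,
    survey = survey, population = population,
    truth = list(config = config, hospitalist_ids = bill$hospitalist_ids,
                 np_pa = lk$truth)
  ), class = "pcw_bundle")
}

#' @export
print.pcw_bundle <- function(x, ...) {
  cat("Synthetic workforce data bundle\n")
  for (nm in c("roster", "billing", "links", "survey", "population")) {
    cat(sprintf("  %-10s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Write a bundle to CSV files with a YAML truth sidecar
#'
#' @param bundle a [simulate_bundle()] result.
#' @param outdir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_bundle <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "pcw_bundle"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in c("roster", "billing", "links", "survey", "population")) {
    p <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(bundle[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  truth <- bundle$truth
  cfg <- truth$config
  cfg_list <- unclass(cfg)
  cfg_list$visit_rate_params <- NULL  # tabular; keep sidecar small
  cfg_list$population_base <- NULL
  cfg_list$age_distribution <- as.list(cfg_list$age_distribution)
  sidecar <- list(config = cfg_list,
                  hospitalist_ids = as.list(truth$hospitalist_ids))
  tp <- file.path(outdir, "truth.yaml")
  yaml::write_yaml(sidecar, tp)
  utils::write.csv(truth$np_pa, file.path(outdir, "truth_np_pa.csv"),
                   row.names = FALSE)
  invisible(c(paths, tp))
}
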