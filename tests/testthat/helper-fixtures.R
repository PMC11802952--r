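# small generator configuration for fast unit tests
small_config <- function(seed = 101, ...) {
  defaults <- list(seed = seed, n_physicians = 1500, n_nps = 600,
                   n_pas = 300, n_survey_persons = 2000)
  do.call(gen_config, utils::modifyList(defaults, list(...)))
}

# one fully-specified office-based linkage row, overridable field-wise
link_row <- function(...) {
  base <- data.frame(
    provider_id = "NP000001", year = 2020L, profession = "NP",
    organization_id = "ORG1", org_service_share = 1,
    facility_type = "none", n_pcp_physicians = 0L, n_nonpcp_physicians = 0L,
    n_social_workers = 0L, n_psychologists = 0L, n_other_clinicians = 0L,
    share_hospital = 0, share_ed = 0, share_nursing_home = 0,
    share_assisted_living = 0, share_home_health = 0, share_office = 1,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# binomial standard error for a proportion
binom_se <- function(p, n) sqrt(p * (1 - p) / n)
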