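#' Pipeline configuration
#'
#' A single configuration object driving the end-to-end run: the synthetic
#' generator config (or paths to CSV inputs), the activity schedule, the
#' primary care specialty set, the hospitalist threshold, the classifier
#' config, the visit multipliers (`NULL` derives them from the classified
#' office/primary-care shares, as the published method does), the baseline
#' year and the reporting years.
#'
#' @param simulate a [gen_config()] object, or `NULL` when `paths` given.
#' @param paths named list of CSV paths (`roster`, `billing`, `links`,
#'   `survey`, `population`) when not simulating.
#' @param schedule age-activity schedule.
#' @param pcp_codes primary care specialty set.
#' @param hospitalist_threshold strict hospital E&M share threshold.
#' @param classifier a [classifier_config()].
#' @param multipliers `NULL` (derive) or named `c(np = , pa = )`.
#' @param baseline_year baseline year for the projection.
#' @param survey_year reference year for visit rates.
#' @param projection_years reporting years; default every fifth year of the
#'   population span.
#' @param order decomposition order.
#' @return object of class `pcw_pipeline_config`.
#' @export
pipeline_config <- function(simulate = gen_config(), paths = NULL,
                            schedule = default_activity_schedule(),
                            pcp_codes = pcp_specialties(),
                            hospitalist_threshold = 0.90,
                            classifier = classifier_config(),
                            multipliers = NULL,
                            baseline_year = 2020, survey_year = 2019,
                            projection_years = NULL,
                            order = "growth_first") {
  if (is.null(simulate) && is.null(paths)) {
    stop("either a 'simulate' generator config or input 'paths' is required")
  }
  if (!is.null(paths)) {
    need <- c("roster", "billing", "links", "survey", "population")
    miss <- setdiff(need, names(paths))
    if (length(miss)) {
      stop("missing input path(s): ", paste(miss, collapse = ", "))
    }
  }
  structure(list(simulate = simulate, paths = paths, schedule = schedule,
                 pcp_codes = pcp_codes,
                 hospitalist_threshold = hospitalist_threshold,
                 classifier = classifier, multipliers = multipliers,
                 baseline_year = baseline_year, survey_year = survey_year,
                 projection_years = projection_years, order = order),
            class = "pcw_pipeline_config")
}

.read_inputs <- function(paths) {
  read1 <- function(nm) {
    p <- paths[[nm]]
    if (!file.exists(p)) stop("missing input file for '", nm, "': ", p)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  list(roster = read1("roster"), billing = read1("billing"),
       links = read1("links"), survey = read1("survey"),
       population = read1("population"))
}

#' Run the full workforce accounting and projection pipeline
#'
#' Simulates (or reads) the five input tables, enumerates physicians,
#' classifies NPs/PAs, estimates survey-weighted visit rates and totals,
#' derives the visit multipliers, fits the need projection model and
#' assembles the five reporting tables plus a run manifest (config hash,
#' per-stage row counts, rule-firing tallies). Deterministic given the
#' generator seed.
#'
#' @param config a [pipeline_config()] (a bare [gen_config()] is accepted
#'   and wrapped with defaults).
#' @param outdir optional directory; when given, [write_tables()] is called.
#' @return object of class `pcw_run`: list with `tables` (table1..table5,
#'   rates), `attributions`, `shares`, `multipliers`, `model`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  if (inherits(config, "pcw_config")) config <- pipeline_config(config)
  stopifnot(inherits(config, "pcw_pipeline_config"))

  if (!is.null(config$paths)) {
    inputs <- .read_inputs(config$paths)
  } else {
    bundle <- simulate_bundle(config$simulate)
    inputs <- bundle[c("roster", "billing", "links", "survey", "population")]
  }

  table1 <- enumerate_physicians(inputs$roster, inputs$billing,
                                 schedule = config$schedule,
                                 pcp_codes = config$pcp_codes,
                                 threshold = config$hospitalist_threshold)
  attributions <- classify_np_pa(inputs$links, config$classifier)
  table2 <- enumerate_np_pa(attributions)
  shares <- office_and_pc_shares(attributions, inputs$links)
  multipliers <- config$multipliers
  if (is.null(multipliers)) {
    get_mult <- function(prof) {
      m <- shares$multiplier[shares$profession == prof]
      if (length(m) != 1 || is.na(m)) {
        stop("cannot derive visit multiplier for ", prof,
             "; supply 'multipliers' explicitly")
      }
      m
    }
    multipliers <- c(np = get_mult("NP"), pa = get_mult("PA"))
  }

  rates <- weighted_visit_rates(inputs$survey, year = config$survey_year)
  table3 <- visit_totals_by_year(inputs$survey, multipliers)
  table4 <- per_capita_rates(table3)
  pc_rates <- primary_care_rate_table(rates, multipliers)

  by <- config$baseline_year
  t1row <- table1[table1$year == by, , drop = FALSE]
  if (nrow(t1row) == 0) stop("baseline year ", by, " absent from roster data")
  np_pc <- table2$n_primary_care[table2$year == by & table2$profession == "NP"]
  pa_pc <- table2$n_primary_care[table2$year == by & table2$profession == "PA"]
  if (!length(np_pc) || !length(pa_pc)) {
    stop("baseline year ", by, " absent from NP/PA attribution data")
  }
  baseline <- baseline_provider_count(t1row$pcp_excl_hospitalists, np_pc,
                                      pa_pc)

  model <- pc_need_model(pc_rates, inputs$population, baseline,
                         baseline_year = by, order = config$order)
  proj_years <- config$projection_years
  if (is.null(proj_years)) {
    yrs <- sort(unique(inputs$population$year))
    proj_years <- yrs[(yrs - by) %% 5 == 0]
    if (length(proj_years) < 2) proj_years <- yrs
  }
  table5 <- predict(model, years = proj_years)

  manifest <- list(
    package_version = as.character(utils::packageVersion("pcworkforce")),
    config_hash = .config_hash(config),
    seed = if (!is.null(config$simulate)) config$simulate$seed else NA,
    rows = lapply(inputs, nrow),
    rule_firings = as.list(table(attributions$rule)),
    multipliers = as.list(multipliers),
    baseline_year = by,
    baseline_providers = baseline,
    visits_per_provider = model$vpp,
    decomposition_order = config$order
  )

  out <- structure(list(
    tables = list(table1 = table1, table2 = table2, table3 = table3,
                  table4 = table4, table5 = table5, rates = rates),
    attributions = attributions, shares = shares, multipliers = multipliers,
    model = model, manifest = manifest
  ), class = "pcw_run")
  if (!is.null(outdir)) write_tables(out, outdir)
  out
}

# hash the config by serialising to YAML and md5-summing the file; avoids a
# dependency on a dedicated hashing package
.config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  flat <- utils::capture.output(utils::str(config, give.attr = FALSE))
  writeLines(flat, f)
  unname(tools::md5sum(f))
}

#' @export
print.pcw_run <- function(x, ...) {
  cat("Primary care workforce pipeline run\n")
  cat(sprintf("  baseline (%s): %s providers\n", x$manifest$baseline_year,
              format(round_half_up(x$manifest$baseline_providers),
                     big.mark = ",")))
  cat(sprintf("  multipliers: np %.3f, pa %.3f\n", x$multipliers[["np"]],
              x$multipliers[["pa"]]))
  print(x$model)
  invisible(x)
}

#' Render run results as report-style tables
#'
#' Applies the reporting conventions: headcounts rounded to integers
#' (half-up), percents to one decimal, per-capita rates to two decimals;
#' the NP/PA table in wide All / Primary Care / Percent layout.
#'
#' @param run a [run_pipeline()] result.
#' @return named list of formatted data.frames.
#' @export
render_tables <- function(run) {
  stopifnot(inherits(run, "pcw_run"))
  tb <- run$tables
  t1 <- tb$table1
  for (col in c("all_age_adjusted", "pcp_age_adjusted", "hospitalists",
                "pcp_excl_hospitalists")) {
    t1[[col]] <- round_half_up(t1[[col]])
  }
  t1 <- t1[, c("year", "all_raw", "all_age_adjusted", "pcp_raw",
               "pcp_age_adjusted", "pcp_excl_hospitalists", "hospitalists")]

  t2l <- tb$table2
  yrs <- sort(unique(t2l$year))
  get <- function(yr, prof, col) {
    v <- t2l[[col]][t2l$year == yr & t2l$profession == prof]
    if (length(v)) v else NA_real_
  }
  t2 <- data.frame(
    year = yrs,
    np_all = vapply(yrs, get, numeric(1), prof = "NP", col = "n_all"),
    np_primary_care = round_half_up(
      vapply(yrs, get, numeric(1), prof = "NP", col = "n_primary_care")),
    np_percent = vapply(yrs, get, numeric(1), prof = "NP", col = "percent"),
    pa_all = vapply(yrs, get, numeric(1), prof = "PA", col = "n_all"),
    pa_primary_care = round_half_up(
      vapply(yrs, get, numeric(1), prof = "PA", col = "n_primary_care")),
    pa_percent = vapply(yrs, get, numeric(1), prof = "PA", col = "percent")
  )

  t3 <- tb$table3
  for (col in c("subspecialist_visits", "pcp_visits", "np_nurse_visits_adj",
                "pa_visits_adj", "total_primary_care_visits", "population")) {
    t3[[col]] <- round_half_up(t3[[col]])
  }

  t5 <- tb$table5
  for (col in c("baseline", "growth_effect", "aging_effect", "total_need",
                "needed_additional")) {
    t5[[col]] <- round_half_up(t5[[col]])
  }

  list(table1_physicians = t1, table2_np_pa = t2, table3_visit_totals = t3,
       table4_per_capita = as.data.frame(tb$table4),
       table5_projection = t5,
       rate_table = as.data.frame(tb$rates))
}

#' Write rendered tables and the run manifest to a directory
#'
#' CSVs are written with [utils::write.csv()] (RFC-4180 quoting, UTF-8); the
#' manifest goes to `manifest.yaml`. Re-running an identical configuration
#' reproduces byte-identical files.
#'
#' @param run a [run_pipeline()] result.
#' @param outdir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_tables <- function(run, outdir) {
  rendered <- render_tables(run)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(rendered)) {
    p <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(rendered[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  mp <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(run$manifest, mp)
  invisible(c(paths, mp))
}
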