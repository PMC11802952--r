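#' Baseline primary care provider count under the broad definition
#'
#' Primary care physicians excluding hospitalists, plus NPs and PAs
#' attributed to primary care.
#'
#' @param pcp_excl_hospitalists,np_primary_care,pa_primary_care component
#'   counts for the baseline year.
#' @return their sum.
#' @export
#' @examples
#' baseline_provider_count(236497, 73750, 32955)  # 343202
baseline_provider_count <- function(pcp_excl_hospitalists, np_primary_care,
                                    pa_primary_care) {
  comps <- c(pcp_excl_hospitalists, np_primary_care, pa_primary_care)
  if (length(comps) != 3 || any(is.na(comps))) {
    stop("all three baseline components must be present")
  }
  sum(comps)
}

#' Annual visits per primary care provider
#'
#' National annual visit total divided by the provider count — the
#' denominator converting projected visits into needed clinicians. Metadata
#' records the workforce definition and the (possibly different) numerator
#' and denominator years.
#'
#' @param total_visits annual national visit total (> 0).
#' @param provider_count provider headcount (> 0).
#' @param definition `"broad"` (PCPs + primary care NPs/PAs) or `"pcp"`.
#' @param numerator_year,denominator_year optional reference years.
#' @return object of class `pcw_vpp`: the ratio with metadata attributes.
#' @export
visits_per_provider <- function(total_visits, provider_count,
                                definition = c("broad", "pcp"),
                                numerator_year = NULL,
                                denominator_year = NULL) {
  definition <- match.arg(definition)
  if (total_visits <= 0) stop("total visits must be positive")
  if (provider_count <= 0) stop("provider count must be positive")
  structure(total_visits / provider_count, class = "pcw_vpp",
            definition = definition, numerator_year = numerator_year,
            denominator_year = denominator_year)
}

#' @export
print.pcw_vpp <- function(x, ...) {
  cat(sprintf("Visits per provider: %.1f (%s definition", unclass(x),
              attr(x, "definition")))
  ny <- attr(x, "numerator_year"); dy <- attr(x, "denominator_year")
  if (!is.null(ny) || !is.null(dy)) {
    cat(sprintf("; visits %s / providers %s",
                if (is.null(ny)) "?" else ny, if (is.null(dy)) "?" else dy))
  }
  cat(")\n")
  invisible(x)
}

# internal: validated rate lookup keyed by age_bin x sex
.rate_vector <- function(rates) {
  check_columns(rates, c("age_bin", "sex", "mean_visits"), "rates")
  if (any(is.na(rates$mean_visits))) {
    stop("rate grid contains missing cells; projection refuses incomplete grids")
  }
  stats::setNames(rates$mean_visits, paste(rates$age_bin, rates$sex))
}

#' Project total annual visits for one year
#'
#' Applies the age-sex visit rate grid to the projected population:
#' `sum(rate[bin, sex] * population[bin, sex, year])`.
#'
#' @param rates all-primary-care rate grid (`age_bin`, `sex`,
#'   `mean_visits`), complete and without missing cells.
#' @param population population table (`year`, `age_bin`, `sex`,
#'   `population`).
#' @param year projection year to evaluate.
#' @return total projected visits (numeric scalar).
#' @export
project_total_visits <- function(rates, population, year) {
  rv <- .rate_vector(rates)
  check_columns(population, c("year", "age_bin", "sex", "population"),
                "population")
  pop <- population[population$year == year, , drop = FALSE]
  if (nrow(pop) == 0) stop("population table has no rows for year ", year)
  keys <- paste(pop$age_bin, pop$sex)
  if (!all(keys %in% names(rv))) {
    stop("population contains cells absent from the rate grid")
  }
  sum(rv[keys] * pop$population)
}

#' Providers needed to deliver a visit total
#'
#' @param projected_visits total annual visits.
#' @param vpp visits per provider (a [visits_per_provider()] object or a
#'   positive number).
#' @return needed provider count (fractional; round only for reporting).
#' @export
providers_needed <- function(projected_visits, vpp) {
  v <- as.numeric(vpp)
  if (v <= 0) stop("visits per provider must be positive")
  projected_visits / v
}

#' Decompose incremental provider need into growth and aging effects
#'
#' Under the default `"growth_first"` order, the population-growth effect is
#' the extra need were the year-`year` total population to keep the baseline
#' age-sex composition — `baseline * (total_pop(year)/total_pop(baseline) -
#' 1)` — and the aging effect is the residual, so
#' `baseline + growth + aging = total need` exactly. `"aging_first"` holds
#' the total fixed at baseline while shifting to the year's composition, and
#' assigns the residual to growth.
#'
#' @param rates all-primary-care rate grid.
#' @param population population table covering both years.
#' @param baseline_year,year the two years compared.
#' @param baseline_providers baseline provider count.
#' @param order `"growth_first"` (default) or `"aging_first"`.
#' @return named numeric `c(growth = , aging = )`.
#' @export
decompose_need <- function(rates, population, baseline_year, year,
                           baseline_providers,
                           order = c("growth_first", "aging_first")) {
  order <- match.arg(order)
  v0 <- project_total_visits(rates, population, baseline_year)
  vt <- project_total_visits(rates, population, year)
  p0 <- sum(population$population[population$year == baseline_year])
  pt <- sum(population$population[population$year == year])
  if (p0 <= 0) stop("baseline population must be positive")
  total <- baseline_providers * vt / v0
  if (order == "growth_first") {
    growth <- baseline_providers * (pt / p0 - 1)
    aging <- total - baseline_providers - growth
  } else {
    aging <- baseline_providers * ((vt * p0 / pt) / v0 - 1)
    growth <- total - baseline_providers - aging
  }
  c(growth = growth, aging = aging)
}

#' Build the projected-need table
#'
#' One row per reporting year with the baseline provider count, the
#' population-growth and aging effects, the total projected need, and the
#' additional providers needed over baseline. Row identities
#' `total = baseline + growth + aging` and `needed = total - baseline` hold
#' exactly; the baseline-year row has zero effects.
#'
#' Total need scales the baseline by the ratio of projected to baseline-year
#' visits, which is equivalent to dividing projected visits by a
#' visits-per-provider denominator calibrated so that the baseline year
#' needs exactly the baseline workforce. Supplying `vpp` overrides that
#' calibration (e.g. a mixed-year statistic); additivity is then preserved
#' through the residual but the baseline-year row may show nonzero need.
#'
#' @param rates all-primary-care rate grid.
#' @param population population projection table.
#' @param baseline_providers baseline provider count.
#' @param years reporting years; default all years in `population`.
#' @param baseline_year default the earliest population year.
#' @param vpp optional visits-per-provider override.
#' @param order decomposition order, see [decompose_need()].
#' @return data.frame of class `pcw_table5`: `year`, `baseline`,
#'   `growth_effect`, `aging_effect`, `total_need`, `needed_additional`.
#' @export
build_projection_table <- function(rates, population, baseline_providers,
                                   years = NULL, baseline_year = NULL,
                                   vpp = NULL,
                                   order = c("growth_first", "aging_first")) {
  order <- match.arg(order)
  check_columns(population, c("year", "age_bin", "sex", "population"),
                "population")
  if (is.null(baseline_year)) baseline_year <- min(population$year)
  if (is.null(years)) years <- sort(unique(population$year))
  v0 <- project_total_visits(rates, population, baseline_year)
  p0 <- sum(population$population[population$year == baseline_year])
  vpp_cal <- if (is.null(vpp)) v0 / baseline_providers else as.numeric(vpp)

  rows <- lapply(years, function(t) {
    vt <- project_total_visits(rates, population, t)
    pt <- sum(population$population[population$year == t])
    total <- providers_needed(vt, vpp_cal)
    if (order == "growth_first") {
      growth <- baseline_providers * (pt / p0 - 1)
      aging <- total - baseline_providers - growth
    } else {
      aging <- baseline_providers * ((vt * p0 / pt) / v0 - 1)
      growth <- total - baseline_providers - aging
    }
    data.frame(year = t, baseline = baseline_providers,
               growth_effect = growth, aging_effect = aging,
               total_need = total,
               needed_additional = total - baseline_providers)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pcw_table5", "data.frame")
  attr(out, "baseline_year") <- baseline_year
  attr(out, "vpp") <- vpp_cal
  attr(out, "order") <- order
  out
}

#' Fit a primary care need projection model
#'
#' The package's central object: given an age-sex visit rate grid, a
#' population projection and a baseline provider count, computes total
#' projected visits per year, converts them to needed clinicians via a
#' visits-per-provider denominator, and decomposes incremental need into
#' population-growth and aging effects. Methods: `print`, `summary`, `coef`,
#' `predict` (need at new years or populations), `plot` (stacked effects).
#'
#' @param rates all-primary-care rate grid (`age_bin`, `sex`,
#'   `mean_visits`), e.g. from [primary_care_rate_table()].
#' @param population population projection (`year`, `age_bin`, `sex`,
#'   `population`).
#' @param baseline_providers baseline provider count (broad definition).
#' @param baseline_year default earliest population year.
#' @param vpp optional [visits_per_provider()] override; by default the
#'   denominator is calibrated so the baseline year needs exactly the
#'   baseline workforce.
#' @param order decomposition order, see [decompose_need()].
#' @return object of class `pc_need_model`.
#' @export
#' @examples
#' cfg <- gen_config(seed = 3, n_physicians = 200, n_nps = 80, n_pas = 40,
#'                   n_survey_persons = 2000)
#' pop <- gen_population_projection(cfg)
#' rates <- primary_care_rate_table(
#'   weighted_visit_rates(gen_visit_survey(cfg), year = 2019))
#' m <- pc_need_model(rates, pop, baseline_providers = 343202)
#' m
pc_need_model <- function(rates, population, baseline_providers,
                          baseline_year = NULL, vpp = NULL,
                          order = c("growth_first", "aging_first")) {
  order <- match.arg(order)
  if (baseline_providers <= 0) stop("baseline provider count must be positive")
  if (is.null(baseline_year)) baseline_year <- min(population$year)
  proj <- build_projection_table(rates, population, baseline_providers,
                                 baseline_year = baseline_year, vpp = vpp,
                                 order = order)
  structure(list(rates = rates, population = population,
                 baseline_providers = baseline_providers,
                 baseline_year = baseline_year,
                 vpp = attr(proj, "vpp"), order = order,
                 projection = proj),
            class = "pc_need_model")
}

#' @export
print.pc_need_model <- function(x, ...) {
  cat("Primary care need projection model\n")
  cat(sprintf("  baseline (%d): %s providers | visits/provider: %.1f\n",
              x$baseline_year, format(round_half_up(x$baseline_providers),
                                      big.mark = ","), x$vpp))
  last <- x$projection[nrow(x$projection), ]
  cat(sprintf("  horizon %d: total need %s (+%s)\n", last$year,
              format(round_half_up(last$total_need), big.mark = ","),
              format(round_half_up(last$needed_additional), big.mark = ",")))
  invisible(x)
}

#' @export
coef.pc_need_model <- function(object, ...) {
  c(baseline_providers = object$baseline_providers,
    visits_per_provider = object$vpp)
}

#' Predict projected need for given years
#'
#' @param object a [pc_need_model()].
#' @param years years to report; default the model's population years.
#' @param newdata optional replacement population table (same columns).
#' @param ... unused.
#' @return a `pcw_table5` projection table.
#' @export
predict.pc_need_model <- function(object, years = NULL, newdata = NULL, ...) {
  pop <- if (is.null(newdata)) object$population else newdata
  build_projection_table(object$rates, pop, object$baseline_providers,
                         years = years, baseline_year = object$baseline_year,
                         vpp = object$vpp, order = object$order)
}

#' @export
summary.pc_need_model <- function(object, years = NULL, ...) {
  yrs <- sort(unique(object$population$year))
  if (is.null(years)) {
    step <- yrs[(yrs - object$baseline_year) %% 5 == 0]
    years <- if (length(step) > 1) step else yrs
  }
  out <- list(model = object,
              table = predict(object, years = years))
  class(out) <- "summary.pc_need_model"
  out
}

#' @export
print.summary.pc_need_model <- function(x, ...) {
  print(x$model)
  tb <- x$table
  for (col in c("baseline", "growth_effect", "aging_effect", "total_need",
                "needed_additional")) {
    tb[[col]] <- round_half_up(tb[[col]])
  }
  cat("\nProjected need by year (growth/aging decomposition):\n")
  print.data.frame(tb, row.names = FALSE)
  invisible(x)
}

#' Plot the growth/aging decomposition of projected need
#'
#' Stacked area chart: baseline workforce, plus the population-growth and
#' aging contributions to projected need by year.
#'
#' @param x a [pc_need_model()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.pc_need_model <- function(x, ...) {
  tb <- x$projection
  yr <- tb$year
  top <- tb$total_need
  mid <- tb$baseline + tb$growth_effect
  graphics::plot(yr, top, type = "n", xlab = "Year",
                 ylab = "Primary care clinicians needed",
                 ylim = c(min(tb$baseline) * 0.95, max(top) * 1.02), ...)
  graphics::polygon(c(yr, rev(yr)), c(rep(min(tb$baseline) * 0.95,
                                          length(yr)), rev(tb$baseline)),
                    col = "grey90", border = NA)
  graphics::polygon(c(yr, rev(yr)), c(tb$baseline, rev(mid)),
                    col = "grey70", border = NA)
  graphics::polygon(c(yr, rev(yr)), c(mid, rev(top)),
                    col = "grey40", border = NA)
  graphics::lines(yr, top, lwd = 2)
  graphics::legend("topleft", bty = "n", fill = c("grey90", "grey70", "grey40"),
                   legend = c("Baseline", "Population growth", "Aging"))
  invisible(x)
}
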