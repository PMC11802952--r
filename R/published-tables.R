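#' Published US national summary tables
#'
#' Loads the published 2010-2040 US national primary care workforce and visit
#' summary tables bundled with the package: physician trend counts with
#' age-activity adjustment and hospitalist exclusion (2012-2020), NP/PA
#' primary care counts (2016-2020), office-based visit totals and per-capita
#' rates by provider type (2010-2019), and the projected-need decomposition
#' (2020-2040). These are printed aggregate estimates, used in tests and
#' examples to verify the package's accounting identities; the underlying
#' microdata are restricted and are emulated by the synthetic module instead.
#'
#' @param which one of `"physicians"`, `"np_pa"`, `"visit_totals"`,
#'   `"per_capita"`, `"projection"`.
#' @return the requested table as a data.frame.
#' @export
#' @examples
#' t5 <- published_tables("projection")
#' all(t5$total_need == t5$baseline + t5$growth_effect + t5$aging_effect)
published_tables <- function(which = c("physicians", "np_pa", "visit_totals",
                                       "per_capita", "projection")) {
  which <- match.arg(which)
  file <- switch(which,
    physicians = "us_physician_trends_2012_2020.csv",
    np_pa = "us_np_pa_primary_care_2016_2020.csv",
    visit_totals = "us_visit_totals_2010_2019.csv",
    per_capita = "us_visits_per_capita_2010_2019.csv",
    projection = "us_projected_need_2020_2040.csv"
  )
  path <- system.file("extdata", file, package = "pcworkforce")
  if (path == "") stop("bundled table not found: ", file)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
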