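Package: pcworkforce
Title: Primary Care Workforce Accounting and Need Projection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for utilization-based primary care workforce analysis:
    enumeration of primary care physicians from provider rosters with
    age-activity adjustment and hospitalist exclusion, rule-based attribution
    of nurse practitioners and physician assistants to primary care from
    practice-linkage data, survey-weighted estimation of annual visit rates by
    age and sex, and projection of needed clinicians under population growth
    and aging with an exact growth/aging decomposition. Includes a synthetic
    microdata generator emulating the provider roster, billing, practice
    linkage, visit survey, and population projection sources so the full
    pipeline runs and is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
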