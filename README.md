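# pcworkforce

Utilization-based primary care workforce accounting and need projection for
the United States, 2020–2040.

Health workforce planners and researchers need to answer a deceptively
simple question: given how often people of each age and sex visit primary
care, how many clinicians does a growing and aging population require?
`pcworkforce` implements the full accounting pipeline behind that answer:

* **Physician census** — count primary care physicians (PCPs, the six
  generalist specialties) from a provider roster, down-weighting by an
  age-declining probability of active practice and excluding hospitalists
  (physicians billing > 90% of evaluation & management services from a
  hospital).
* **NP/PA attribution** — classify nurse practitioners and physician
  assistants into primary care from practice-linkage data via six explicit
  rules (facility type, practice composition, setting of care), with
  fractional attribution in multi-specialty practices.
* **Visit rates** — survey-weighted mean annual visits per person by age
  bin × sex × provider type, zero-visit persons included, with NP/PA visit
  counts scaled to primary care by multipliers derived from the attribution
  stage.
* **Need projection** — apply the rates to projected populations and
  convert visits to clinicians. For baseline workforce *B*, rate grid
  *r(a,s)* and populations *P_t(a,s)*:

  N_t = B · V_t / V_0,  where V_t = Σ_{a,s} r(a,s) P_t(a,s),

  with the increase decomposed exactly into a population-growth effect
  G_t = B·(ΣP_t/ΣP_0 − 1) and an aging effect A_t = N_t − B − G_t.

* **Synthetic data** — a generator emulating all five restricted national
  sources (roster, billing, practice linkage, visit survey, population
  projection) with known ground truth, so the whole pipeline runs and is
  testable without licensed microdata.

The published national figures this accounting reproduces — a 2020 baseline
of 343,202 primary care clinicians (236,497 PCPs excluding hospitalists +
73,750 NPs + 32,955 PAs) growing to a projected need of 400,761 by 2040, an
additional 57,559 clinicians — are bundled as reference tables
(`published_tables()`) and verified in the test suite through the package's
own operations.

## Worked example

```r
library(pcworkforce)
run <- run_pipeline(pipeline_config(gen_config(seed = 1)))
summary(run$model)
#> Primary care need projection model
#>   baseline (2020): 7,875 providers | visits/provider: 79705.1
#>   horizon 2040: total need 9,416 (+1,542)
#>
#> Projected need by year (growth/aging decomposition):
#>  year baseline growth_effect aging_effect total_need needed_additional
#>  2020     7875             0            0       7875                 0
#>  2025     7875           248          126       8249               374
#>  2030     7875           496          259       8630               755
#>  2035     7875           744          400       9020              1145
#>  2040     7875           992          549       9416              1542
```

This simulates a scaled-down study population (20,000 physicians, 6,000
NPs, 3,000 PAs, 20,000 survey respondents; roughly 1/40 of national
headcounts), enumerates 7,875 baseline primary care providers, and projects
a need of 9,416 by 2040 under +12.6% population growth and an aging shift —
an increase of 1,542 (19.6%), of which 992 (64%) is attributable to
population growth and 549 to aging. Row identities
(`total = baseline + growth + aging`, `needed = total − baseline`) hold
exactly; the baseline-year row shows zero effects by construction.

The fitted `pc_need_model` object supports `print`, `summary`, `coef`,
`predict` (new years or counterfactual populations) and `plot` (stacked
growth/aging decomposition). Individual stages are exported
(`enumerate_physicians()`, `classify_np_pa()`, `enumerate_np_pa()`,
`weighted_visit_rates()`, `visit_totals_by_year()`,
`build_projection_table()`, …) and accept plain data frames / CSVs, so real
microdata can replace the synthetic bundle through the same interfaces.

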