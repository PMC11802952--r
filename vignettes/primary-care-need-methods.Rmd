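---
title: "Methods: primary care workforce accounting and need projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: primary care workforce accounting and need projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcworkforce)
```

## The problem

How many primary care clinicians will the United States need by 2040?
`pcworkforce` implements a utilization-based accounting answer in four
stages, plus a synthetic microdata generator that emulates the five
restricted national data sources the real analysis rests on (a proprietary
physician roster, Medicare enrollment/billing linkages, a person-level visit
survey, and census population projections), so the entire pipeline runs,
and is testable, without any licensed data.

The accounting logic is:

1. **Supply.** Count primary care physicians (PCPs) active in ambulatory
   care, and add nurse practitioners (NPs) and physician assistants (PAs)
   attributed to primary care — the *broad* workforce definition.
2. **Demand.** Estimate mean annual primary care visits per person by age
   bin and sex from a weighted survey, and apply those rates to projected
   populations to get total annual visits per future year.
3. **Conversion.** Divide projected visits by annual visits per provider to
   get the clinicians needed, and decompose the increase over baseline into
   a population-growth effect and an aging effect.

## Physician enumeration

Physicians whose specialty is one of the six generalist categories
(`pcp_specialties()`) count as PCPs. Two corrections follow:

* **Age-activity adjustment.** Rosters overcount retirees, so each head is
  down-weighted by an age-declining probability of active direct patient
  care. The schedule is a required input. The package default
  (`default_activity_schedule()`: 1.00 below 55, stepping by decade through
  0.75, 0.50, 0.25 to 0 at 85) is a documented stand-in, *not* an
  empirically estimated schedule; substantive analyses should supply their
  own. Adjusted counts are expected values and therefore fractional;
  rounding (half-up, matching printed tables) happens only at report time.
* **Hospitalist exclusion.** A PCP billing strictly more than 90% of
  evaluation & management (E&M) services with a hospital place of service is
  a hospitalist and leaves the ambulatory count. "More than" is taken
  literally: a 90.0% share is not flagged. Zero-E&M profiles are
  indeterminate — left unflagged and reported via an attribute rather than
  silently dropped.

`enumerate_physicians()` emits, per year, the raw and adjusted counts for
all physicians and PCPs, the hospitalist count (age-adjusted, among PCPs),
and the exclusion-adjusted PCP count; the identity
`pcp_excl_hospitalists = pcp_age_adjusted - hospitalists` holds exactly for
every row.

## NP/PA attribution from practice linkage

No national roster identifies primary care NPs/PAs, so attribution is
inferred from the organisation each provider bills through. Six assumptions
drive `classify_np_pa()`; because no precedence among them is published, the
package orders them explicitly and configurably, applying administrative
facility designations before inferential composition rules:

1. *Setting override*: providers primarily working in hospital, emergency
   department, nursing home, assisted living or home health settings are
   not primary care (strictly more than a configurable majority threshold,
   default 0.5, of their services).
2. *Rule 3*: rural health clinic (RHC) and federally qualified health
   center (FQHC) staff are primary care.
3. *Rule 5*: retail clinics, critical access hospitals and skilled nursing
   facilities are not.
4. *Rule 4*: organisations dominated by social workers and psychologists
   (same majority threshold) are not.
5. *Rules 1–2*: in physician practices the primary care fraction equals
   the PCP share of the practice's physicians — zero when there are no
   PCPs, fractional in multi-specialty practices.
6. *Rule 6*: solo organisations with no physicians or other clinicians are
   primary care.

The first rule that fires decides, and its label is recorded, so rule-firing
tallies are auditable in the run manifest. Attribution is *fractional by
design* (expected counts): a PA in a practice with 3 PCPs among 12
physicians contributes 0.25 of a primary care PA. This reproduces published
aggregate percents deterministically; a probabilistic assignment mode was
deliberately not made the default because it adds variance without changing
expectations. Providers linked to several organisations attribute through
the largest service share (ties: higher primary care fraction).

`office_and_pc_shares()` estimates, per profession, the share working
predominantly in an office setting and, among those, the mean primary care
fraction. The latter is the **visit multiplier**: survey visit counts to the
combined nurse/NP category and to PAs are scaled by it (published values
0.456 and 0.358) because the survey cannot tell primary care visits from
other visits to those provider types, and nurse visits are not separable
from NP visits at all — the package applies the multiplier to the combined
category and makes no attempt to split it.

## Survey-weighted visit rates

`weighted_visit_rates()` computes, for each age bin × sex × provider type
cell, `sum(weight * visits) / sum(weight)` over the full sample *including
zero-visit persons*. Age bins are 0–4, 5–13, 14–17, 18–24, 25–44, 45–64,
65–84, 85+, implemented half-open (`[65, 85)`, `[85, Inf)`) so ages
partition cleanly; the printed convention "65–85" is interpreted as
`[65, 85)`. The estimator is invariant to weight rescaling, and per-capita
rates (totals divided by the weight sum) coincide with the weighted means by
construction. Empty cells propagate as missing and the projection refuses
incomplete grids rather than imputing. No complex-survey design-effect
variance estimation is attempted — the package reports point estimates, and
its tests use linearised weighted standard errors only to check estimator
calibration on synthetic data.

A survey year affected by known data inconsistencies (e.g. a pandemic year)
is handled by simply not passing it as the reference year; the package
applies no special-casing.

## The need projection model

`pc_need_model()` is the package's central object. Given the combined
primary-care rate grid `r(a, s)` (PCP + multiplier-adjusted NP and PA
rates), a population projection `P_t(a, s)` and a baseline workforce `B`
(PCPs excluding hospitalists + primary care NPs + primary care PAs):

* projected visits: `V_t = sum_{a,s} r(a,s) * P_t(a,s)`;
* total need: `N_t = V_t / vpp`, with the visits-per-provider denominator
  `vpp` calibrated by default to `V_0 / B` so the baseline year needs
  exactly the baseline workforce (equivalently `N_t = B * V_t / V_0`);
* growth effect: `G_t = B * (sum P_t / sum P_0 - 1)` — the need increase
  were the future total population to keep the baseline age–sex
  composition;
* aging effect: `A_t = N_t - B - G_t`, the residual.

Additivity `N_t = B + G_t + A_t` and `needed = N_t - B` are exact by
construction, pure-growth scenarios give a zero aging effect, and need is
linear in visits (the ratio identity `N_t / B = V_t / V_0`). The
decomposition formula is a package design choice — the published account
shows the split only graphically — and the opposite convention
(aging-first, growth as residual) is available via `order = "aging_first"`
for sensitivity; the two agree on the total by construction.

The published statistic divides a 2019 visit total by a 2020 baseline
workforce; `visits_per_provider()` reproduces that mixed-year number with
metadata, and it can be passed to `build_projection_table()` explicitly. The
self-calibrated denominator remains the default because it is the only
convention under which the baseline-year row shows zero effects exactly,
which the published projection table itself satisfies.

## The synthetic generator: what it emulates, and what it does not

No distributional forms are published for any source, so the generator's
distributions are stand-ins chosen to make every downstream stage testable
with known truth:

* Visit counts are **Poisson** with cell-specific means — the simplest
  count model consistent with estimating cell means. The estimator uses
  only weighted means, so nothing downstream depends on this choice.
* Survey weights are **log-normal** noise (sd log 0.5) around
  `population / n`, so weighted and unweighted estimates differ and the
  weighting code is genuinely exercised, while the weight total still
  estimates the population.
* The default rate surface is U-shaped in age for PCP visits, with boys
  slightly above girls through 13 and women above men from 18–64, matching
  the qualitative published pattern; levels put the overall PCP mean near
  1.6 visits/person/year.
* Hospitalist billing shares are drawn strictly above 0.92 for generated
  hospitalists and at or below 0.60 otherwise, so the >0.90 flag recovers
  the truth set *exactly* — the generator brackets the threshold instead of
  straddling it.
* NP/PA organisations are built mechanism-first: the intended primary care
  status is drawn, then an organisation consistent with it is constructed
  (FQHC/RHC, PCP-only, solo, multi-specialty with a symmetric-binomial PCP
  share whose truncation to 1..n−1 preserves the mean of 1/2, no-PCP,
  retail/SNF/critical-access, behavioral-health, or non-office settings).
  All intended primary care providers are office-based, so the overall
  primary care share, the office share, and the primary-care-among-office
  share are linked: `pc_among_office = pc_share / office_share`. One tenth
  of non-office providers sit in FQHCs specifically to exercise the
  setting-override precedence.
* The population projection is **exact**: totals follow the configured
  growth path to machine precision and bin shares interpolate linearly
  toward a 2040 target composition (65+ near 23%), scaled by
  `aging_strength`; within-bin sex splits stay at baseline. Default growth
  reaches +12.6% by 2040, in line with census projections.

Defaults elsewhere mirror published 2020 aggregates: PCP specialty share
0.345, hospitalist share 0.14, NP/PA primary care shares 0.321/0.275,
office shares 0.815/0.853. Default problem sizes (20,000 physicians, 6,000
NPs, 3,000 PAs, 20,000 survey persons per year) are scaled-down study
populations chosen so parameter-recovery tests have tight binomial standard
errors while the full pipeline remains quick to run; they are package
choices, roughly 1/40 of the national headcounts.

Passing tests on synthetic data therefore demonstrate *accounting
correctness and estimator calibration* — identities that hold exactly, and
parameters recovered within sampling error. They do not validate the
stand-in distributions against real rosters or surveys, nor the published
activity schedule, multipliers, or census projections themselves; with real
microdata those inputs replace the synthetic ones unchanged through the
same CSV interfaces.

## Numerical conventions and degenerate inputs

* All intermediate arithmetic is double precision; rounding is applied only
  by the report renderer — headcounts to integers, per-capita rates to two
  decimals, percents to one decimal, all half-up (`round_half_up()`),
  matching printed-table conventions. Rounding columns independently can
  leave a rendered row off its identity by one unit; the unrounded tables
  satisfy the identities to machine precision.
* Strictness: the hospitalist rule and both "primarily"/"dominance"
  thresholds use strict `>`.
* Zero-total E&M profiles: indeterminate, unflagged, reported.
* Professions with no office-based providers: office share 0, multiplier
  undefined, flagged `degenerate`; the pipeline stops with an instruction
  to supply multipliers explicitly.
* Empty rate cells: `NA`, and `project_total_visits()` errors on incomplete
  grids.
* Generated E&M counts are large enough (≥ 200) that rounding the hospital
  count cannot move a share across the 0.90 threshold.

## Reproducibility

Every generator stage seeds its own RNG stream from `config$seed` plus a
fixed offset, so stages are individually deterministic and bundles are
byte-identical across runs and across call orders. `run_pipeline()` writes a
manifest (config hash, per-stage row counts, rule-firing tallies,
multipliers, baseline, visits-per-provider) alongside the rendered tables;
identical configurations reproduce bit-identical CSVs.

```{r example, eval = FALSE}
run <- run_pipeline(pipeline_config(gen_config(seed = 1)))
summary(run$model)
plot(run$model)
```

## Known limitations

* The classifier's rule precedence and majority thresholds are package
  decisions surfaced as configuration, because the six assumptions are
  published without conflict-resolution rules.
* No geographic stratification, no DO/MD distinction, no state
  scope-of-practice modelling, no panel-size or retirement scenarios, and
  no insurance-expansion demand scenarios.
* The age-activity schedule default is illustrative; results are sensitive
  to it in the oldest bands.
* Respondent misclassification of provider types in visit surveys is not
  corrected; the NP/nurse category is handled only through the multiplier.
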