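test_that("generator configuration validates its invariants", {
  expect_s3_class(gen_config(), "pcw_config")
  expect_error(gen_config(np_pc_share = 1.2), "in \\[0, 1\\]")
  expect_error(gen_config(n_physicians = -5), "non-negative integer")
  expect_error(gen_config(np_pc_share = 0.9, np_office_share = 0.8),
               "must not exceed")
  bad_ages <- c("30" = 0.6, "40" = 0.6)
  expect_error(gen_config(age_distribution = bad_ages), "summing to 1")
  rp <- default_visit_rate_params()
  expect_error(gen_config(visit_rate_params = rp[-1, ]), "every")
  rp2 <- rp; rp2$mean[1] <- -1
  expect_error(gen_config(visit_rate_params = rp2), "non-negative")
})

test_that("roster generation is deterministic, honours empty and share configs", {
  cfg <- small_config()
  r1 <- gen_provider_roster(cfg)
  r2 <- gen_provider_roster(cfg)
  expect_identical(r1, r2)

  r0 <- gen_provider_roster(small_config(n_physicians = 0))
  expect_equal(sum(r0$profession == "physician"), 0)
  expect_equal(sum(r0$profession == "NP"), 600)

  # PCP specialty share within 3 binomial s.e. of the configured value
  cfg_big <- gen_config(seed = 7, n_physicians = 10000, n_nps = 10, n_pas = 10,
                        pcp_specialty_share = 0.35)
  r <- gen_provider_roster(cfg_big)
  phys <- r[r$profession == "physician", ]
  share <- mean(classify_pcp_specialty(phys))
  expect_lt(abs(share - 0.35), 3 * binom_se(0.35, 10000))
})

test_that("billing generation brackets the hospitalist threshold strictly", {
  cfg0 <- small_config(hospitalist_share = 0)
  r <- gen_provider_roster(cfg0)
  b0 <- gen_billing_profiles(r, cfg0)
  shares <- b0$billing$em_hospital /
    (b0$billing$em_hospital + b0$billing$em_office + b0$billing$em_other)
  expect_true(all(shares <= 0.90))
  expect_length(b0$hospitalist_ids, 0)

  cfg1 <- small_config(hospitalist_share = 1)
  b1 <- gen_billing_profiles(gen_provider_roster(cfg1), cfg1)
  flagged <- flag_hospitalist(b1$billing$em_hospital, b1$billing$em_office,
                              b1$billing$em_other)
  keys <- paste(b1$billing$provider_id, b1$billing$year, sep = ":")
  expect_setequal(keys[flagged], b1$hospitalist_ids)

  # share parameter recovered by downstream flagging at n = 5000 PCPs
  cfg <- gen_config(seed = 11, n_physicians = 5000, n_nps = 10, n_pas = 10,
                    pcp_specialty_share = 1, hospitalist_share = 0.15)
  roster <- gen_provider_roster(cfg)
  b <- gen_billing_profiles(roster, cfg)
  f <- flag_hospitalist(b$billing$em_hospital, b$billing$em_office,
                        b$billing$em_other)
  expect_lt(abs(mean(f) - 0.15), 3 * binom_se(0.15, 5000))
})

test_that("practice links force rules and embed recoverable shares", {
  # all NPs in FQHCs: truth marks them all primary care
  r <- gen_provider_roster(small_config())
  cfg_all_pc <- small_config(np_pc_share = 1, np_office_share = 1,
                             pa_pc_share = 1, pa_office_share = 1,
                             multispecialty_share = 0)
  lk <- gen_practice_links(r, cfg_all_pc)
  expect_true(all(lk$truth$pc_fraction_truth == 1))

  cfg_none <- small_config(np_pc_share = 0, pa_pc_share = 0,
                           multispecialty_share = 0)
  lk0 <- gen_practice_links(r, cfg_none)
  expect_true(all(lk0$truth$pc_fraction_truth == 0))

  # links reference roster ids
  lk2 <- gen_practice_links(r, small_config())
  expect_true(all(lk2$links$provider_id %in% r$provider_id))
})

test_that("visit survey draws match configured cell means and include zeros", {
  rp <- default_visit_rate_params()
  rp$mean <- 0
  cfg0 <- small_config(visit_rate_params = rp)
  s0 <- gen_visit_survey(cfg0)
  expect_true(all(s0$visits_pcp == 0) && all(s0$visits_pa == 0))

  # equal weights, constant mean 2.0: weighted mean within 3 Poisson s.e.
  rp2 <- default_visit_rate_params()
  rp2$mean <- 2
  cfg <- gen_config(seed = 5, n_survey_persons = 20000, weight_sdlog = 0,
                    visit_rate_params = rp2)
  s <- gen_visit_survey(cfg)
  m <- sum(s$weight * s$visits_pcp) / sum(s$weight)
  expect_lt(abs(m - 2), 3 * sqrt(2 / 20000))
  expect_gt(sum(s$visits_pcp == 0), 0)
  expect_true(all(s$weight > 0))
})

test_that("estimated PCP rate profile is U-shaped under the default config", {
  cfg <- gen_config(seed = 9, n_survey_persons = 40000)
  s <- gen_visit_survey(cfg)
  r <- weighted_visit_rates(s, year = 2019, types = "pcp")
  prof <- tapply(r$mean_visits, r$age_bin, mean)[age_bins()$labels]
  mid <- mean(prof[c("18-24", "25-44")])
  expect_gt(prof[["0-4"]], mid)
  expect_gt(prof[["85+"]], mid)
  expect_gt(prof[["85+"]], prof[["45-64"]])
})

test_that("population projection honours growth, aging and conservation", {
  labs <- age_bins()$labels
  yrs <- 2020:2025
  growth <- stats::setNames(rep(1.1, length(yrs)), yrs)
  growth[["2020"]] <- 1
  cfg_g <- small_config(projection_years = yrs, growth_path = growth,
                        aging_strength = 0)
  pop <- gen_population_projection(cfg_g)
  base <- pop[pop$year == 2020, ]
  p25 <- pop[pop$year == 2025, ]
  key <- function(d) paste(d$age_bin, d$sex)
  expect_equal(p25$population[order(key(p25))],
               1.1 * base$population[order(key(base))], tolerance = 1e-12)

  # pure aging conserves yearly totals exactly
  cfg_a <- small_config(projection_years = yrs,
                        growth_path = stats::setNames(rep(1, length(yrs)), yrs),
                        aging_strength = 1)
  pop_a <- gen_population_projection(cfg_a)
  totals <- tapply(pop_a$population, pop_a$year, sum)
  expect_equal(as.vector(totals), rep(sum(base$population), length(yrs)),
               tolerance = 1e-12)
  # but the composition shifts older
  old0 <- sum(pop_a$population[pop_a$year == 2020 &
                                 pop_a$age_bin %in% c("65-84", "85+")])
  old1 <- sum(pop_a$population[pop_a$year == 2025 &
                                 pop_a$age_bin %in% c("65-84", "85+")])
  expect_gt(old1, old0)

  # mixed scenario: totals follow the configured growth path exactly
  g2 <- stats::setNames(seq(1, 1.2, length.out = length(yrs)), yrs)
  cfg_m <- small_config(projection_years = yrs, growth_path = g2,
                        aging_strength = 0.5)
  pop_m <- gen_population_projection(cfg_m)
  tm <- tapply(pop_m$population, pop_m$year, sum)
  expect_equal(as.vector(tm), unname(sum(base$population) * g2),
               tolerance = 1e-12)

  expect_error(small_config(projection_years = yrs,
                            growth_path = stats::setNames(c(-1, rep(1, 5)),
                                                          yrs)),
               "positive")
})

test_that("identical seed and config give identical bundles", {
  b1 <- simulate_bundle(small_config(seed = 77))
  b2 <- simulate_bundle(small_config(seed = 77))
  expect_identical(b1$roster, b2$roster)
  expect_identical(b1$billing, b2$billing)
  expect_identical(b1$links, b2$links)
  expect_identical(b1$survey, b2$survey)
  expect_identical(b1$population, b2$population)
  expect_identical(b1$truth$hospitalist_ids, b2$truth$hospitalist_ids)

  b3 <- simulate_bundle(small_config(seed = 78))
  expect_false(identical(b1$roster, b3$roster))
})

test_that("bundle tables are internally consistent and truth is separate", {
  b <- simulate_bundle(small_config())
  expect_true(all(b$billing$provider_id %in% b$roster$provider_id))
  expect_true(all(b$links$provider_id %in% b$roster$provider_id))
  expect_true(all(b$survey$weight > 0))
  expect_true(all(b$population$population >= 0))
  expect_false("pc_fraction_truth" %in%
                 unlist(lapply(b[c("roster", "billing", "links", "survey")],
                               names)))
})

test_that("write_bundle round-trips tables through CSV", {
  d <- withr::local_tempdir()
  b <- simulate_bundle(small_config(n_physicians = 100, n_nps = 50,
                                    n_pas = 20, n_survey_persons = 100))
  paths <- write_bundle(b, d)
  expect_true(all(file.exists(paths)))
  roster2 <- read.csv(file.path(d, "roster.csv"), stringsAsFactors = FALSE)
  expect_equal(nrow(roster2), nrow(b$roster))
  expect_equal(roster2$provider_id, b$roster$provider_id)
})
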