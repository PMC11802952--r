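# small rate grid + population fixture used across projection tests
proj_fixture <- function(seed = 1, years = c(2020, 2030)) {
  set.seed(seed)
  grid <- expand.grid(age_bin = age_bins()$labels,
                      sex = c("female", "male"), stringsAsFactors = FALSE)
  rates <- data.frame(grid, mean_visits = runif(nrow(grid), 0.5, 4))
  pop <- do.call(rbind, lapply(years, function(y) {
    data.frame(year = y, grid,
               population = runif(nrow(grid), 1e5, 5e6))
  }))
  list(rates = rates, pop = pop)
}

test_that("baseline provider count is the three-way sum", {
  expect_equal(baseline_provider_count(236497, 73750, 32955), 343202)
  expect_equal(baseline_provider_count(0, 10, 5), 15)
  expect_error(baseline_provider_count(NA, 10, 5), "must be present")
})

test_that("visits per provider is a homogeneous ratio with metadata", {
  v <- visits_per_provider(1000, 10)
  expect_equal(as.numeric(v), 100)
  expect_equal(as.numeric(visits_per_provider(2000, 20)), 100)
  # mixed-year broad-definition statistic
  v2 <- visits_per_provider(605693149, 343202, definition = "broad",
                            numerator_year = 2019, denominator_year = 2020)
  expect_equal(as.numeric(v2), 605693149 / 343202)
  expect_equal(attr(v2, "definition"), "broad")
  expect_error(visits_per_provider(0, 10), "positive")
  expect_error(visits_per_provider(10, 0), "positive")
})

test_that("projected visits equal the brute-force rate x population sum", {
  fx <- proj_fixture()
  v <- project_total_visits(fx$rates, fx$pop, 2030)
  pop30 <- fx$pop[fx$pop$year == 2030, ]
  oracle <- 0
  for (i in seq_len(nrow(pop30))) {
    r <- fx$rates$mean_visits[fx$rates$age_bin == pop30$age_bin[i] &
                                fx$rates$sex == pop30$sex[i]]
    oracle <- oracle + r * pop30$population[i]
  }
  expect_equal(v, oracle)

  zero <- fx$rates; zero$mean_visits <- 0
  expect_equal(project_total_visits(zero, fx$pop, 2030), 0)

  na_rates <- fx$rates; na_rates$mean_visits[3] <- NA
  expect_error(project_total_visits(na_rates, fx$pop, 2030), "incomplete")
  expect_error(project_total_visits(fx$rates, fx$pop, 2050), "no rows")
})

test_that("providers_needed is linear in visits", {
  expect_equal(providers_needed(1000, 100), 10)
  expect_equal(providers_needed(1100, 100), 11)
  v <- visits_per_provider(500, 5)
  expect_equal(providers_needed(1000, v), 10)
})

test_that("decomposition isolates growth and aging scenarios", {
  fx <- proj_fixture()
  pop <- fx$pop[fx$pop$year == 2020, ]
  base <- 1000

  # identical populations: both effects zero
  pop_id <- rbind(pop, transform(pop, year = 2030))
  d <- decompose_need(fx$rates, pop_id, 2020, 2030, base)
  expect_equal(unname(d), c(0, 0), tolerance = 1e-10)

  # uniform x1.2 scaling: growth = 0.2 x baseline, aging = 0
  pop_g <- rbind(pop, transform(pop, year = 2030, population = 1.2 * population))
  d <- decompose_need(fx$rates, pop_g, 2020, 2030, base)
  expect_equal(d[["growth"]], 0.2 * base, tolerance = 1e-10)
  expect_equal(d[["aging"]], 0, tolerance = 1e-10)

  # structure shift at fixed total: growth = 0, aging = total change
  shift <- pop
  tot <- sum(shift$population)
  w <- rev(seq_len(nrow(shift)))
  shift$population <- tot * w / sum(w)
  pop_a <- rbind(pop, transform(shift, year = 2030))
  d <- decompose_need(fx$rates, pop_a, 2020, 2030, base)
  expect_equal(d[["growth"]], 0, tolerance = 1e-10)
  v0 <- project_total_visits(fx$rates, pop_a, 2020)
  vt <- project_total_visits(fx$rates, pop_a, 2030)
  expect_equal(d[["aging"]], base * (vt / v0 - 1), tolerance = 1e-10)

  # aging-first ordering also sums to the same total
  d2 <- decompose_need(fx$rates, pop_a, 2020, 2030, base,
                       order = "aging_first")
  expect_equal(sum(d2), sum(d), tolerance = 1e-10)
})

test_that("projection table satisfies the exact row identities", {
  fx <- proj_fixture(seed = 3, years = c(2020, 2025, 2030, 2035, 2040))
  tb <- build_projection_table(fx$rates, fx$pop, baseline_providers = 343202)
  expect_equal(tb$total_need,
               tb$baseline + tb$growth_effect + tb$aging_effect,
               tolerance = 1e-9)
  expect_equal(tb$needed_additional, tb$total_need - tb$baseline,
               tolerance = 1e-9)
  # baseline-year row has zero effects and zero additional need
  b0 <- tb[tb$year == 2020, ]
  expect_equal(b0$growth_effect, 0, tolerance = 1e-9)
  expect_equal(b0$aging_effect, 0, tolerance = 1e-9)
  expect_equal(b0$total_need, 343202, tolerance = 1e-9)

  # ratio identity: need(t)/baseline = visits(t)/visits(baseline)
  v0 <- project_total_visits(fx$rates, fx$pop, 2020)
  for (t in c(2025, 2030, 2040)) {
    vt <- project_total_visits(fx$rates, fx$pop, t)
    expect_equal(tb$total_need[tb$year == t] / 343202, vt / v0,
                 tolerance = 1e-12)
  }
})

test_that("increasing any population cell never decreases total need", {
  fx <- proj_fixture(seed = 9)
  tb1 <- build_projection_table(fx$rates, fx$pop, 1000)
  pop2 <- fx$pop
  i <- which(pop2$year == 2030)[5]
  pop2$population[i] <- pop2$population[i] * 2
  tb2 <- build_projection_table(fx$rates, pop2, 1000)
  expect_gte(tb2$total_need[tb2$year == 2030],
             tb1$total_need[tb1$year == 2030])
})

test_that("the fitted model self-consistently reproduces its baseline", {
  cfg <- small_config()
  pop <- gen_population_projection(cfg)
  rates <- primary_care_rate_table(
    weighted_visit_rates(gen_visit_survey(cfg), year = 2019))
  m <- pc_need_model(rates, pop, baseline_providers = 343202)
  p <- predict(m, years = 2020)
  expect_equal(p$total_need, 343202, tolerance = 1e-9)
  expect_equal(unname(coef(m)["baseline_providers"]), 343202)
  # visits at baseline population / calibrated vpp = baseline exactly
  v0 <- project_total_visits(rates, pop, 2020)
  expect_equal(providers_needed(v0, m$vpp), 343202, tolerance = 1e-9)
})

test_that("model methods print, summarise, predict and plot", {
  fx <- proj_fixture(seed = 5, years = seq(2020, 2040, 5))
  m <- pc_need_model(fx$rates, fx$pop, baseline_providers = 5000)
  expect_output(print(m), "Primary care need projection model")
  expect_output(print(summary(m)), "decomposition")
  expect_equal(nrow(predict(m, years = c(2030, 2040))), 2)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(m))
})
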