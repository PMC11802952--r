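test_that("each attribution rule fires on its canonical case", {
  # FQHC, office-based -> primary care by the facility rule
  a <- classify_np_pa(link_row(facility_type = "FQHC"))
  expect_equal(a$pc_fraction, 1)
  expect_equal(a$rule, "rule3")

  # multi-specialty practice: 3 PCPs of 12 physicians -> 0.25
  a <- classify_np_pa(link_row(profession = "PA", n_pcp_physicians = 3,
                               n_nonpcp_physicians = 9))
  expect_equal(a$pc_fraction, 0.25)
  expect_equal(a$rule, "rule2")

  # practice with physicians but no PCPs -> 0
  a <- classify_np_pa(link_row(n_nonpcp_physicians = 5))
  expect_equal(a$pc_fraction, 0)
  expect_equal(a$rule, "rule1")

  # retail clinic, critical access hospital, skilled nursing facility -> 0
  for (ft in c("retail_clinic", "critical_access_hospital",
               "skilled_nursing_facility")) {
    a <- classify_np_pa(link_row(facility_type = ft))
    expect_equal(a$pc_fraction, 0)
    expect_equal(a$rule, "rule5")
  }

  # behavioral-health dominated organisation -> 0
  a <- classify_np_pa(link_row(n_social_workers = 4, n_psychologists = 3,
                               n_other_clinicians = 2))
  expect_equal(a$pc_fraction, 0)
  expect_equal(a$rule, "rule4")

  # solo practice, nobody else in the organisation -> 1
  a <- classify_np_pa(link_row())
  expect_equal(a$pc_fraction, 1)
  expect_equal(a$rule, "rule6")

  # setting override beats the FQHC rule: 0.95 hospital share in an FQHC
  a <- classify_np_pa(link_row(facility_type = "FQHC", share_hospital = 0.95,
                               share_office = 0.05))
  expect_equal(a$pc_fraction, 0)
  expect_equal(a$rule, "setting_override")

  expect_error(classify_np_pa(link_row(facility_type = "spaceship")),
               "unknown facility type")
  expect_error(classify_np_pa(link_row(profession = "physician")),
               "NP and PA records only")
})

test_that("precedence behaves as a first-firing-rule engine for any ordering", {
  # oracle: evaluate each rule independently, then pick the first firing one
  fire <- function(row, thr = 0.5) {
    nonoff <- row$share_hospital + row$share_ed + row$share_nursing_home +
      row$share_assisted_living + row$share_home_health
    nphys <- row$n_pcp_physicians + row$n_nonpcp_physicians
    members <- nphys + row$n_social_workers + row$n_psychologists +
      row$n_other_clinicians
    list(
      setting_override = if (nonoff > thr) 0 else NULL,
      rule3 = if (row$facility_type %in% c("RHC", "FQHC")) 1 else NULL,
      rule5 = if (row$facility_type %in%
                    c("retail_clinic", "critical_access_hospital",
                      "skilled_nursing_facility")) 0 else NULL,
      rule4 = if (members > 0 &&
                    (row$n_social_workers + row$n_psychologists) >
                      thr * members) 0 else NULL,
      rule12 = if (nphys > 0) row$n_pcp_physicians / nphys
               else if (members > 0) 0 else NULL,
      rule6 = if (members == 0) 1 else NULL
    )
  }
  set.seed(42)
  fac <- c("RHC", "FQHC", "retail_clinic", "critical_access_hospital",
           "skilled_nursing_facility", "none")
  orderings <- list(
    c("setting_override", "rule3", "rule5", "rule4", "rule12", "rule6"),
    c("rule3", "setting_override", "rule5", "rule4", "rule12", "rule6"),
    c("rule12", "rule4", "rule5", "rule3", "setting_override", "rule6"),
    c("rule6", "rule12", "rule4", "rule5", "rule3", "setting_override")
  )
  for (i in 1:60) {
    row <- link_row(
      facility_type = sample(fac, 1),
      n_pcp_physicians = sample(0:5, 1), n_nonpcp_physicians = sample(0:5, 1),
      n_social_workers = sample(0:4, 1), n_psychologists = sample(0:3, 1),
      n_other_clinicians = sample(0:3, 1),
      share_hospital = runif(1), share_office = runif(1)
    )
    for (ord in orderings) {
      fired <- fire(row)
      expected <- NA_real_
      for (rule in ord) {
        if (!is.null(fired[[rule]])) { expected <- fired[[rule]]; break }
      }
      got <- classify_np_pa(row, classifier_config(precedence = ord))
      expect_equal(got$pc_fraction, expected,
                   info = paste("ordering", paste(ord, collapse = ">")))
    }
  }
})

test_that("classification is a pure function of inputs and config", {
  b <- simulate_bundle(small_config())
  a1 <- classify_np_pa(b$links)
  a2 <- classify_np_pa(b$links)
  expect_identical(a1, a2)
  expect_true(all(a1$pc_fraction >= 0 & a1$pc_fraction <= 1))
  expect_true(all(nchar(a1$rule) > 0))
})

test_that("multi-organisation providers attribute via the largest service share", {
  two <- rbind(link_row(organization_id = "A", org_service_share = 0.7,
                        facility_type = "FQHC"),
               link_row(organization_id = "B", org_service_share = 0.3,
                        n_nonpcp_physicians = 4))
  a <- classify_np_pa(two)
  expect_equal(nrow(a), 1)
  expect_equal(a$pc_fraction, 1)  # the 0.7-share FQHC wins
  # tie: the higher primary care fraction wins, and is logged
  tie <- rbind(link_row(organization_id = "A", org_service_share = 0.5,
                        n_nonpcp_physicians = 4),
               link_row(organization_id = "B", org_service_share = 0.5,
                        facility_type = "RHC"))
  expect_equal(classify_np_pa(tie)$pc_fraction, 1)
})

test_that("yearly tabulation partitions providers exactly", {
  b <- simulate_bundle(small_config())
  a <- classify_np_pa(b$links)
  t2 <- enumerate_np_pa(a)
  for (i in seq_len(nrow(t2))) {
    g <- a[a$year == t2$year[i] & a$profession == t2$profession[i], ]
    non_pc <- sum(1 - g$pc_fraction)
    expect_equal(t2$n_primary_care[i] + non_pc, t2$n_all[i],
                 tolerance = 1e-10)
    expect_equal(t2$percent[i],
                 round_half_up(100 * t2$n_primary_care[i] / t2$n_all[i], 1))
  }
  # degenerate: every attribution zero
  a0 <- a; a0$pc_fraction <- 0
  expect_true(all(enumerate_np_pa(a0)$percent == 0))
})

test_that("classifier recovers the generator truth exactly per provider", {
  b <- simulate_bundle(small_config(seed = 55))
  a <- classify_np_pa(b$links)
  truth <- b$truth$np_pa
  m <- merge(a, truth, by = c("provider_id", "year"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$pc_fraction, m$pc_fraction_truth, tolerance = 1e-12)
})

test_that("office and primary-care shares recover configured values", {
  # configured at office 0.815 with 0.456 primary care among office-based
  cfg <- gen_config(seed = 21, n_physicians = 10, n_nps = 20000, n_pas = 1000,
                    np_pc_share = 0.815 * 0.456, np_office_share = 0.815)
  b <- simulate_bundle(cfg)
  a <- classify_np_pa(b$links)
  sh <- office_and_pc_shares(a, b$links)
  np <- sh[sh$profession == "NP", ]
  expect_lt(abs(np$office_share - 0.815), 3 * binom_se(0.815, 20000))
  n_office <- round(np$office_share * 20000)
  expect_lt(abs(np$pc_share_office - 0.456), 3 * binom_se(0.456, n_office))
  expect_false(np$degenerate)

  # all office, all primary care
  one <- classify_np_pa(link_row(facility_type = "FQHC"))
  sh1 <- office_and_pc_shares(one, link_row(facility_type = "FQHC"))
  expect_equal(sh1$office_share, 1)
  expect_equal(sh1$pc_share_office, 1)

  # no office-based providers: share 0 and flagged degenerate
  hosp <- link_row(share_hospital = 0.9, share_office = 0.1)
  sh0 <- office_and_pc_shares(classify_np_pa(hosp), hosp)
  expect_equal(sh0$office_share, 0)
  expect_true(sh0$degenerate)
  expect_true(is.na(sh0$pc_share_office))
})
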