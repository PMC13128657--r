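test_that("generation is a pure function of config and seed", {
  cfg <- cohort_config(n_patients = 400, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$episodes, b$episodes)
  expect_identical(a$infections, b$infections)

  c2 <- generate_cohort(cohort_config(n_patients = 400, seed = 22))
  expect_false(identical(a$episodes, c2$episodes))
})

test_that("zero hazard yields zero infections; onsets obey the 48h rule", {
  off <- generate_cohort(cohort_config(n_patients = 300,
                                       daily_infection_hazard = 0, seed = 1))
  expect_equal(nrow(off$infections), 0L)
  expect_identical(off$episodes, off$baseline)

  hot <- generate_cohort(cohort_config(n_patients = 500,
                                       daily_infection_hazard = 0.05, seed = 2))
  expect_gt(nrow(hot$infections), 0)
  los <- setNames(hot$baseline$length_of_stay, hot$baseline$episode_id)
  expect_true(all(hot$infections$onset_day >= 2))
  expect_true(all(hot$infections$onset_day <=
                  los[hot$infections$episode_id]))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(n_patients = 0), "n_patients",
               class = "dip_config_error")
  expect_error(cohort_config(daily_infection_hazard = 1.2),
               "daily_infection_hazard", class = "dip_config_error")
  expect_error(cohort_config(mdro_count_distribution = c("0" = 0.5, "1" = 0.4,
                                                         "2" = 0.2, "3+" = 0.2)),
               "mdro_count_distribution", class = "dip_config_error")
  bad_cat <- default_dip_catalogue(); bad_cat$cost_sdlog[1] <- -1
  expect_error(cohort_config(dip_catalogue = bad_cat), "dip_catalogue",
               class = "dip_config_error")
  expect_error(effect_spec(los_extension = -2), "los_extension",
               class = "dip_config_error")
  expect_error(effect_spec(mdro_escalation = 0.5), "mdro_escalation",
               class = "dip_config_error")
})

test_that("default hazard is calibrated: observed incidence sits in the binomial band", {
  cfg <- cohort_config(n_patients = 20000, seed = 77)
  co <- generate_cohort(cfg)
  n_inf <- length(unique(co$infections$episode_id))
  band <- qbinom(c(0.025, 0.975), 20000, 0.004)
  expect_gte(n_inf, band[1])
  expect_lte(n_inf, band[2])
})

test_that("expected infection count is monotone in the hazard", {
  mean_infected <- function(h, seeds) {
    mean(vapply(seeds, function(s) {
      co <- generate_cohort(cohort_config(n_patients = 150,
                                          daily_infection_hazard = h,
                                          seed = s))
      length(unique(co$infections$episode_id))
    }, numeric(1)))
  }
  seeds <- 1:200
  expect_lte(mean_infected(0.004, seeds), mean_infected(0.02, seeds))
})

test_that("inject_effects changes only infected episodes, by the stated formula", {
  eps <- make_episodes(
    make_episode("A", cost = 10000, diag = 1500, los = 12,
                 surgery = TRUE, wound = "II"),
    make_episode("B", cost = 8000, diag = 1000, los = 6)
  )
  inf <- make_infection("A", 5, site = "other")

  null_fx <- effect_spec(0, 0, 0, 1, 0)
  expect_identical(inject_effects(eps, inf, null_fx), eps)

  fx <- effect_spec(5000, 800, 9, mdro_escalation = 1, wound_class_escalation = 0)
  out <- inject_effects(eps, inf, fx)
  expect_equal(out$hospitalization_cost_cny[1], 15000)
  expect_equal(out$diagnostic_cost_cny[1], 2300)
  expect_equal(out$length_of_stay[1], 21)
  expect_identical(out[2, ], eps[2, ])     # uninfected row untouched

  # two MDRO types escalate the cost delta to 5000 * m (hand formula)
  m <- 1.7
  fx2 <- effect_spec(5000, 800, 9, mdro_escalation = m)
  inf2 <- make_infection("A", 5, mdro_types = "CRE;MRSA")
  out2 <- inject_effects(eps, inf2, fx2)
  expect_equal(out2$hospitalization_cost_cny[1], 10000 + 5000 * m)

  # SSI wound-class gradient is additive on the episode's wound class (II -> 2)
  fx3 <- effect_spec(5000, 800, 9, mdro_escalation = 1,
                     wound_class_escalation = 300)
  inf3 <- make_infection("A", 5, site = "SSI")
  out3 <- inject_effects(eps, inf3, fx3)
  expect_equal(out3$hospitalization_cost_cny[1], 10000 + 5000 + 300 * 2)

  expect_error(inject_effects(eps, make_infection("Z", 3), fx),
               class = "dip_integrity_error")
})

test_that("injected deltas equal the effect spec exactly for every infected episode", {
  cfg <- recovery_config(n = 4000, seed = 5)
  co <- generate_cohort(cfg)
  ids <- unique(co$infections$episode_id)
  i <- match(ids, co$episodes$episode_id)
  expect_equal(co$episodes$hospitalization_cost_cny[i] -
                 co$baseline$hospitalization_cost_cny[i],
               rep(5031.01 * 7.12, length(i)))
  expect_equal(co$episodes$length_of_stay[i] - co$baseline$length_of_stay[i],
               rep(9L, length(i)))
  # invariants: diagnostic cost within hospitalization cost, LOS >= 1
  expect_true(all(co$episodes$diagnostic_cost_cny <=
                  co$episodes$hospitalization_cost_cny))
  expect_true(all(co$episodes$length_of_stay >= 1))
})

test_that("cohorts round-trip through the CSV schemas", {
  co <- generate_cohort(cohort_config(n_patients = 120,
                                      daily_infection_hazard = 0.03, seed = 3))
  dir <- tempfile()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$episodes, co$episodes, tolerance = 1e-12)
  expect_equal(back$infections, co$infections, tolerance = 1e-12)
})
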