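test_that("exact matching enforces every criterion", {
  case <- make_episode("C1", age = 60)
  # age within 5 years: +4 matches
  expect_equal(exact_match(case, make_episode("K1", age = 64))$pairs$control_id,
               "K1")
  # +6 does not
  expect_equal(nrow(exact_match(case, make_episode("K2", age = 66))$pairs), 0)
  # different sex is excluded
  expect_equal(nrow(exact_match(case, make_episode("K3", sex = "female"))$pairs), 0)
  # different CACI stratum is excluded even with identical demographics
  hi <- make_episode("C2", caci_stratum = "high", caci_score = 4L)
  lo <- make_episode("K4", caci_stratum = "low", caci_score = 2L)
  expect_equal(nrow(exact_match(hi, lo)$pairs), 0)
  # different DIP category is excluded
  expect_equal(nrow(exact_match(case,
                                make_episode("K5", dip_category = "D9"))$pairs), 0)
  # empty control pool: all cases unmatched, not an error
  none <- exact_match(case, make_episode("K9", age = 20))
  expect_equal(none$n_unmatched_cases, 1L)
})

test_that("exact matching is greedy without replacement with age tie-breaks", {
  cases <- make_episodes(make_episode("C1", age = 60),
                         make_episode("C2", age = 60))
  controls <- make_episodes(make_episode("K1", age = 63),
                            make_episode("K2", age = 61),
                            make_episode("K3", age = 61))
  m <- exact_match(cases, controls)
  # C1 first: closest age is 61, tie between K2/K3 broken by id -> K2
  expect_equal(m$pairs$control_id[m$pairs$case_id == "C1"], "K2")
  expect_equal(m$pairs$control_id[m$pairs$case_id == "C2"], "K3")
  # every emitted pair satisfies the criteria, both sides used at most once
  expect_false(any(duplicated(m$pairs$control_id)))
  expect_false(any(duplicated(m$pairs$case_id)))
})

test_that("propensity matching pairs identical covariates at distance zero", {
  cases <- make_episodes(make_episode("C1", age = 55),
                         make_episode("C2", age = 70, sex = "female"))
  controls <- make_episodes(make_episode("K1", age = 55),
                            make_episode("K2", age = 70, sex = "female"),
                            make_episode("K3", age = 55))
  m <- propensity_match(cases, controls, seed = 4)
  expect_equal(nrow(m$pairs), 2)
  twin <- m$pairs[m$pairs$case_id == "C1", ]
  expect_equal(twin$control_id, "K1")   # distance 0, id tie-break over K3
  expect_equal(twin$distance, 0, tolerance = 1e-10)
})

test_that("propensity caliper excludes distant controls", {
  # cases bracket the controls in age (no separation), but every control
  # sits 10+ age-units away while the caliper is 0.2 SD of the pooled logit
  cases <- make_episodes(make_episode("C1", age = 50),
                         make_episode("C2", age = 74))
  controls <- make_episodes(make_episode("K1", age = 60),
                            make_episode("K2", age = 61),
                            make_episode("K3", age = 62))
  m <- propensity_match(cases, controls, seed = 1)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$n_unmatched_cases, 2L)
})

test_that("propensity matching equals greedy minimum-distance enumeration", {
  cases <- make_episodes(make_episode("C1", age = 50),
                         make_episode("C2", age = 60, sex = "female"),
                         make_episode("C3", age = 70))
  controls <- make_episodes(make_episode("K1", age = 52),
                            make_episode("K2", age = 58, sex = "female"),
                            make_episode("K3", age = 65),
                            make_episode("K4", age = 71, sex = "female"),
                            make_episode("K5", age = 49))
  seed <- 31
  m <- propensity_match(cases, controls, caliper = 0.2, seed = seed)

  # oracle: refit the same propensity model (CACI stratum is constant here,
  # so age + sex), then walk cases in the seeded order taking the nearest
  # unused in-caliper control
  pooled <- rbind(cbind(case = 1, cases), cbind(case = 0, controls))
  fit <- glm(case ~ age + sex, binomial(), data = pooled)
  lp <- predict(fit)
  width <- 0.2 * sd(lp)
  lpc <- lp[1:3]; lpk <- lp[4:8]
  set.seed(seed); ord <- sample.int(3)
  used <- rep(FALSE, 5); expect_pairs <- list()
  for (i in ord) {
    d <- abs(lpk - lpc[i]); d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= width) {
      used[j] <- TRUE
      expect_pairs[[length(expect_pairs) + 1]] <-
        c(cases$episode_id[i], controls$episode_id[j])
    }
  }
  got <- m$pairs[order(m$pairs$case_id), c("case_id", "control_id")]
  want <- do.call(rbind, expect_pairs)
  want <- want[order(want[, 1]), , drop = FALSE]
  expect_equal(got$case_id, want[, 1])
  expect_equal(got$control_id, want[, 2])
})

test_that("degenerate propensity fits are diagnosed", {
  cases <- do.call(rbind, lapply(1:4, function(i)
    make_episode(paste0("C", i), age = 30 + i)))
  controls <- do.call(rbind, lapply(1:4, function(i)
    make_episode(paste0("K", i), age = 70 + i)))
  expect_error(propensity_match(cases, controls, seed = 1),
               class = "dip_psm_error")
})

test_that("risk-set eligibility follows the not-yet-infected-at-T1 rule", {
  case <- make_episode("A", los = 20)
  pool <- make_episodes(
    make_episode("B", los = 3),                 # discharged before T1 = 5
    make_episode("C", los = 12),                # never infected, in risk set
    make_episode("D", los = 15),                # infected day 2: already a case
    make_episode("E", los = 12)                 # infected day 9 > T1: eligible
  )
  inf <- rbind(make_infection("A", 5), make_infection("D", 2),
               make_infection("E", 9))
  elig <- eligible_risk_set(case, 5, pool, inf)
  expect_setequal(elig$episode_id, c("C", "E"))
  # boundary: infected exactly at T1 is not "not yet infected at T1"
  inf_b <- rbind(make_infection("A", 5), make_infection("C", 5))
  elig_b <- eligible_risk_set(case, 5, pool, inf_b)
  expect_false("C" %in% elig_b$episode_id)
  expect_error(eligible_risk_set(case, 1, pool, inf),
               class = "dip_domain_error")
})

test_that("risk-set matching resolves the toy eligibility example", {
  eps <- make_episodes(
    make_episode("A", los = 20, age = 64),   # case, T1 = 5
    make_episode("B", los = 3, age = 60),
    make_episode("C", los = 12, age = 64),
    make_episode("D", los = 15, age = 60)    # case, T1 = 2
  )
  inf <- rbind(make_infection("A", 5), make_infection("D", 2))
  m <- risk_set_match(eps, inf)
  # A's only eligible partner at T1 = 5 is C: B was discharged on day 3 and
  # D was already infected on day 2 (D itself pairs earlier, at T1 = 2)
  expect_equal(m$pairs[m$pairs$case_id == "A", "control_id"], "C")
  expect_equal(m$pairs[m$pairs$case_id == "A", "t1"], 5L)
  expect_equal(m$pairs[m$pairs$case_id == "D", "control_id"], "B")
  expect_false("D" %in% m$pairs$control_id)

  # no eligible candidate at any T1: zero pairs, all cases unmatched
  solo <- make_episodes(make_episode("X", los = 10))
  m0 <- risk_set_match(solo, make_infection("X", 4))
  expect_equal(nrow(m0$pairs), 0)
  expect_equal(m0$n_unmatched_cases, 1L)
})

test_that("a control that later becomes a case is retained as control", {
  eps <- make_episodes(
    make_episode("A", los = 20),
    make_episode("B", los = 20)
  )
  inf <- rbind(make_infection("A", 3), make_infection("B", 10))
  expect_message(m <- risk_set_match(eps, inf), "retained as control")
  expect_equal(m$pairs$case_id, "A")
  expect_equal(m$pairs$control_id, "B")
  expect_equal(m$dropped_case_ids, "B")
  expect_equal(m$n_unmatched_cases, 0L)
})

test_that("risk-set matcher agrees with the brute-force oracle on random cohorts", {
  for (seed in c(2, 14, 33)) {
    rc <- random_match_cohort(n = 50, seed = seed, p_infect = 0.25)
    if (nrow(rc$infections) == 0) next
    got <- suppressMessages(risk_set_match(rc$episodes, rc$infections))
    want <- bf_risk_set_match(rc$episodes, rc$infections, match_criteria())
    if (is.null(want)) {
      expect_equal(nrow(got$pairs), 0)
    } else {
      expect_equal(got$pairs[, c("case_id", "control_id", "t1")], want,
                   ignore_attr = TRUE)
    }
    # pair-level invariants: criteria hold, control at risk at T1
    for (r in seq_len(nrow(got$pairs))) {
      ca <- rc$episodes[rc$episodes$episode_id == got$pairs$case_id[r], ]
      co <- rc$episodes[rc$episodes$episode_id == got$pairs$control_id[r], ]
      expect_equal(ca$dip_category, co$dip_category)
      expect_equal(ca$sex, co$sex)
      expect_equal(ca$caci_stratum, co$caci_stratum)
      expect_lte(abs(ca$age - co$age), 5)
      expect_gte(co$length_of_stay, got$pairs$t1[r])
      ev <- rc$infections[rc$infections$episode_id == co$episode_id, ]
      if (nrow(ev) > 0) expect_gt(min(ev$onset_day), got$pairs$t1[r])
    }
  }
})

test_that("matching is deterministic under a fixed seed", {
  rc <- random_match_cohort(n = 60, seed = 9, p_infect = 0.3)
  infected <- unique(rc$infections$episode_id)
  cases <- rc$episodes[rc$episodes$episode_id %in% infected, ]
  controls <- rc$episodes[!rc$episodes$episode_id %in% infected, ]
  expect_identical(exact_match(cases, controls)$pairs,
                   exact_match(cases, controls)$pairs)
  expect_identical(propensity_match(cases, controls, seed = 5)$pairs,
                   propensity_match(cases, controls, seed = 5)$pairs)
  expect_identical(suppressMessages(risk_set_match(rc$episodes, rc$infections)$pairs),
                   suppressMessages(risk_set_match(rc$episodes, rc$infections)$pairs))
})
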