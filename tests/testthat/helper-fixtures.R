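# toy episode / infection builders used across matching and pipeline tests

make_episode <- function(id, sex = "male", age = 60, dip_category = "D1",
                         los = 10, cost = 10000, diag = 1500,
                         payment = 10000, payment_type = "DIP",
                         codes = "C50.9", surgery = FALSE,
                         wound = "none", device = FALSE,
                         caci_stratum = "low", caci_score = 2L) {
  data.frame(episode_id = id, sex = sex, age = age, admission_day = 1L,
             length_of_stay = los, dip_category = dip_category,
             payment_type = payment_type,
             hospitalization_cost_cny = cost, diagnostic_cost_cny = diag,
             dip_standard_payment_cny = payment, icd10_codes = codes,
             surgery_flag = surgery, wound_class = wound,
             invasive_device_flag = device,
             caci_score = caci_score, caci_stratum = caci_stratum,
             stringsAsFactors = FALSE)
}

make_episodes <- function(...) do.call(rbind, list(...))

make_infection <- function(episode_id, onset_day, site = "other",
                           organisms = "E. coli", mdro_types = "",
                           event_id = NULL) {
  if (length(episode_id) == 0) return(no_infections())
  data.frame(event_id = event_id %||% paste0("ev_", episode_id, "_", onset_day),
             episode_id = episode_id, onset_day = onset_day, site = site,
             organisms = organisms, mdro_types = mdro_types,
             stringsAsFactors = FALSE)
}

no_infections <- function() {
  data.frame(event_id = character(), episode_id = character(),
             onset_day = integer(), site = character(),
             organisms = character(), mdro_types = character(),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small random cohort of episodes + infections for matcher stress tests
random_match_cohort <- function(n = 50, seed = 1, p_infect = 0.2) {
  set.seed(seed)
  ep <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_episode(sprintf("R%03d", i),
                 sex = sample(c("male", "female"), 1),
                 age = sample(40:80, 1),
                 dip_category = sample(c("D1", "D2"), 1),
                 los = sample(2:30, 1),
                 caci_stratum = sample(c("low", "high"), 1))
  }))
  inf_ids <- ep$episode_id[runif(n) < p_infect & ep$length_of_stay >= 2]
  infections <- do.call(rbind, c(lapply(inf_ids, function(id) {
    los <- ep$length_of_stay[ep$episode_id == id]
    make_infection(id, if (los == 2) 2L else sample(2:los, 1))
  }), list(no_infections())))
  list(episodes = ep, infections = infections)
}

# cohort config for fast recovery experiments: exact single-shift truth
recovery_config <- function(n = 20000, seed = 1,
                            cost_usd = 5031.01, diag_usd = 798.81,
                            los_days = 9, rate = 7.12) {
  cohort_config(
    n_patients = n,
    effects = effect_spec(cost_inflation = cost_usd * rate,
                          diagnostic_inflation = diag_usd * rate,
                          los_extension = los_days,
                          mdro_escalation = 1, wound_class_escalation = 0),
    seed = seed
  )
}
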