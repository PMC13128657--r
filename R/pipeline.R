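INDICATORS <- c(hospitalization_cost = "hospitalization_cost_usd",
                diagnostic_cost = "diagnostic_cost_usd",
                length_of_stay = "length_of_stay",
                dip_differential = "differential_usd")

#' Category concentration report
#'
#' Ranks DIP categories by hospital-acquired infection case count
#' (descending, ties by category label) and, for each of the top `top_k`,
#' reports the case count, the within-category incidence rate, the
#' infection percentage (the category's share of all HAI cases), and the
#' infected-versus-uninfected comparison of the four settlement indicators
#' (Mann-Whitney + Hodges-Lehmann, USD at `rate`).
#'
#' @param episodes Episode table.
#' @param infections Non-empty infection-event table.
#' @param top_k How many categories to report (all if fewer exist).
#' @param rate CNY per USD.
#' @return List: `categories` (ranking table) and `comparisons` (long
#'   table, one row per category x indicator).
#' @export
run_category_report <- function(episodes, infections, top_k = 5, rate = 7.12) {
  check_referential(episodes, infections)
  if (nrow(infections) == 0) stop_domain("no infection events to report on")
  episodes <- add_settlement(episodes, rate)
  infected_ids <- unique(infections$episode_id)
  inf_flag <- episodes$episode_id %in% infected_ids
  n_total_cases <- length(infected_ids)

  counts <- table(episodes$dip_category[inf_flag])
  ranking <- data.frame(dip_category = names(counts),
                        n_hai = as.integer(counts), stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$n_hai, ranking$dip_category), , drop = FALSE]
  ranking <- utils::head(ranking, top_k)
  ranking$n_total <- as.integer(table(episodes$dip_category)[ranking$dip_category])
  ranking$incidence_pct <- incidence_rate(ranking$n_hai, ranking$n_total)
  ranking$infection_pct <- incidence_rate(ranking$n_hai, n_total_cases)
  rownames(ranking) <- NULL

  comps <- lapply(ranking$dip_category, function(cat) {
    in_cat <- episodes$dip_category == cat
    tabs <- lapply(names(INDICATORS), function(ind) {
      gc <- compare_groups(episodes[[INDICATORS[[ind]]]][in_cat & inf_flag],
                           episodes[[INDICATORS[[ind]]]][in_cat & !inf_flag],
                           indicator = ind)
      cbind(dip_category = cat, comparison_table(list(gc)))
    })
    do.call(rbind, tabs)
  })
  list(categories = ranking, comparisons = do.call(rbind, comps))
}

#' Infection-classification report
#'
#' Among infected episodes only, stratifies the four settlement indicators
#' by (i) infection frequency during the stay, (ii) catheter association
#' (CLABSI/VAP/CAUTI vs other), (iii) number of distinct MDRO types, and
#' (iv) surgical-site-infection wound class, reporting group medians with
#' quartiles and the Kruskal-Wallis (three or more groups) or
#' Mann-Whitney (two groups) p-value per stratification x indicator.
#' Stratifications with a single non-empty level are skipped with a
#' message.
#'
#' @param episodes Episode table.
#' @param profiles Output of [infection_profiles()] for `episodes`.
#' @param rate CNY per USD.
#' @return List: `groups` (medians per stratification level) and `tests`
#'   (test used, statistic and p per stratification x indicator).
#' @export
run_classification_report <- function(episodes, profiles, rate = 7.12) {
  episodes <- add_settlement(episodes, rate)
  dat <- cbind(episodes[match(profiles$episode_id, episodes$episode_id), ],
               profiles[, setdiff(names(profiles), "episode_id")])
  dat <- dat[dat$frequency > 0, , drop = FALSE]
  if (nrow(dat) == 0) stop_domain("no infected episodes to classify")

  strata <- list(frequency = dat$frequency_bin,
                 catheter_associated = ifelse(dat$catheter_associated,
                                              "yes", "no"),
                 mdro_type_count = dat$mdro_count_bin,
                 ssi_wound_class = dat$ssi_wound_class)
  groups <- list(); tests <- list()
  for (s in names(strata)) {
    lv <- strata[[s]]
    lvls <- sort(unique(lv))
    if (length(lvls) < 2) {
      message("run_classification_report: single level in ", s, "; skipped")
      next
    }
    for (ind in names(INDICATORS)) {
      v <- dat[[INDICATORS[[ind]]]]
      gs <- split(v, lv)
      qt <- t(vapply(gs, quantile, numeric(3), probs = c(0.5, 0.25, 0.75)))
      groups[[length(groups) + 1L]] <- data.frame(
        classification = s, level = names(gs),
        n = vapply(gs, length, integer(1)), indicator = ind,
        median = qt[, 1], p25 = qt[, 2], p75 = qt[, 3],
        stringsAsFactors = FALSE, row.names = NULL)
      if (length(gs) == 2) {
        mw <- mann_whitney(gs[[1]], gs[[2]])
        tst <- data.frame(classification = s, indicator = ind,
                          test = "mann_whitney", statistic = mw$Z,
                          p_value = mw$p_value, stringsAsFactors = FALSE)
      } else {
        kw <- kruskal_wallis(gs)
        tst <- data.frame(classification = s, indicator = ind,
                          test = "kruskal_wallis", statistic = kw$H,
                          p_value = kw$p_value, stringsAsFactors = FALSE)
      }
      tests[[length(tests) + 1L]] <- tst
    }
  }
  list(groups = do.call(rbind, groups), tests = do.call(rbind, tests))
}

#' Matched case-control analysis
#'
#' Runs one matching design and compares matched cases against their
#' controls on the four settlement indicators (USD at `rate`).
#'
#' @param episodes Episode table (CACI columns added if missing).
#' @param infections Infection-event table.
#' @param model `"risk_set"` (primary), `"exact"` or `"psm"`.
#' @param criteria A [match_criteria()].
#' @param caliper Caliper for `"psm"` in logit-propensity SD units.
#' @param seed Seed for the designs that use one.
#' @param rate CNY per USD.
#' @return List: `cohort` (a `"matched_cohort"`), `comparisons` (list of
#'   four `"group_comparison"`), `table` (their [comparison_table()], empty
#'   when nothing matched).
#' @export
run_matched_analysis <- function(episodes, infections,
                                 model = c("risk_set", "exact", "psm"),
                                 criteria = match_criteria(), caliper = 0.2,
                                 seed = 1L, rate = 7.12) {
  model <- match.arg(model)
  if (!"caci_stratum" %in% names(episodes)) episodes <- add_caci(episodes)
  episodes <- add_settlement(episodes, rate)
  infected_ids <- unique(infections$episode_id)
  cases <- episodes[episodes$episode_id %in% infected_ids, , drop = FALSE]
  never <- episodes[!episodes$episode_id %in% infected_ids, , drop = FALSE]

  cohort <- switch(model,
    exact = exact_match(cases, never, criteria, seed),
    psm = propensity_match(cases, never, criteria, caliper, seed),
    risk_set = risk_set_match(episodes, infections, criteria, seed))

  if (nrow(cohort$pairs) == 0)
    return(list(cohort = cohort, comparisons = list(),
                table = data.frame(), status = "no matched pairs"))

  case_rows <- match(cohort$pairs$case_id, episodes$episode_id)
  ctrl_rows <- match(cohort$pairs$control_id, episodes$episode_id)
  comparisons <- lapply(names(INDICATORS), function(ind) {
    compare_groups(episodes[[INDICATORS[[ind]]]][case_rows],
                   episodes[[INDICATORS[[ind]]]][ctrl_rows], indicator = ind)
  })
  names(comparisons) <- names(INDICATORS)
  list(cohort = cohort, comparisons = comparisons,
       table = comparison_table(comparisons), status = "ok")
}

#' Analysis configuration for [run_full()]
#'
#' @param simulate A [cohort_config()] to generate the cohort, or `NULL`
#'   to read `episodes.csv`/`infections.csv` from `input_dir`.
#' @param input_dir Directory with input CSVs when `simulate` is `NULL`.
#' @param models Matching designs to run (first one feeds the GLM).
#' @param caliper PSM caliper in logit-SD units.
#' @param alpha Two-sided significance level in (0, 1).
#' @param rate CNY per USD.
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed; overrides the seed inside `simulate`.
#' @param top_k Categories in the concentration report.
#' @return List of class `"analysis_config"`.
#' @export
analysis_config <- function(simulate = cohort_config(), input_dir = NULL,
                            models = c("risk_set", "exact", "psm"),
                            caliper = 0.2, alpha = 0.05, rate = 7.12,
                            out_dir = tempfile("dipburden_run_"), seed = 1L,
                            top_k = 5) {
  if (alpha <= 0 || alpha >= 1) config_error("alpha", "must lie in (0, 1)")
  if (rate <= 0) config_error("rate", "must be positive")
  models <- match.arg(models, c("risk_set", "exact", "psm"),
                      several.ok = TRUE)
  if (!is.null(simulate)) simulate$seed <- as.integer(seed)
  structure(list(simulate = simulate, input_dir = input_dir, models = models,
                 caliper = caliper, alpha = alpha, rate = rate,
                 out_dir = out_dir, seed = as.integer(seed), top_k = top_k),
            class = "analysis_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or CSV ingest), CACI scoring,
#' infection profiling, the category concentration report, the
#' infection-classification report, every requested matched analysis, and
#' the payment-differential GLM on the first requested design. All
#' artifacts are written as CSVs under `config$out_dir` together with a
#' run manifest recording the seed, parameters and conventions in force.
#' Identical configs produce identical bundles.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, the report bundle (a list of all tables and objects).
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("input", {
    if (!is.null(config$simulate)) generate_cohort(config$simulate)
    else read_cohort(config$input_dir)
  })
  episodes <- stage("caci", add_caci(cohort$episodes))
  episodes <- stage("settlement", add_settlement(episodes, config$rate))
  profiles <- stage("profiles", infection_profiles(episodes, cohort$infections))

  category <- stage("category_report",
                    run_category_report(episodes, cohort$infections,
                                        top_k = config$top_k,
                                        rate = config$rate))
  classification <- stage("classification_report",
                          run_classification_report(episodes, profiles,
                                                    rate = config$rate))
  matched <- lapply(config$models, function(m) {
    stage(paste0("matched_", m),
          run_matched_analysis(episodes, cohort$infections, model = m,
                               caliper = config$caliper, seed = config$seed,
                               rate = config$rate))
  })
  names(matched) <- config$models
  glm_fit <- stage("glm", {
    primary <- matched[[config$models[1]]]
    if (nrow(primary$cohort$pairs) > 0)
      suppressWarnings(fit_differential_glm(episodes, cohort$infections,
                                            primary$cohort,
                                            rate = config$rate))
    else NULL
  })

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) write.csv(df, file.path(config$out_dir, f),
                                 row.names = FALSE, fileEncoding = "UTF-8")
  w(episodes, "episodes.csv")
  w(cohort$infections, "infections.csv")
  w(profiles, "profiles.csv")
  w(category$categories, "category_ranking.csv")
  w(category$comparisons, "category_comparisons.csv")
  w(classification$groups, "classification_groups.csv")
  w(classification$tests, "classification_tests.csv")
  pairs_all <- do.call(rbind, lapply(names(matched), function(m)
    cbind(model = m, matched[[m]]$cohort$pairs)))
  w(pairs_all, "pairs.csv")
  for (m in names(matched))
    if (nrow(matched[[m]]$table) > 0)
      w(matched[[m]]$table, paste0("matched_", m, ".csv"))
  if (!is.null(glm_fit)) w(glm_fit$coefficients, "glm_differential.csv")

  manifest <- c(
    paste0("package: dipburden ", as.character(utils::packageVersion("dipburden"))),
    paste0("seed: ", config$seed),
    paste0("models: ", paste(config$models, collapse = ", ")),
    paste0("alpha: ", config$alpha),
    paste0("exchange_rate_cny_per_usd: ", config$rate),
    paste0("psm_caliper: ", config$caliper, " x SD(logit propensity)"),
    "mw_exact_threshold: exact p when min(n) <= 20 and no ties",
    "hl_ci: distribution-free Moses interval, no interpolation",
    "glm_vcov: HC1 sandwich, normal-reference intervals",
    "risk_set_policy: control reuse forbidden; later-infected controls retained as controls",
    paste0("n_episodes: ", nrow(episodes)),
    paste0("n_infection_events: ", nrow(cohort$infections))
  )
  writeLines(manifest, file.path(config$out_dir, "manifest.txt"))

  invisible(list(episodes = episodes, infections = cohort$infections,
                 profiles = profiles, category = category,
                 classification = classification, matched = matched,
                 glm = glm_fit, manifest = manifest,
                 out_dir = config$out_dir))
}
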