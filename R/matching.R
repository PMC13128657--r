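#' Matching criteria shared by all three designs
#'
#' Cases and controls must share the DIP category, sex and CACI risk
#' stratum, and differ in age by at most `max_age_difference` years. These
#' are hard constraints in exact and risk-set matching; in propensity
#' matching they enter the propensity model instead (with the DIP category
#' kept as an exact constraint).
#'
#' @param require_same_dip_category,require_same_sex,require_same_caci_stratum
#'   Logical constraints, all `TRUE` by default.
#' @param max_age_difference Maximum absolute age difference in years
#'   (default 5, >= 0).
#' @return List of class `"match_criteria"`.
#' @export
match_criteria <- function(require_same_dip_category = TRUE,
                           require_same_sex = TRUE,
                           max_age_difference = 5,
                           require_same_caci_stratum = TRUE) {
  if (max_age_difference < 0) stop_domain("max_age_difference must be >= 0")
  structure(list(require_same_dip_category = require_same_dip_category,
                 require_same_sex = require_same_sex,
                 max_age_difference = max_age_difference,
                 require_same_caci_stratum = require_same_caci_stratum),
            class = "match_criteria")
}

# logical index of pool rows satisfying the criteria against one case row
criteria_ok <- function(case_row, pool, criteria) {
  ok <- rep(TRUE, nrow(pool))
  if (criteria$require_same_dip_category)
    ok <- ok & pool$dip_category == case_row$dip_category
  if (criteria$require_same_sex)
    ok <- ok & pool$sex == case_row$sex
  if (criteria$require_same_caci_stratum)
    ok <- ok & pool$caci_stratum == case_row$caci_stratum
  ok & abs(pool$age - case_row$age) <= criteria$max_age_difference
}

new_matched_cohort <- function(model, pairs, n_cases, dropped = character()) {
  structure(list(model = model, pairs = pairs, n_cases = n_cases,
                 n_matched = nrow(pairs),
                 n_unmatched_cases = n_cases - nrow(pairs) - length(dropped),
                 dropped_case_ids = dropped),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("Matched cohort (%s): %d/%d cases matched 1:1, %d unmatched",
              x$model, x$n_matched, x$n_cases, x$n_unmatched_cases))
  if (length(x$dropped_case_ids))
    cat(sprintf(", %d case(s) retained as controls", length(x$dropped_case_ids)))
  cat("\n")
  invisible(x)
}

empty_pairs <- function() {
  data.frame(case_id = character(), control_id = character(),
             t1 = integer(), distance = numeric(), stringsAsFactors = FALSE)
}

#' Exact 1:1 matching (Model 1)
#'
#' Conventional 1:1 exact matching of infected cases to never-infected
#' controls on the [match_criteria()]: same DIP category, sex and CACI
#' stratum, age within the allowed difference. Greedy without replacement,
#' cases processed in episode-id order; among eligible controls the one
#' with the smallest absolute age difference wins, ties broken by
#' episode-id order.
#'
#' @param cases,controls Disjoint episode tables with `caci_stratum`
#'   already computed (see [add_caci()]).
#' @param criteria A [match_criteria()].
#' @param seed Accepted for interface symmetry with the other designs; the
#'   procedure is fully deterministic, so it is unused.
#' @return A `"matched_cohort"` with a `pairs` data frame
#'   (`case_id`, `control_id`, `t1` = NA, `distance` = NA).
#' @export
exact_match <- function(cases, controls, criteria = match_criteria(),
                        seed = NULL) {
  check_match_input(cases, controls)
  cases <- cases[order(cases$episode_id), , drop = FALSE]
  used <- logical(nrow(controls))
  out <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    ok <- which(!used & criteria_ok(cases[i, ], controls, criteria))
    if (length(ok) == 0) next
    agediff <- abs(controls$age[ok] - cases$age[i])
    best <- ok[order(agediff, controls$episode_id[ok])][1]
    used[best] <- TRUE
    out[[i]] <- data.frame(case_id = cases$episode_id[i],
                           control_id = controls$episode_id[best],
                           t1 = NA_integer_, distance = NA_real_,
                           stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                            list(empty_pairs())))
  new_matched_cohort("exact", pairs, nrow(cases))
}

check_match_input <- function(cases, controls) {
  if (length(intersect(cases$episode_id, controls$episode_id)))
    stop_domain("case and control sets must be disjoint",
                class = "dip_integrity_error")
  for (col in c("dip_category", "sex", "age", "caci_stratum")) {
    if (!col %in% names(cases) || !col %in% names(controls))
      stop_domain(paste0("matching requires column '", col,
                         "' (run add_caci() first?)"))
  }
  invisible(TRUE)
}

#' Propensity-score caliper matching (Model 2)
#'
#' 1:1 nearest-neighbour matching on the logit propensity of case status,
#' with a caliper of `caliper` standard deviations of the pooled logit
#' propensity. The propensity model is a logistic regression of case
#' status on age, sex and CACI stratum; the DIP category is respected as
#' an exact constraint during matching rather than entering as
#' high-cardinality dummies. Cases are processed in random order under
#' `seed`; controls are used without replacement.
#'
#' @inheritParams exact_match
#' @param caliper Caliper width in SD units of the logit propensity
#'   (default 0.2).
#' @param seed Seed for the random case processing order.
#' @return A `"matched_cohort"`; `pairs$distance` holds the absolute logit
#'   propensity difference.
#' @export
propensity_match <- function(cases, controls, criteria = match_criteria(),
                             caliper = 0.2, seed = 1L) {
  check_match_input(cases, controls)
  pooled <- rbind(
    data.frame(case = 1L, cases[, c("episode_id", "age", "sex",
                                    "caci_stratum", "dip_category")]),
    data.frame(case = 0L, controls[, c("episode_id", "age", "sex",
                                       "caci_stratum", "dip_category")])
  )
  if (nrow(unique(pooled[, c("age", "sex", "caci_stratum")])) < 2)
    stop_domain("propensity model needs at least two distinct covariate patterns")
  # constant covariates carry no information and would break the fit
  covs <- c("age", "sex", "caci_stratum")
  covs <- covs[vapply(covs, function(v) length(unique(pooled[[v]])) > 1,
                      logical(1))]
  fit <- suppressWarnings(glm(as.formula(paste("case ~", paste(covs, collapse = " + "))),
                              family = binomial(), data = pooled))
  p <- fitted(fit)
  if (any(p > 1 - 1e-8) || any(p < 1e-8) || !fit$converged)
    stop_domain(paste("degenerate propensity fit (perfect separation);",
                      "consider exact matching instead"),
                class = "dip_psm_error")
  lp <- predict(fit)                      # logit scale
  width <- caliper * sd(lp)
  lp_case <- lp[pooled$case == 1L]
  lp_ctrl <- lp[pooled$case == 0L]

  set.seed(seed)
  ord <- sample.int(nrow(cases))
  used <- logical(nrow(controls))
  out <- vector("list", nrow(cases))
  for (i in ord) {
    ok <- which(!used)
    if (criteria$require_same_dip_category)
      ok <- ok[controls$dip_category[ok] == cases$dip_category[i]]
    if (length(ok) == 0) next
    d <- abs(lp_ctrl[ok] - lp_case[i])
    inside <- d <= width
    if (!any(inside)) next
    best <- ok[inside][order(d[inside], controls$episode_id[ok[inside]])][1]
    used[best] <- TRUE
    out[[i]] <- data.frame(case_id = cases$episode_id[i],
                           control_id = controls$episode_id[best],
                           t1 = NA_integer_,
                           distance = abs(lp_ctrl[best] - lp_case[i]),
                           stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                            list(empty_pairs())))
  new_matched_cohort("psm", pairs, nrow(cases))
}

#' Risk set of a case at its infection time
#'
#' Candidates eligible to serve as the control of a case infected on day
#' `t1`: they satisfy the [match_criteria()] against the case, were still
#' hospitalized at `t1` (length of stay >= `t1`) and were not yet infected
#' at `t1` (no infection event with onset on or before `t1`; patients
#' infected later remain eligible).
#'
#' @param case_row One-row episode data frame for the case.
#' @param t1 Infection onset day (>= 2, days since admission).
#' @param pool Candidate episode table (with `caci_stratum`).
#' @param infections Infection-event table covering the pool.
#' @param criteria A [match_criteria()].
#' @return The eligible subset of `pool` (possibly empty).
#' @export
eligible_risk_set <- function(case_row, t1, pool, infections,
                              criteria = match_criteria()) {
  if (t1 < 2) stop_domain("t1 must be >= 2 (hospital-acquired rule)")
  ok <- criteria_ok(case_row, pool, criteria)
  ok <- ok & pool$length_of_stay >= t1
  ok <- ok & pool$episode_id != case_row$episode_id
  if (nrow(infections) > 0) {
    infected_by_t1 <- unique(infections$episode_id[infections$onset_day <= t1])
    ok <- ok & !(pool$episode_id %in% infected_by_t1)
  }
  pool[ok, , drop = FALSE]
}

#' Risk-set matching at infection onset (Model 3, primary design)
#'
#' Matches each infected case, at its first infection onset day T1, to a
#' patient not yet infected at T1 rather than to a never-infected patient,
#' removing the time-dependent bias that inflates naive attributable
#' length-of-stay estimates. Cases are processed in ascending T1 (ties by
#' episode id) and matched greedily 1:1 without replacement within their
#' [eligible_risk_set()]; among eligible candidates the smallest absolute
#' age difference wins, ties broken by episode id.
#'
#' An episode never serves as both case and control: a later-infected
#' patient already selected as a control is retained as a control and
#' dropped from the case list (logged via `message()` and recorded in
#' `dropped_case_ids`).
#'
#' @param episodes Episode table with `caci_stratum` (see [add_caci()]).
#' @param infections Infection-event table with `onset_day`.
#' @param criteria A [match_criteria()].
#' @param seed Accepted for interface symmetry; the procedure is
#'   deterministic, so it is unused.
#' @return A `"matched_cohort"`; `pairs$t1` holds each case's onset day.
#' @export
risk_set_match <- function(episodes, infections, criteria = match_criteria(),
                           seed = NULL) {
  check_referential(episodes, infections)
  if (nrow(infections) == 0)
    return(new_matched_cohort("risk_set", empty_pairs(), 0L))
  t1 <- tapply(infections$onset_day, infections$episode_id, min)
  case_ids <- names(t1)[order(unname(t1), names(t1))]
  t1 <- unname(t1[case_ids])

  # vectorised greedy pass: one eligibility mask per case over the pool
  id <- episodes$episode_id
  first_onset <- rep(Inf, nrow(episodes))
  first_onset[match(case_ids, id)] <- t1
  available <- rep(TRUE, nrow(episodes))        # not yet used on either side

  dropped <- character()
  out <- list()
  for (i in seq_along(case_ids)) {
    ci <- match(case_ids[i], id)
    if (!available[ci]) {
      message("risk_set_match: case ", case_ids[i],
              " already used as a control; retained as control")
      dropped <- c(dropped, case_ids[i])
      next
    }
    available[ci] <- FALSE                       # a case never re-enters the pool
    if (t1[i] < 2) stop_domain("t1 must be >= 2 (hospital-acquired rule)")
    ok <- available &
      episodes$length_of_stay >= t1[i] &
      first_onset > t1[i] &
      criteria_ok(episodes[ci, , drop = FALSE], episodes, criteria)
    if (!any(ok)) next
    cand <- which(ok)
    agediff <- abs(episodes$age[cand] - episodes$age[ci])
    best <- cand[order(agediff, id[cand])][1]
    available[best] <- FALSE
    out[[length(out) + 1L]] <- data.frame(case_id = case_ids[i],
                                          control_id = id[best],
                                          t1 = as.integer(t1[i]),
                                          distance = NA_real_,
                                          stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, c(out, list(empty_pairs())))
  new_matched_cohort("risk_set", pairs, length(case_ids), dropped = dropped)
}
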