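# Independent brute-force oracles. Deliberately naive: loops and full
# enumeration, no shared code with the package internals.

# median of all pairwise differences, via explicit loops
bf_hodges_lehmann <- function(x, y) {
  d <- numeric(0)
  for (xi in x) for (yj in y) d <- c(d, xi - yj)
  d <- sort(d)
  m <- length(d)
  if (m %% 2 == 1) d[(m + 1) / 2] else (d[m / 2] + d[m / 2 + 1]) / 2
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
bf_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  all_u <- apply(utils::combn(length(pooled), nx), 2, u_of)
  p_le <- mean(all_u <= u_obs)
  p_ge <- mean(all_u >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Kruskal-Wallis H from the textbook rank formula (no ties assumed)
bf_kw_h <- function(groups) {
  all_v <- unlist(groups)
  r <- rank(all_v)
  N <- length(all_v)
  idx <- split(seq_along(all_v), rep(seq_along(groups), lengths(groups)))
  s <- sum(vapply(idx, function(i) sum(r[i])^2 / length(i), numeric(1)))
  12 / (N * (N + 1)) * s - 3 * (N + 1)
}

# risk-set matcher re-derived from the eligibility rules with naive loops
bf_risk_set_match <- function(episodes, infections, criteria) {
  onset <- tapply(infections$onset_day, infections$episode_id, min)
  ord <- order(unname(onset), names(onset))
  case_ids <- names(onset)[ord]
  t1s <- unname(onset)[ord]
  used <- character(0)
  pairs <- NULL
  for (k in seq_along(case_ids)) {
    cid <- case_ids[k]
    if (cid %in% used) next
    cr <- episodes[episodes$episode_id == cid, ]
    best_id <- NA_character_; best_age <- Inf
    for (j in seq_len(nrow(episodes))) {
      pj <- episodes[j, ]
      if (pj$episode_id == cid) next
      if (pj$episode_id %in% used) next
      if (pj$episode_id %in% case_ids[seq_len(k)]) next
      if (criteria$require_same_dip_category && pj$dip_category != cr$dip_category) next
      if (criteria$require_same_sex && pj$sex != cr$sex) next
      if (criteria$require_same_caci_stratum && pj$caci_stratum != cr$caci_stratum) next
      if (abs(pj$age - cr$age) > criteria$max_age_difference) next
      if (pj$length_of_stay < t1s[k]) next
      ev <- infections[infections$episode_id == pj$episode_id, ]
      if (nrow(ev) > 0 && min(ev$onset_day) <= t1s[k]) next
      ad <- abs(pj$age - cr$age)
      if (ad < best_age ||
          (ad == best_age && (is.na(best_id) || pj$episode_id < best_id))) {
        best_age <- ad; best_id <- pj$episode_id
      }
    }
    if (!is.na(best_id)) {
      used <- c(used, best_id)
      pairs <- rbind(pairs, data.frame(case_id = cid, control_id = best_id,
                                       t1 = as.integer(t1s[k]),
                                       stringsAsFactors = FALSE))
    }
  }
  pairs
}

# OLS closed form via the normal equations
bf_ols <- function(X, y) as.vector(solve(t(X) %*% X, t(X) %*% y))
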