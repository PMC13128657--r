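#' Mann-Whitney U test
#'
#' Two-sided two-sample rank test. The U statistic is computed from pooled
#' midranks. When both samples have at most 20 observations per side and
#' the pooled data are tie-free, the p-value comes from the exact null
#' distribution of U; otherwise from the tie-corrected normal approximation
#' (no continuity correction). The standardised statistic Z is always
#' reported alongside U, signed so that Z > 0 when `x` tends to exceed `y`.
#'
#' @param x,y Non-empty numeric samples.
#' @return List of class `"mw_test"`: `U` (for `x`), `Z`, `p_value`,
#'   `method` (`"exact"` or `"normal"`), `n_x`, `n_y`.
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0)
    stop_domain("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop_domain("samples must be finite")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2

  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  mu <- nx * ny / 2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
  Z <- if (sigma2 <= 0) 0 else (U - mu) / sqrt(sigma2)

  if (!has_ties && min(nx, ny) <= 20) {
    method <- "exact"
    p <- 2 * min(pwilcox(U, nx, ny), 1 - pwilcox(U - 1, nx, ny))
    p <- min(1, p)
  } else {
    method <- "normal"
    p <- if (sigma2 <= 0) 1 else 2 * pnorm(-abs(Z))
  }
  structure(list(U = U, Z = Z, p_value = p, method = method,
                 n_x = nx, n_y = ny), class = "mw_test")
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees
#' of freedom (a thin wrapper around [stats::kruskal.test()]).
#'
#' @param groups List of two or more non-empty numeric samples.
#' @return List: `H`, `df`, `p_value`, `k`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_domain("need at least two groups")
  if (any(vapply(groups, length, integer(1)) == 0))
    stop_domain("all groups must be non-empty")
  kt <- kruskal.test(groups)
  H <- unname(kt$statistic)
  p <- unname(kt$p.value)
  if (is.nan(H)) { H <- 0; p <- 1 }  # all observations tied
  list(H = H, df = unname(kt$parameter), p_value = p, k = length(groups))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction, df = (r-1)(c-1).
#'
#' @param tab Matrix of non-negative counts, total > 0, no zero row or
#'   column margin.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) <= 0)
    stop_domain("counts must be non-negative with positive total")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_domain("contingency table has a zero margin")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Hodges-Lehmann median difference with distribution-free CI
#'
#' The Hodges-Lehmann estimate of the location difference between two
#' samples: the median of all `n_x * n_y` pairwise differences
#' `x_i - y_j`. The confidence interval is the rank-based (Moses) interval:
#' order statistics of the sorted pairwise-difference set at a cut `K`
#' taken from the Mann-Whitney null distribution at the requested level —
#' exact null quantiles when both sides have at most 20 observations,
#' otherwise the normal approximation `K = floor(m/2 - z * sd_U)`. No
#' interpolation between order statistics is applied (conservative).
#'
#' @param x,y Non-empty numeric samples.
#' @param level Confidence level, default 0.95.
#' @return List of class `"hl_estimate"`: `md`, `ci_low`, `ci_high`,
#'   `level`.
#' @export
hodges_lehmann <- function(x, y, level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0)
    stop_domain("both samples must be non-empty")
  if (level <= 0 || level >= 1) stop_domain("level must lie in (0, 1)")
  nx <- length(x); ny <- length(y); m <- nx * ny
  if (m > 4e7) stop_domain("sample sizes too large for pairwise enumeration")
  d <- sort(as.vector(outer(x, y, "-")))
  md <- median(d)

  alpha <- 1 - level
  if (min(nx, ny) <= 20) {
    K <- qwilcox(alpha / 2, nx, ny)
    if (pwilcox(K, nx, ny) > alpha / 2) K <- K - 1  # keep coverage >= level
    K <- K + 1                                       # 1-based order statistic
  } else {
    K <- floor(m / 2 - qnorm(1 - alpha / 2) * sqrt(nx * ny * (nx + ny + 1) / 12))
  }
  K <- max(1, min(K, floor((m + 1) / 2)))
  structure(list(md = md, ci_low = d[K], ci_high = d[m + 1 - K], level = level),
            class = "hl_estimate")
}

#' Compare cases and controls on one settlement indicator
#'
#' Assembles the full comparison for one indicator: median and quartiles
#' per group (linear interpolation between closest ranks), Mann-Whitney
#' test, and the Hodges-Lehmann median difference with its confidence
#' interval. The sign convention is case minus control, so a negative
#' median difference on the DIP payment differential means cases lose more.
#'
#' @param case_values,control_values Non-empty numeric vectors.
#' @param indicator Label for the indicator being compared.
#' @param level Confidence level for the Hodges-Lehmann interval.
#' @return List of class `"group_comparison"`: `indicator`, per-group
#'   summaries `(median, p25, p75, n)`, `U`, `Z`, `md`, `ci_low`,
#'   `ci_high`, `p_value`, `method`.
#' @export
compare_groups <- function(case_values, control_values,
                           indicator = "indicator", level = 0.95) {
  mw <- mann_whitney(case_values, control_values)
  hl <- hodges_lehmann(case_values, control_values, level = level)
  summ <- function(v) c(median = unname(median(v)),
                        p25 = unname(quantile(v, 0.25)),
                        p75 = unname(quantile(v, 0.75)),
                        n = length(v))
  structure(list(indicator = indicator,
                 case_summary = summ(case_values),
                 control_summary = summ(control_values),
                 U = mw$U, Z = mw$Z, md = hl$md,
                 ci_low = hl$ci_low, ci_high = hl$ci_high,
                 p_value = mw$p_value, method = mw$method, level = level),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 2, ...) {
  fmt <- function(s) sprintf("%.2f (%.2f, %.2f), n=%d",
                             s["median"], s["p25"], s["p75"], as.integer(s["n"]))
  cat(x$indicator, "\n",
      "  cases:    ", fmt(x$case_summary), "\n",
      "  controls: ", fmt(x$control_summary), "\n",
      sprintf("  MD %.2f (95%% CI %.2f, %.2f), Z = %.3f, p = %.4g\n",
              x$md, x$ci_low, x$ci_high, x$Z, x$p_value), sep = "")
  invisible(x)
}

#' Flatten group comparisons into a report table
#'
#' @param comparisons List of `"group_comparison"` objects.
#' @return Data frame, one row per indicator, with `M (P25, P75)` style
#'   summary strings and numeric MD/CI/p columns (rounded half-up to 2
#'   decimals at this reporting boundary).
#' @export
comparison_table <- function(comparisons) {
  row <- function(gc) {
    fmt <- function(s) sprintf("%.2f(%.2f, %.2f)",
                               round_half_up(s["median"]),
                               round_half_up(s["p25"]), round_half_up(s["p75"]))
    data.frame(indicator = gc$indicator,
               n_case = as.integer(gc$case_summary["n"]),
               n_control = as.integer(gc$control_summary["n"]),
               case_m_p25_p75 = fmt(gc$case_summary),
               control_m_p25_p75 = fmt(gc$control_summary),
               Z = round_half_up(gc$Z, 3),
               md = round_half_up(gc$md),
               ci_low = round_half_up(gc$ci_low),
               ci_high = round_half_up(gc$ci_high),
               p_value = gc$p_value,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(comparisons, row))
}
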