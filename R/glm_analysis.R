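#' Build the design for the payment-differential GLM
#'
#' Assembles the modelling frame for the regression of DIP payment
#' differentials on the matched cohort. Outcome: the differential (USD by
#' default). Predictors with their reference levels: sex (male), payment
#' type (non-DIP), age (continuous), CACI stratum (low, i.e. <= 3),
#' invasive device (no), surgery (no), wound classification (no surgery as
#' reference; dummies for classes 0/I/II/III), HAI (no), catheter-associated
#' infection (no), and MDRO type count (0; dummies for 1/2/3+).
#'
#' Factor levels absent from the data are dropped with a warning; a
#' rank-deficient design raises an error naming the collinear columns.
#'
#' @param data Modelling frame with columns `differential_usd`, `sex`,
#'   `payment_type`, `age`, `caci_stratum`, `invasive_device_flag`,
#'   `surgery_flag`, `wound_class`, `hai`, `catheter_associated`,
#'   `mdro_count_bin` (as produced by [matched_model_frame()]).
#' @param outcome Name of the outcome column.
#' @return List of class `"dip_design"`: `formula`, `data` (with factors
#'   releveled), `X` (model matrix), `y`.
#' @export
build_design <- function(data, outcome = "differential_usd") {
  need <- c(outcome, "sex", "payment_type", "age", "caci_stratum",
            "invasive_device_flag", "surgery_flag", "wound_class", "hai",
            "catheter_associated", "mdro_count_bin")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_domain(paste("design is missing column(s):",
                      paste(miss, collapse = ", ")))
  if (any(!complete.cases(data[need])))
    stop_domain("design rows contain missing values")

  d <- data
  d$sex <- factor(d$sex, levels = c("male", "female"))
  d$payment_type <- factor(d$payment_type, levels = c("non-DIP", "DIP"))
  d$caci_stratum <- factor(d$caci_stratum, levels = c("low", "high"))
  d$invasive_device_flag <- factor(ifelse(d$invasive_device_flag, "yes", "no"),
                                   levels = c("no", "yes"))
  d$surgery_flag <- factor(ifelse(d$surgery_flag, "yes", "no"),
                           levels = c("no", "yes"))
  d$wound_class <- factor(as.character(d$wound_class),
                          levels = c("none", "0", "I", "II", "III"))
  d$hai <- factor(ifelse(d$hai, "yes", "no"), levels = c("no", "yes"))
  d$catheter_associated <- factor(ifelse(d$catheter_associated, "yes", "no"),
                                  levels = c("no", "yes"))
  d$mdro_count_bin <- factor(as.character(d$mdro_count_bin),
                             levels = c("0", "1", "2", "3+"))

  terms <- c("sex", "payment_type", "age", "caci_stratum",
             "invasive_device_flag", "surgery_flag", "wound_class", "hai",
             "catheter_associated", "mdro_count_bin")
  for (v in terms) {
    if (!is.factor(d[[v]])) next
    present <- levels(d[[v]])[levels(d[[v]]) %in% unique(as.character(d[[v]]))]
    empty <- setdiff(levels(d[[v]]), present)
    if (length(empty)) {
      warning("dropping empty level(s) of ", v, ": ",
              paste(empty, collapse = ", "))
      d[[v]] <- factor(as.character(d[[v]]), levels = present)
    }
    if (nlevels(d[[v]]) < 2) {
      warning("dropping constant predictor ", v)
      terms <- setdiff(terms, v)
    }
  }

  f <- as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
  X <- model.matrix(f, d)
  y <- d[[outcome]]
  if (sd(y) == 0) stop_domain("outcome is constant; nothing to model")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_domain(paste("rank-deficient design; collinear column(s):",
                      paste(bad, collapse = ", ")))
  }
  structure(list(formula = f, data = d, X = X, y = y, outcome = outcome),
            class = "dip_design")
}

#' Fit the Gaussian identity-link GLM with robust (sandwich) errors
#'
#' Point estimates are the Gaussian identity-link GLM solution (ordinary
#' least squares); standard errors come from the heteroskedasticity-
#' consistent HC1 sandwich estimator, with 95% confidence intervals
#' `B +/- z[0.975] * SE` and two-sided p-values on the normal reference
#' (set `t_reference = TRUE` for t-based inference on n - p degrees of
#' freedom).
#'
#' @param design A `"dip_design"` from [build_design()].
#' @param level Confidence level (default 0.95).
#' @param t_reference Use the t distribution instead of the normal.
#' @return Object of class `"dip_glmfit"`: coefficient table (`term`, `B`,
#'   `robust_se`, `ci_low`, `ci_high`, `p_value`), `n_obs`, `family`,
#'   `vcov_type`, and the underlying `glm` fit.
#' @export
fit_glm <- function(design, level = 0.95, t_reference = FALSE) {
  stopifnot(inherits(design, "dip_design"))
  fit <- glm(design$formula, family = gaussian(), data = design$data)
  if (fit$rank < ncol(design$X))
    stop_domain("singular normal equations: rank-deficient fit")
  B <- coef(fit)
  vc <- sandwich::vcovHC(fit, type = "HC1")
  se <- sqrt(diag(vc))
  q <- if (t_reference) stats::qt(1 - (1 - level) / 2, df = fit$df.residual)
       else qnorm(1 - (1 - level) / 2)
  z <- B / se
  p <- if (t_reference) 2 * stats::pt(-abs(z), df = fit$df.residual)
       else 2 * pnorm(-abs(z))
  tab <- data.frame(term = names(B), B = unname(B), robust_se = unname(se),
                    ci_low = unname(B - q * se), ci_high = unname(B + q * se),
                    p_value = unname(p), stringsAsFactors = FALSE)
  structure(list(coefficients = tab, n_obs = length(design$y),
                 family = "gaussian(identity)", vcov_type = "HC1",
                 level = level, fit = fit),
            class = "dip_glmfit")
}

#' @export
print.dip_glmfit <- function(x, ...) {
  cat(sprintf("Gaussian identity-link GLM of %s, %s robust SEs, n = %d\n",
              deparse(x$fit$formula[[2]]), x$vcov_type, x$n_obs))
  tab <- x$coefficients
  tab[, -1] <- lapply(tab[, -1], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Modelling frame for the matched cohort
#'
#' Stacks the matched cases and controls of a `"matched_cohort"` into one
#' modelling frame: settlement columns (USD at `rate`), CACI stratum,
#' infection-profile classifications, and an `hai` indicator (`TRUE` for
#' cases). Controls that never acquired an infection carry the null
#' profile.
#'
#' @param episodes Episode table with `caci_stratum` and settlement
#'   columns (or they are added here).
#' @param infections Infection-event table.
#' @param cohort A `"matched_cohort"`.
#' @param rate CNY per USD.
#' @return Data frame, one row per matched episode.
#' @export
matched_model_frame <- function(episodes, infections, cohort, rate = 7.12) {
  if (!"caci_stratum" %in% names(episodes)) episodes <- add_caci(episodes)
  if (!"differential_usd" %in% names(episodes))
    episodes <- add_settlement(episodes, rate)
  ids <- c(cohort$pairs$case_id, cohort$pairs$control_id)
  sub <- episodes[match(ids, episodes$episode_id), , drop = FALSE]
  prof <- infection_profiles(sub, infections[infections$episode_id %in% ids, ,
                                             drop = FALSE])
  sub <- cbind(sub, prof[, c("frequency", "frequency_bin",
                             "catheter_associated", "mdro_type_count",
                             "mdro_count_bin", "ssi_wound_class")])
  sub$hai <- sub$episode_id %in% cohort$pairs$case_id
  rownames(sub) <- NULL
  sub
}

#' Fit the payment-differential GLM on a matched cohort
#'
#' Convenience wrapper: builds the modelling frame, the design, and fits
#' the robust Gaussian GLM of the DIP payment differential.
#'
#' @inheritParams matched_model_frame
#' @param level Confidence level.
#' @return A `"dip_glmfit"`.
#' @export
fit_differential_glm <- function(episodes, infections, cohort, rate = 7.12,
                                 level = 0.95) {
  mf <- matched_model_frame(episodes, infections, cohort, rate)
  fit_glm(build_design(mf), level = level)
}
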