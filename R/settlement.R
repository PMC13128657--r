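#' DIP payment differential
#'
#' The settlement indicator at the heart of the analysis: the DIP standard
#' payment for the episode's category minus the actual hospitalization cost.
#' Positive values are a surplus for the hospital, negative values a loss.
#' Computed for every discharge regardless of whether the episode was
#' settled under DIP.
#'
#' @param standard_payment DIP standard payment (currency units).
#' @param actual_cost Actual hospitalization cost (same units, >= 0).
#' @return `standard_payment - actual_cost`, vectorised.
#' @export
dip_differential <- function(standard_payment, actual_cost) {
  if (any(!is.finite(standard_payment)) || any(!is.finite(actual_cost)))
    stop_domain("payment and cost must be finite")
  if (any(actual_cost < 0))
    stop_domain("actual_cost must be non-negative")
  standard_payment - actual_cost
}

#' HAI incidence rate
#'
#' Newly diagnosed hospital-acquired infection cases (patients, not events)
#' over all hospitalized patients in the same period, times 100. Reported
#' rounded half-up to `digits` decimals; pass `digits = NULL` for the
#' full-precision value used in downstream arithmetic.
#'
#' @param n_cases Number of infected patients (0 <= n_cases <= n_patients).
#' @param n_patients Total hospitalized patients (> 0).
#' @param digits Reporting precision; `NULL` for unrounded.
#' @return Percentage.
#' @examples
#' incidence_rate(803, 205569)  # 0.39
#' @export
incidence_rate <- function(n_cases, n_patients, digits = 2) {
  if (any(n_patients <= 0)) stop_domain("n_patients must be positive")
  if (any(n_cases < 0) || any(n_cases > n_patients))
    stop_domain("n_cases must lie in [0, n_patients]")
  rate <- 100 * n_cases / n_patients
  if (is.null(digits)) rate else round_half_up(rate, digits)
}

#' Convert CNY amounts to USD
#'
#' @param amount_cny Amount(s) in CNY.
#' @param rate Exchange rate, CNY per USD; the 2024 annual average is 7.12.
#' @return Amount(s) in USD.
#' @export
convert_currency <- function(amount_cny, rate = 7.12) {
  if (length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop_domain("exchange rate must be a single positive number")
  amount_cny / rate
}

#' Classify the infections of one episode
#'
#' Collapses an episode's infection events into the stratification variables
#' used in the classification analyses: event frequency (binned 0/1/2/3+),
#' whether any event was catheter-associated (CLABSI, VAP or CAUTI), the
#' number of distinct multidrug-resistant organism (MDRO) types across the
#' whole stay (set union over events, binned 0/1/2/3+), and the surgical
#' wound contamination class when any event is a surgical site infection.
#'
#' @param episode One-row episode data frame (needs `episode_id`,
#'   `wound_class`).
#' @param events Infection-event rows for this episode (possibly none);
#'   needs `episode_id`, `site`, `mdro_types` (semicolon-joined).
#' @return One-row data frame: `episode_id`, `frequency` (integer count),
#'   `frequency_bin`, `catheter_associated`, `mdro_type_count` (integer),
#'   `mdro_count_bin`, `ssi_wound_class`.
#' @export
classify_infections <- function(episode, events) {
  if (nrow(events) > 0 && any(events$episode_id != episode$episode_id))
    stop_domain("infection event does not belong to this episode",
                class = "dip_integrity_error")
  n_ev <- nrow(events)
  catheter <- n_ev > 0 && any(events$site %in% c("CLABSI", "VAP", "CAUTI"))
  mdro <- if (n_ev == 0) character() else
    unique(unlist(strsplit(events$mdro_types, ";", fixed = TRUE)))
  mdro <- mdro[nzchar(mdro)]
  has_ssi <- n_ev > 0 && any(events$site == "SSI")
  data.frame(
    episode_id = episode$episode_id,
    frequency = n_ev,
    frequency_bin = bin_3plus(n_ev),
    catheter_associated = catheter,
    mdro_type_count = length(mdro),
    mdro_count_bin = bin_3plus(length(mdro)),
    ssi_wound_class = if (has_ssi) as.character(episode$wound_class) else "non-SSI",
    stringsAsFactors = FALSE
  )
}

bin_3plus <- function(n) ifelse(n >= 3, "3+", as.character(n))

#' Infection profiles for a whole cohort
#'
#' Vectorised [classify_infections()] over every episode; uninfected
#' episodes get the null profile (frequency 0, no catheter association,
#' 0 MDRO types, `"non-SSI"`).
#'
#' @param episodes Episode table.
#' @param infections Infection-event table; every `episode_id` must exist in
#'   `episodes`.
#' @return Data frame with one profile row per episode, in episode order.
#' @export
infection_profiles <- function(episodes, infections) {
  check_referential(episodes, infections)
  split_ev <- split(seq_len(nrow(infections)), infections$episode_id)
  out <- lapply(seq_len(nrow(episodes)), function(i) {
    idx <- split_ev[[as.character(episodes$episode_id[i])]]
    classify_infections(episodes[i, , drop = FALSE],
                        infections[idx %||% integer(0), , drop = FALSE])
  })
  do.call(rbind, out)
}

check_referential <- function(episodes, infections) {
  orphan <- setdiff(infections$episode_id, episodes$episode_id)
  if (length(orphan))
    stop_domain(paste0("infection events reference unknown episode(s): ",
                       paste(utils::head(orphan, 5), collapse = ", ")),
                class = "dip_integrity_error")
  invisible(TRUE)
}

#' Settlement columns for an episode table
#'
#' Adds the DIP payment differential in CNY and, at the configured exchange
#' rate, USD-converted cost, diagnostic-cost and differential columns used
#' by the reporting layer.
#'
#' @param episodes Episode table with `hospitalization_cost_cny`,
#'   `diagnostic_cost_cny` and `dip_standard_payment_cny`.
#' @param rate CNY per USD.
#' @return `episodes` with `differential_cny`, `hospitalization_cost_usd`,
#'   `diagnostic_cost_usd`, `differential_usd` appended.
#' @export
add_settlement <- function(episodes, rate = 7.12) {
  episodes$differential_cny <- dip_differential(episodes$dip_standard_payment_cny,
                                                episodes$hospitalization_cost_cny)
  episodes$hospitalization_cost_usd <- convert_currency(episodes$hospitalization_cost_cny, rate)
  episodes$diagnostic_cost_usd <- convert_currency(episodes$diagnostic_cost_cny, rate)
  episodes$differential_usd <- convert_currency(episodes$differential_cny, rate)
  episodes
}
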