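#' Direct medical costs of snakebite (USD)
#'
#' Bottom-up costing over patients reaching conventional care: hospitalization
#' (length of stay by antivenom indication), antivenom treatment courses plus
#' their logistics, adverse-drug-reaction management, and amputation
#' procedures. Unit costs are in local currency and converted to USD by the
#' country's exchange rate.
#'
#' @param outcome A `tree_outcome` from [run_tree].
#' @param cp A [country_parameters] object.
#' @param values Optional parameter override as in [run_tree].
#' @return Named list: `hospitalization`, `antivenom`, `adr_management`,
#'   `amputation` (USD).
#' @export
direct_medical_costs <- function(outcome, cp, values = NULL) {
  v <- if (is.null(values)) base_values(cp) else values
  if (any(v[cost_value_names()] < 0)) {
    stop("direct_medical_costs: negative unit cost", call. = FALSE)
  }
  hosp_days <- outcome$indicated_conventional * v[["los_indicated"]] +
    outcome$not_indicated_conventional * v[["los_not_indicated"]]
  fx <- cp$exchange_rate
  list(
    hospitalization = hosp_days * v[["cost_hospital_day"]] / fx,
    antivenom = outcome$treated_antivenom *
      (v[["cost_antivenom_course"]] + v[["cost_antivenom_logistics"]]) / fx,
    adr_management = outcome$adr_cases * v[["cost_adr_management"]] / fx,
    amputation = outcome$amputations * v[["cost_amputation"]] / fx
  )
}

cost_value_names <- function() {
  c("cost_hospital_day", "cost_antivenom_course", "cost_antivenom_logistics",
    "cost_adr_management", "cost_amputation", "cost_transport",
    "cost_food_person_day")
}

#' Direct non-medical costs of snakebite (USD)
#'
#' Transportation per conventional-care episode and additional food for the
#' victim and one accompanying relative over the hospital stay.
#'
#' @inheritParams direct_medical_costs
#' @return Named list: `transport`, `food` (USD).
#' @export
direct_nonmedical_costs <- function(outcome, cp, values = NULL) {
  v <- if (is.null(values)) base_values(cp) else values
  if (any(v[cost_value_names()] < 0)) {
    stop("direct_nonmedical_costs: negative unit cost", call. = FALSE)
  }
  fx <- cp$exchange_rate
  person_days <- 2 * (outcome$indicated_conventional * v[["los_indicated"]] +
                        outcome$not_indicated_conventional * v[["los_not_indicated"]])
  list(
    transport = outcome$conventional_total * v[["cost_transport"]] / fx,
    food = person_days * v[["cost_food_person_day"]] / fx
  )
}

#' Productivity loss during the snakebite episode (USD)
#'
#' Human-capital valuation of the time the victim and one accompanying
#' relative lose during the hospital stay: person-days times daily income,
#' where daily income is GDP per capita divided by the configured divisor
#' (365 calendar days by default).
#'
#' @inheritParams direct_medical_costs
#' @return USD.
#' @export
episode_productivity_loss <- function(outcome, cp, values = NULL) {
  v <- if (is.null(values)) base_values(cp) else values
  daily_income <- cp$gdp_per_capita / cp$daily_income_divisor
  person_days <- 2 * (outcome$indicated_conventional * v[["los_indicated"]] +
                        outcome$not_indicated_conventional * v[["los_not_indicated"]])
  person_days * daily_income
}

#' Productivity loss from one premature death (USD)
#'
#' Human-capital approach: GDP per capita over the remaining working years
#' from the age at death to retirement, with each year's income growing at the
#' GDP growth rate and discounted at the discount rate (first lost year
#' undiscounted). No loss accrues at or beyond retirement age. Remaining years
#' are truncated to whole years.
#'
#' @param age_at_death Age at death (years, >= 0).
#' @param gdp_per_capita GDP per capita (USD).
#' @param growth Annual GDP per capita growth rate (fraction).
#' @param discount Annual discount rate (fraction).
#' @param retirement_age Retirement age (years).
#' @return Discounted productivity loss in USD (0 at or beyond retirement).
#' @export
#' @examples
#' premature_death_loss(50, 1000, 0, 0.03)   # 8786.11
#' premature_death_loss(30, 1000, 0.03, 0.03) # 30000: growth cancels discount
premature_death_loss <- function(age_at_death, gdp_per_capita, growth,
                                 discount, retirement_age = 60) {
  if (any(age_at_death < 0)) {
    stop("premature_death_loss: age must be >= 0", call. = FALSE)
  }
  vapply(age_at_death, function(a) {
    n <- floor(retirement_age - a)
    if (n <= 0) return(0)
    ratio <- (1 + growth) / (1 + discount)
    gdp_per_capita * sum(ratio^(0:(n - 1)))
  }, numeric(1))
}

#' Societal-perspective cost breakdown for one country (USD)
#'
#' Assembles direct medical, direct non-medical and indirect costs. Indirect
#' costs combine episode productivity losses with premature-death losses,
#' where each stratum's deaths are valued at that stratum's mean age at death.
#'
#' @inheritParams direct_medical_costs
#' @param ptsd_cost PTSD productivity losses (USD) to fold into indirect
#'   costs; non-zero only in the PTSD scenario.
#' @return A list of class `cost_breakdown` with components `hospitalization`,
#'   `antivenom`, `adr_management`, `amputation`, `transport`, `food`,
#'   `productivity_episode`, `productivity_premature_death`,
#'   `productivity_ptsd` and subtotals `direct_medical`, `direct_nonmedical`,
#'   `indirect`, `total` (all USD).
#' @export
total_costs <- function(outcome, cp, values = NULL, ptsd_cost = 0) {
  v <- if (is.null(values)) base_values(cp) else values
  med <- direct_medical_costs(outcome, cp, v)
  nonmed <- direct_nonmedical_costs(outcome, cp, v)
  episode <- episode_productivity_loss(outcome, cp, v)
  premature <- sum(outcome$strata$deaths *
                     premature_death_loss(outcome$strata$mean_age_at_death,
                                          cp$gdp_per_capita,
                                          v[["gdp_growth"]],
                                          v[["discount_rate"]],
                                          cp$retirement_age))
  out <- c(med, nonmed,
           list(productivity_episode = episode,
                productivity_premature_death = premature,
                productivity_ptsd = ptsd_cost))
  out$direct_medical <- med$hospitalization + med$antivenom +
    med$adr_management + med$amputation
  out$direct_nonmedical <- nonmed$transport + nonmed$food
  out$indirect <- episode + premature + ptsd_cost
  out$total <- out$direct_medical + out$direct_nonmedical + out$indirect
  structure(out, class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown> (USD)\n")
  cat(sprintf("  direct medical     : %14.2f\n", x$direct_medical))
  cat(sprintf("  direct non-medical : %14.2f\n", x$direct_nonmedical))
  cat(sprintf("  indirect           : %14.2f\n", x$indirect))
  cat(sprintf("  total              : %14.2f\n", x$total))
  invisible(x)
}
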