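#' PTSD scenario specification
#'
#' Post-traumatic stress disorder is modelled as an additional mental
#' disability: it occurs in a fraction of survivors of systemic envenoming
#' (base case 8%, plausible range 2-18%) and in a smaller fraction of victims
#' without envenoming (base case 2%). Each case carries a disability weight
#' over a duration and loses a fraction of daily income over that duration.
#' Weight/duration/productivity defaults are reconstructions, configurable.
#'
#' @param p_after_envenoming Probability of PTSD in survivors of envenoming
#'   (a [param_value] or scalar/list coercible to one).
#' @param p_after_no_envenoming Probability of PTSD in non-envenomed victims.
#' @param weight Disability weight in (0, 1).
#' @param duration Duration of PTSD in years.
#' @param productivity_loss_fraction Fraction of daily income lost while
#'   symptomatic.
#' @return A list of class `ptsd_spec`.
#' @export
ptsd_spec <- function(p_after_envenoming = param_value(0.08, 0.02, 0.18, "beta"),
                      p_after_no_envenoming = param_value(0.02),
                      weight = 0.158, duration = 1,
                      productivity_loss_fraction = 0.25) {
  p_env <- as_param_value(p_after_envenoming, "probability", "p_after_envenoming")
  p_noenv <- as_param_value(p_after_no_envenoming, "probability",
                            "p_after_no_envenoming")
  if (!(weight > 0 && weight < 1)) stop("ptsd_spec: weight must be in (0, 1)",
                                        call. = FALSE)
  if (duration <= 0) stop("ptsd_spec: duration must be > 0", call. = FALSE)
  if (productivity_loss_fraction < 0 || productivity_loss_fraction > 1) {
    stop("ptsd_spec: productivity_loss_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(p_after_envenoming = p_env,
                 p_after_no_envenoming = p_noenv,
                 weight = weight, duration = duration,
                 productivity_loss_fraction = productivity_loss_fraction),
            class = "ptsd_spec")
}

#' Expected PTSD cases
#'
#' @param outcome A `tree_outcome`.
#' @param spec A [ptsd_spec].
#' @param p_env,p_noenv Optional numeric overrides of the base-case
#'   probabilities in `spec` (used by the sensitivity analyses).
#' @return Expected cases: envenoming survivors times the post-envenoming
#'   probability plus non-envenomed victims times the no-envenoming
#'   probability.
#' @export
ptsd_cases <- function(outcome, spec = ptsd_spec(), p_env = NULL, p_noenv = NULL) {
  p1 <- if (is.null(p_env)) spec$p_after_envenoming$point else p_env
  p2 <- if (is.null(p_noenv)) spec$p_after_no_envenoming$point else p_noenv
  p1 * outcome$survivors_envenomed + p2 * outcome$not_indicated
}

#' PTSD disease and economic burden
#'
#' @param cases Expected PTSD cases.
#' @param spec A [ptsd_spec].
#' @param cp A [country_parameters] object (for daily income).
#' @return List with `yld` (years, cases x weight x duration) and
#'   `productivity_cost` (USD, cases x duration x 365 x daily income x loss
#'   fraction).
#' @export
ptsd_burden <- function(cases, spec, cp) {
  daily_income <- cp$gdp_per_capita / cp$daily_income_divisor
  list(
    yld = cases * spec$weight * spec$duration,
    productivity_cost = cases * spec$duration * 365 * daily_income *
      spec$productivity_loss_fraction
  )
}
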