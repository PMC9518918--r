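#' Demographic profile of snakebite victims
#'
#' Describes how victims split across sex/age strata and the mean age at death
#' within each stratum. Stratum shares drive the disaggregation of all
#' expected counts; mean age at death drives years of life lost and
#' premature-death productivity losses.
#'
#' @param strata A data frame with columns `sex` (`"female"`/`"male"`),
#'   `age_low`, `age_high` (years, `age_low < age_high`), `share`
#'   (fractions summing to 1) and `mean_age_at_death` (years, inside the
#'   stratum's age band).
#' @return A validated data frame of class `age_sex_profile`.
#' @export
#' @examples
#' age_sex_profile(data.frame(
#'   sex = c("female", "male"), age_low = c(0, 0), age_high = c(99, 99),
#'   share = c(0.4, 0.6), mean_age_at_death = c(38, 35)))
age_sex_profile <- function(strata) {
  strata <- as.data.frame(strata)
  required <- c("sex", "age_low", "age_high", "share", "mean_age_at_death")
  missing <- setdiff(required, names(strata))
  if (length(missing) > 0) {
    stop("age_sex_profile: missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(strata$sex %in% c("female", "male"))) {
    stop("age_sex_profile: sex must be 'female' or 'male'", call. = FALSE)
  }
  if (abs(sum(strata$share) - 1) > 1e-9) {
    stop("age_sex_profile: stratum shares must sum to 1 (got ",
         sum(strata$share), ")", call. = FALSE)
  }
  if (any(strata$share < 0)) stop("age_sex_profile: negative share", call. = FALSE)
  if (any(strata$age_low >= strata$age_high)) {
    stop("age_sex_profile: age_low must be < age_high", call. = FALSE)
  }
  # strata of the same sex must not overlap in age
  for (s in c("female", "male")) {
    sub <- strata[strata$sex == s, , drop = FALSE]
    if (nrow(sub) > 1) {
      sub <- sub[order(sub$age_low), ]
      if (any(sub$age_low[-1] < sub$age_high[-nrow(sub)])) {
        stop("age_sex_profile: overlapping age strata for sex ", s, call. = FALSE)
      }
    }
  }
  bad <- strata$mean_age_at_death < strata$age_low |
    strata$mean_age_at_death > strata$age_high
  if (any(bad)) {
    stop("age_sex_profile: mean_age_at_death outside its stratum's age band",
         call. = FALSE)
  }
  class(strata) <- c("age_sex_profile", "data.frame")
  strata
}

# Names of tree/cost/macro parameters held as param_value objects, with the
# validation kind for each.
country_param_kinds <- function() {
  c(incidence               = "positive",
    p_conventional_first    = "probability",
    p_switch_to_conventional = "probability",
    p_indicated             = "probability",
    antivenom_courses       = "positive",
    p_adr                   = "probability",
    p_death_treated         = "probability",
    rr_death_untreated      = "relative_risk",
    p_amputation_survivor   = "probability",
    los_indicated           = "positive",
    los_not_indicated       = "positive",
    cost_hospital_day       = "positive",
    cost_antivenom_course   = "positive",
    cost_antivenom_logistics = "positive",
    cost_adr_management     = "positive",
    cost_amputation         = "positive",
    cost_transport          = "positive",
    cost_food_person_day    = "positive",
    gdp_growth              = "real",
    discount_rate           = "real")
}

#' Full input parameter set for one country
#'
#' Bundles demography, decision-tree probabilities, unit costs (local
#' currency), and macro-economic inputs for one country. Uncertain entries are
#' [param_value] objects (point estimate plus plausible range); scalars are
#' promoted to fixed parameters.
#'
#' Defaults follow standard burden-of-disease practice: relative risk of death
#' without antivenom 2.33 (1.26-4.06, lognormal), discount rate 3% (varied
#' 0-6% in one-way sensitivity analysis only), retirement age 60.
#'
#' @param name Country label.
#' @param population Total population (persons).
#' @param profile An [age_sex_profile] (or data frame coercible to one).
#' @param incidence Snakebite victims per 100,000 population per year.
#'   Exactly one of `incidence` and `victims` must be supplied.
#' @param victims Annual number of snakebite victims.
#' @param exchange_rate Local currency units per 2019 USD.
#' @param gdp_per_capita GDP per capita, 2019 USD.
#' @param retirement_age Retirement age (years); productivity losses from
#'   premature death stop here.
#' @param daily_income_divisor Days per year used to convert GDP per capita to
#'   daily income (calendar days by default).
#' @param ... The remaining tree, length-of-stay, unit-cost and macro
#'   parameters named in `country_param_kinds()`, each a scalar, a
#'   `list(point=, low=, high=, family=)`, or a [param_value].
#' @return An object of class `country_parameters`.
#' @export
country_parameters <- function(name, population, profile,
                               incidence = NULL, victims = NULL,
                               exchange_rate, gdp_per_capita,
                               retirement_age = 60,
                               daily_income_divisor = 365, ...) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(population) || population <= 0) {
    stop("country_parameters: population must be > 0", call. = FALSE)
  }
  population <- as.numeric(population)
  if (!is.numeric(exchange_rate) || exchange_rate <= 0) {
    stop("country_parameters: exchange_rate must be > 0", call. = FALSE)
  }
  if (!is.numeric(gdp_per_capita) || gdp_per_capita <= 0) {
    stop("country_parameters: gdp_per_capita must be > 0", call. = FALSE)
  }
  if (!is.numeric(retirement_age) || retirement_age <= 0) {
    stop("country_parameters: retirement_age must be > 0", call. = FALSE)
  }
  profile <- if (inherits(profile, "age_sex_profile")) profile else age_sex_profile(profile)

  supplied <- list(...)
  kinds <- country_param_kinds()

  # incidence/victims: exactly one given, the other derived
  if (is.null(incidence) == is.null(victims)) {
    stop("country_parameters: supply exactly one of 'incidence' and 'victims'",
         call. = FALSE)
  }
  if (is.null(incidence)) {
    inc_pv <- as_param_value(victims, "positive", "victims")
    scale <- 1e5 / population
    incidence <- param_value(inc_pv$point * scale, inc_pv$low * scale,
                             inc_pv$high * scale, inc_pv$family)
  } else {
    incidence <- as_param_value(incidence, "positive", "incidence")
  }
  supplied$incidence <- incidence

  # defaults for optional parameters
  if (is.null(supplied$rr_death_untreated)) {
    supplied$rr_death_untreated <- param_value(2.33, 1.26, 4.06, "lognormal")
  }
  if (is.null(supplied$discount_rate)) {
    # range used by one-way SA; the PSA does not sample the discount rate
    supplied$discount_rate <- param_value(0.03, 0, 0.06, "uniform")
  }

  unknown <- setdiff(names(supplied), names(kinds))
  if (length(unknown) > 0) {
    stop("country_parameters: unknown parameters: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(names(kinds), names(supplied))
  if (length(missing) > 0) {
    stop("country_parameters: missing required parameters: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params <- lapply(names(kinds), function(nm) {
    as_param_value(supplied[[nm]], kinds[[nm]], nm)
  })
  names(params) <- names(kinds)

  obj <- structure(list(
    name = name,
    population = population,
    profile = profile,
    params = params,
    exchange_rate = exchange_rate,
    gdp_per_capita = gdp_per_capita,
    retirement_age = retirement_age,
    daily_income_divisor = daily_income_divisor
  ), class = "country_parameters")
  obj
}

#' @export
print.country_parameters <- function(x, ...) {
  cat(sprintf("<country_parameters> %s\n", x$name))
  cat(sprintf("  population  : %s\n", format(x$population, big.mark = ",")))
  cat(sprintf("  incidence   : %.2f per 100,000/yr (victims ~ %s)\n",
              x$params$incidence$point,
              format(round(expected_victims(x$params$incidence$point,
                                            x$population)), big.mark = ",")))
  cat(sprintf("  strata      : %d; retirement age %g; discount %.1f%%\n",
              nrow(x$profile), x$retirement_age,
              100 * x$params$discount_rate$point))
  n_unc <- sum(vapply(x$params, function(p) p$family != "fixed", logical(1)))
  cat(sprintf("  parameters  : %d (%d uncertain)\n", length(x$params), n_unc))
  invisible(x)
}

#' Annual number of snakebite victims (point estimate)
#'
#' @param cp A `country_parameters` object.
#' @return Expected victims per year at base-case incidence.
#' @export
country_victims <- function(cp) {
  expected_victims(cp$params$incidence$point, cp$population)
}

# Base-case (point-estimate) values of all parameters as a named numeric vector.
base_values <- function(cp) {
  vapply(cp$params, function(p) p$point, numeric(1))
}

# ---------------------------------------------------------------------------
# Configuration files (YAML canonical, JSON accepted)

config_schema_version <- 1L

top_level_keys <- function() {
  c("schema_version", "name", "population", "incidence", "victims", "profile",
    "probabilities", "antivenom_courses", "lengths_of_stay", "unit_costs",
    "economics")
}

#' Read and validate a country configuration file
#'
#' Reads a YAML (canonical) or JSON country parameter file, validates every
#' entry, fills documented defaults (discount rate 3%, retirement age 60,
#' relative risk of death untreated 2.33 with range 1.26-4.06) and derives
#' whichever of incidence/victims was not given. Unknown keys are errors. The
#' machine-readable key list ships as `country_schema.json` in the package's
#' `extdata` directory.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated [country_parameters] object.
#' @export
load_country_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  country_parameters_from_config(cfg, label = path)
}

#' Build country parameters from an already-parsed configuration list
#'
#' @param cfg A list with the structure documented in
#'   `system.file("extdata", "country_schema.json", package = "snakeburden")`.
#' @param label Source label used in error messages.
#' @return A validated [country_parameters] object.
#' @export
country_parameters_from_config <- function(cfg, label = "config") {
  unknown <- setdiff(names(cfg), top_level_keys())
  if (length(unknown) > 0) {
    stop(sprintf("%s: unknown configuration keys: %s", label,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  need <- function(key, where = cfg, group = NULL) {
    if (is.null(where[[key]])) {
      stop(sprintf("%s: missing required key '%s'", label,
                   if (is.null(group)) key else paste0(group, ".", key)),
           call. = FALSE)
    }
    where[[key]]
  }
  sv <- need("schema_version")
  if (!identical(as.integer(sv), config_schema_version)) {
    stop(sprintf("%s: unsupported schema_version %s (expected %d)",
                 label, sv, config_schema_version), call. = FALSE)
  }
  name <- need("name")
  population <- need("population")

  profile_cfg <- need("profile")
  profile <- age_sex_profile(do.call(rbind, lapply(profile_cfg, function(s) {
    allowed <- c("sex", "age_low", "age_high", "share", "mean_age_at_death")
    unknown <- setdiff(names(s), allowed)
    if (length(unknown) > 0) {
      stop(sprintf("%s: unknown profile keys: %s", label,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    as.data.frame(s[allowed])
  })))

  probs_cfg <- need("probabilities")
  prob_keys <- c("p_conventional_first", "p_switch_to_conventional",
                 "p_indicated", "p_adr", "p_death_treated",
                 "rr_death_untreated", "p_amputation_survivor")
  unknown <- setdiff(names(probs_cfg), prob_keys)
  if (length(unknown) > 0) {
    stop(sprintf("%s: unknown keys under probabilities: %s", label,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }

  los_cfg <- need("lengths_of_stay")
  los_keys <- c("los_indicated", "los_not_indicated")
  unknown <- setdiff(names(los_cfg), los_keys)
  if (length(unknown) > 0) {
    stop(sprintf("%s: unknown keys under lengths_of_stay: %s", label,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }

  cost_cfg <- need("unit_costs")
  cost_map <- c(hospital_day = "cost_hospital_day",
                antivenom_course = "cost_antivenom_course",
                antivenom_logistics = "cost_antivenom_logistics",
                adr_management = "cost_adr_management",
                amputation = "cost_amputation",
                transport = "cost_transport",
                food_person_day = "cost_food_person_day")
  unknown <- setdiff(names(cost_cfg), names(cost_map))
  if (length(unknown) > 0) {
    stop(sprintf("%s: unknown keys under unit_costs: %s", label,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }

  econ_cfg <- need("economics")
  econ_keys <- c("exchange_rate", "gdp_per_capita", "gdp_growth",
                 "discount_rate", "retirement_age", "daily_income_divisor")
  unknown <- setdiff(names(econ_cfg), econ_keys)
  if (length(unknown) > 0) {
    stop(sprintf("%s: unknown keys under economics: %s", label,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }

  # incidence/victims consistency: both given is allowed only if consistent
  incidence <- cfg$incidence
  victims <- cfg$victims
  if (!is.null(incidence) && !is.null(victims)) {
    inc_pt <- if (is.list(incidence)) incidence$point else incidence
    vic_pt <- if (is.list(victims)) victims$point else victims
    implied <- inc_pt * population / 1e5
    if (abs(implied - vic_pt) / max(vic_pt, 1) > 0.005) {
      stop(sprintf(
        "%s: incidence and victims are inconsistent (incidence implies %.0f victims, got %.0f)",
        label, implied, vic_pt), call. = FALSE)
    }
    victims <- NULL  # prefer incidence as canonical
  }

  args <- c(
    list(name = name, population = population, profile = profile,
         incidence = incidence, victims = victims,
         exchange_rate = need("exchange_rate", econ_cfg, "economics"),
         gdp_per_capita = need("gdp_per_capita", econ_cfg, "economics")),
    probs_cfg,
    los_cfg,
    stats::setNames(cost_cfg, cost_map[names(cost_cfg)]),
    list(antivenom_courses = need("antivenom_courses"),
         gdp_growth = need("gdp_growth", econ_cfg, "economics"))
  )
  if (!is.null(econ_cfg$discount_rate)) args$discount_rate <- econ_cfg$discount_rate
  if (!is.null(econ_cfg$retirement_age)) args$retirement_age <- econ_cfg$retirement_age
  if (!is.null(econ_cfg$daily_income_divisor)) {
    args$daily_income_divisor <- econ_cfg$daily_income_divisor
  }
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(country_parameters, args)
}

#' Write a country configuration file
#'
#' Serializes a [country_parameters] object back to YAML so that
#' `load_country_config(write_country_config(cp, f))` round-trips all fields
#' exactly.
#'
#' @param cp A `country_parameters` object.
#' @param path Output file path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_country_config <- function(cp, path) {
  p <- cp$params
  cfg <- list(
    schema_version = config_schema_version,
    name = cp$name,
    population = cp$population,
    incidence = param_value_to_config(p$incidence),
    profile = lapply(seq_len(nrow(cp$profile)), function(i) {
      as.list(cp$profile[i, c("sex", "age_low", "age_high", "share",
                              "mean_age_at_death")])
    }),
    probabilities = lapply(p[c("p_conventional_first", "p_switch_to_conventional",
                               "p_indicated", "p_adr", "p_death_treated",
                               "rr_death_untreated", "p_amputation_survivor")],
                           param_value_to_config),
    antivenom_courses = param_value_to_config(p$antivenom_courses),
    lengths_of_stay = lapply(p[c("los_indicated", "los_not_indicated")],
                             param_value_to_config),
    unit_costs = list(
      hospital_day = param_value_to_config(p$cost_hospital_day),
      antivenom_course = param_value_to_config(p$cost_antivenom_course),
      antivenom_logistics = param_value_to_config(p$cost_antivenom_logistics),
      adr_management = param_value_to_config(p$cost_adr_management),
      amputation = param_value_to_config(p$cost_amputation),
      transport = param_value_to_config(p$cost_transport),
      food_person_day = param_value_to_config(p$cost_food_person_day)
    ),
    economics = list(
      exchange_rate = cp$exchange_rate,
      gdp_per_capita = cp$gdp_per_capita,
      gdp_growth = param_value_to_config(p$gdp_growth),
      discount_rate = param_value_to_config(p$discount_rate),
      retirement_age = cp$retirement_age,
      daily_income_divisor = cp$daily_income_divisor
    )
  )
  # emit doubles at 17 significant digits so read -> write -> read is exact
  fmt_num <- function(x) {
    if (length(x) == 1L && is.finite(x)) {
      structure(sprintf("%.17g", x), class = "verbatim")
    } else {
      x
    }
  }
  yaml::write_yaml(cfg, path, handlers = list(numeric = fmt_num))
  invisible(path)
}

#' Load all country configurations of a region
#'
#' @param paths Character vector of country configuration files, or a single
#'   region YAML file with keys `name` and `countries` (paths relative to the
#'   region file).
#' @return A named list of [country_parameters].
#' @export
load_region_configs <- function(paths) {
  if (length(paths) == 1L && grepl("\\.ya?ml$", paths) ) {
    cfg <- yaml::read_yaml(paths)
    if (!is.null(cfg$countries)) {
      paths <- file.path(dirname(paths), unlist(cfg$countries))
    }
  }
  countries <- lapply(paths, load_country_config)
  stats::setNames(countries, vapply(countries, `[[`, character(1), "name"))
}
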