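#' Synthetic country archetypes
#'
#' Three archetypes spanning the realistic spread of national snakebite
#' settings, anchored to published extremes: incidence from about 10 to 200
#' per 100,000 and antivenom access from a few percent to essentially
#' complete. `high_access_low_incidence` emulates well-supplied, low-burden
#' settings; `low_access_high_incidence` the opposite; `mid` sits between.
#'
#' @return Named list of archetype definitions (value ranges per parameter).
#' @export
country_archetypes <- function() {
  base <- list(
    log10_population = c(6.7, 8.2),
    p_switch_to_conventional = c(0.2, 0.6),
    p_indicated = c(0.1, 0.9),
    p_adr = c(0.05, 0.35),
    p_amputation_survivor = c(0.001, 0.05),
    los_indicated = c(3, 7),
    los_not_indicated = c(1, 3),
    antivenom_course_usd = c(60, 600),
    logistics_fraction = c(0.1, 0.3),
    adr_management_usd = c(20, 150),
    amputation_usd = c(300, 2000),
    transport_usd = c(5, 40),
    food_usd = c(1, 8),
    log10_exchange_rate = c(0.5, 4.4),
    gdp_growth = c(0.02, 0.07),
    child_share = c(0.1, 0.3),
    male_fraction = c(0.55, 0.7),
    child_death_age = c(8, 14),
    adult_death_age = c(30, 45),
    range_halfwidth = c(0.1, 0.35)
  )
  list(
    high_access_low_incidence = c(base, list(
      incidence = c(5, 30), target_access = c(0.9, 1.0),
      p_conventional_first = c(0.7, 0.95),
      p_death_treated = c(5e-4, 5e-3),
      gdp_per_capita = c(6000, 12000), hospital_day_usd = c(50, 150))),
    mid = c(base, list(
      incidence = c(30, 100), target_access = c(0.3, 0.7),
      p_conventional_first = c(0.4, 0.75),
      p_death_treated = c(2e-3, 2e-2),
      gdp_per_capita = c(2500, 7000), hospital_day_usd = c(20, 60))),
    low_access_high_incidence = c(base, list(
      incidence = c(100, 250), target_access = c(0.02, 0.25),
      p_conventional_first = c(0.2, 0.55),
      p_death_treated = c(1e-2, 8e-2),
      gdp_per_capita = c(1000, 3000), hospital_day_usd = c(8, 30)))
  )
}

#' Generate a synthetic country parameter set
#'
#' Draws a complete, internally consistent [country_parameters] object from an
#' archetype's ranges. Every uncertain quantity gets a plausible range around
#' its point estimate (relative half-width drawn per country). Antivenom
#' supply is set so that the base-case access level equals the archetype's
#' target. Deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @param archetype Archetype name (see [country_archetypes]) or definition.
#' @param name Country label; default derived from seed and archetype.
#' @return A validated [country_parameters] object.
#' @export
generate_country <- function(seed, archetype = "mid", name = NULL) {
  if (is.character(archetype)) {
    label <- match.arg(archetype, names(country_archetypes()))
    a <- country_archetypes()[[label]]
  } else {
    a <- archetype; label <- "custom"
  }
  set.seed(seed)
  u <- function(r) stats::runif(1, r[1], r[2])
  if (is.null(name)) name <- sprintf("SYN-%s-%d", toupper(substr(label, 1, 1)), seed)

  hw <- u(a$range_halfwidth)
  prob <- function(p) param_value(p, max(0, p * (1 - hw)),
                                  min(1, p * (1 + hw)), "beta")
  pos <- function(x, family = "gamma") {
    param_value(x, x * (1 - hw), x * (1 + hw), family)
  }

  population <- round(10 ^ u(a$log10_population))
  incidence <- u(a$incidence)
  p_conv <- u(a$p_conventional_first)
  p_switch <- u(a$p_switch_to_conventional)
  p_ind <- u(a$p_indicated)
  target_access <- u(a$target_access)
  fx <- round(10 ^ u(a$log10_exchange_rate), 2)
  gdp <- round(u(a$gdp_per_capita))
  course_usd <- u(a$antivenom_course_usd)

  indicated_point <- expected_victims(incidence, population) * p_ind
  courses <- target_access * indicated_point

  child <- u(a$child_share)
  male <- u(a$male_fraction)
  profile <- age_sex_profile(data.frame(
    sex = c("female", "male", "female", "male"),
    age_low = c(0, 0, 15, 15),
    age_high = c(15, 15, 99, 99),
    share = c(child * (1 - male), child * male,
              (1 - child) * (1 - male), (1 - child) * male),
    mean_age_at_death = c(rep(round(u(a$child_death_age), 1), 2),
                          rep(round(u(a$adult_death_age), 1), 2))
  ))

  country_parameters(
    name = name,
    population = population,
    profile = profile,
    incidence = pos(incidence),
    exchange_rate = fx,
    gdp_per_capita = gdp,
    p_conventional_first = prob(p_conv),
    p_switch_to_conventional = prob(p_switch),
    p_indicated = prob(p_ind),
    antivenom_courses = param_value(courses),   # supply treated as known
    p_adr = prob(u(a$p_adr)),
    p_death_treated = prob(u(a$p_death_treated)),
    p_amputation_survivor = prob(u(a$p_amputation_survivor)),
    los_indicated = pos(u(a$los_indicated)),
    los_not_indicated = pos(u(a$los_not_indicated)),
    cost_hospital_day = pos(u(a$hospital_day_usd) * fx),
    cost_antivenom_course = pos(course_usd * fx),
    cost_antivenom_logistics = pos(course_usd * u(a$logistics_fraction) * fx),
    cost_adr_management = pos(u(a$adr_management_usd) * fx),
    cost_amputation = pos(u(a$amputation_usd) * fx),
    cost_transport = pos(u(a$transport_usd) * fx),
    cost_food_person_day = pos(u(a$food_usd) * fx),
    gdp_growth = {
      g <- u(a$gdp_growth)
      param_value(g, g - 0.01, g + 0.01, "uniform")
    }
  )
}

#' Generate a synthetic region
#'
#' A deterministic (seeded) list of synthetic countries mixing the three
#' archetypes, in the spirit of a multi-country parameter table: a couple of
#' high-access/low-incidence countries, several intermediate ones, and
#' high-incidence/low-access countries.
#'
#' @param seed Integer seed.
#' @param n_countries Number of countries (>= 1), default 7.
#' @return Named list of [country_parameters].
#' @export
generate_region <- function(seed, n_countries = 7) {
  if (n_countries < 1) stop("generate_region: n_countries must be >= 1",
                            call. = FALSE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_countries)
  labels <- names(country_archetypes())
  arch <- labels[(seq_len(n_countries) - 1L) %% 3L + 1L]
  countries <- lapply(seq_len(n_countries), function(i) {
    generate_country(sub_seeds[i], arch[i],
                     name = sprintf("Synthetica-%s", LETTERS[(i - 1L) %% 26L + 1L]))
  })
  stats::setNames(countries, vapply(countries, `[[`, character(1), "name"))
}

#' Write a synthetic region as standard configuration files
#'
#' Emits one country YAML per member plus a `region.yaml` index so that
#' synthetic and real configurations are indistinguishable to the pipeline.
#'
#' @param countries Named list of [country_parameters].
#' @param dir Output directory.
#' @param region_name Region label.
#' @return Path to the region index file, invisibly.
#' @export
write_region_configs <- function(countries, dir, region_name = "Synthetic region") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(countries, function(cp) {
    f <- paste0(gsub("[^A-Za-z0-9_-]", "_", tolower(cp$name)), ".yaml")
    write_country_config(cp, file.path(dir, f))
    f
  }, character(1))
  idx <- file.path(dir, "region.yaml")
  yaml::write_yaml(list(name = region_name, countries = as.list(unname(files))),
                   idx)
  invisible(idx)
}
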