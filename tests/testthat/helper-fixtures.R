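# Deterministic fixtures built in code.

# A small fully-specified country whose parameters are all fixed unless
# overridden; handy for exact arithmetic checks.
fixed_country <- function(...) {
  overrides <- list(...)
  profile <- age_sex_profile(data.frame(
    sex = c("female", "male"), age_low = c(0, 0), age_high = c(99, 99),
    share = c(0.4, 0.6), mean_age_at_death = c(35, 35)))
  args <- list(
    name = "Testland", population = 1e6, profile = profile,
    incidence = param_value(100),
    exchange_rate = 10, gdp_per_capita = 2000,
    p_conventional_first = param_value(0.6),
    p_switch_to_conventional = param_value(0.3),
    p_indicated = param_value(0.4),
    antivenom_courses = param_value(200),  # access 200/400 = 0.5
    p_adr = param_value(0.1),
    p_death_treated = param_value(0.05),
    rr_death_untreated = param_value(2.33),
    p_amputation_survivor = param_value(0.02),
    los_indicated = param_value(4),
    los_not_indicated = param_value(2),
    cost_hospital_day = param_value(500),
    cost_antivenom_course = param_value(1000),
    cost_antivenom_logistics = param_value(200),
    cost_adr_management = param_value(300),
    cost_amputation = param_value(5000),
    cost_transport = param_value(100),
    cost_food_person_day = param_value(50),
    gdp_growth = param_value(0.03),
    discount_rate = param_value(0.03))
  args[names(overrides)] <- overrides
  do.call(country_parameters, args)
}

# A synthetic country cycling through the archetypes by seed.
random_country <- function(seed) {
  labels <- names(country_archetypes())
  generate_country(seed, labels[(seed %% 3) + 1])
}

# A valid configuration list mirroring the documented YAML schema.
test_config_list <- function() {
  list(
    schema_version = 1L,
    name = "Configland",
    population = 7169500,
    incidence = 200,
    profile = list(
      list(sex = "female", age_low = 0, age_high = 99, share = 0.45,
           mean_age_at_death = 36),
      list(sex = "male", age_low = 0, age_high = 99, share = 0.55,
           mean_age_at_death = 34)),
    probabilities = list(
      p_conventional_first = list(point = 0.4, low = 0.3, high = 0.5),
      p_switch_to_conventional = 0.3,
      p_indicated = list(point = 0.21, low = 0.15, high = 0.28),
      p_adr = 0.2,
      p_death_treated = list(point = 0.1, low = 0.05, high = 0.2),
      p_amputation_survivor = 0.047),
    antivenom_courses = 130,
    lengths_of_stay = list(los_indicated = 4, los_not_indicated = 1.5),
    unit_costs = list(hospital_day = 150000, antivenom_course = 400000,
                      antivenom_logistics = 90000, adr_management = 120000,
                      amputation = 2000000, transport = 60000,
                      food_person_day = 25000),
    economics = list(exchange_rate = 8679.41, gdp_per_capita = 2500,
                     gdp_growth = list(point = 0.05, low = 0.04, high = 0.06))
  )
}

write_test_config <- function(cfg = test_config_list(),
                              path = tempfile(fileext = ".yaml")) {
  yaml::write_yaml(cfg, path)
  path
}
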