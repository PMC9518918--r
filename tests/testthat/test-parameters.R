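test_that("param_value enforces ordering, family and support constraints", {
  pv <- param_value(2.33, 1.26, 4.06, "lognormal")
  expect_s3_class(pv, "param_value")
  expect_error(param_value(0.5, 0.6, 0.7), "low <= point <= high")
  expect_error(param_value(0.5, 0.4, 0.6, "fixed"), "fixed")
  expect_error(param_value(0.9, 0.5, 1.2, "beta"), "\\[0, 1\\]")
  expect_error(as_param_value(1.2, "probability", "p_indicated"), "p_indicated")
  expect_error(as_param_value(list(point = 1, typo = 2), name = "x"), "unknown keys")
  # scalar promotes to fixed; range without family picks the kind default
  expect_identical(as_param_value(0.5, "probability")$family, "fixed")
  expect_identical(
    as_param_value(list(point = 0.2, low = 0.1, high = 0.3), "probability")$family,
    "beta")
  expect_identical(
    as_param_value(list(point = 5, low = 2, high = 9), "positive")$family,
    "gamma")
})

test_that("configs load, validate, derive victims and fill defaults", {
  path <- write_test_config()
  cp <- load_country_config(path)
  # incidence 200 per 100k on a population of 7,169,500 -> 14,339 victims
  expect_equal(country_victims(cp), 14339)
  # absent rr defaults to 2.33 [1.26, 4.06]; discount to 3%; retirement to 60
  expect_equal(unlist(cp$params$rr_death_untreated[1:3]),
               c(point = 2.33, low = 1.26, high = 4.06))
  expect_equal(cp$params$discount_rate$point, 0.03)
  expect_equal(cp$retirement_age, 60)
})

test_that("config errors name the offending key", {
  cfg <- test_config_list()
  cfg$probabilities$p_indicated <- 1.2
  expect_error(load_country_config(write_test_config(cfg)), "p_indicated")

  cfg <- test_config_list()
  cfg$antivenom_courses <- NULL
  expect_error(load_country_config(write_test_config(cfg)), "antivenom_courses")

  cfg <- test_config_list()
  cfg$not_a_key <- 1
  expect_error(load_country_config(write_test_config(cfg)), "not_a_key")

  cfg <- test_config_list()
  cfg$schema_version <- 99L
  expect_error(load_country_config(write_test_config(cfg)), "schema_version")

  # both incidence and victims: consistent passes, >0.5% off is a conflict
  cfg <- test_config_list()
  cfg$victims <- 14339
  expect_silent(load_country_config(write_test_config(cfg)))
  cfg$victims <- 15000
  expect_error(load_country_config(write_test_config(cfg)), "inconsistent")

  # victims alone derives incidence
  cfg <- test_config_list()
  cfg$incidence <- NULL
  cfg$victims <- 14339
  cp <- load_country_config(write_test_config(cfg))
  expect_equal(cp$params$incidence$point, 200)
})

test_that("write/read round-trips every field exactly", {
  for (seed in c(11, 12, 13)) {
    cp <- random_country(seed)
    path <- tempfile(fileext = ".yaml")
    write_country_config(cp, path)
    cp2 <- load_country_config(path)
    expect_identical(cp$name, cp2$name)
    expect_identical(cp$population, cp2$population)
    expect_identical(cp$exchange_rate, cp2$exchange_rate)
    for (nm in names(cp$params)) {
      expect_identical(unlist(cp$params[[nm]][1:4]),
                       unlist(cp2$params[[nm]][1:4]),
                       label = paste(cp$name, nm))
    }
    expect_equal(as.data.frame(cp$profile), as.data.frame(cp2$profile),
                 tolerance = 0)
  }
})

test_that("age/sex profile validation catches bad strata", {
  expect_error(age_sex_profile(data.frame(
    sex = "female", age_low = 0, age_high = 99, share = 0.9,
    mean_age_at_death = 30)), "sum to 1")
  expect_error(age_sex_profile(data.frame(
    sex = c("female", "female"), age_low = c(0, 10), age_high = c(20, 30),
    share = c(0.5, 0.5), mean_age_at_death = c(10, 20))), "overlapping")
  expect_error(age_sex_profile(data.frame(
    sex = "male", age_low = 50, age_high = 40, share = 1,
    mean_age_at_death = 45)), "age_low")
})
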