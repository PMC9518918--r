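test_that("expected victims, access level and untreated death risk", {
  expect_equal(expected_victims(0, 5e6), 0)
  expect_equal(expected_victims(100, 1e5), 100)
  # low-incidence setting: 10.68 per 100k on ~32M people -> ~3,412 victims
  expect_equal(expected_victims(10.68, 31947565), 3412, tolerance = 0.5 / 3412)
  expect_error(expected_victims(-1, 100), "incidence")

  expect_equal(access_level(0, 1000), 0)
  expect_equal(access_level(5000, 1000), 1)
  expect_equal(access_level(100, 0), 1)
  # regional supply of ~42,000 courses against 117,575 indicated victims
  expect_equal(round(access_level(42000, 117575), 3), 0.357)

  expect_equal(death_prob_untreated(0, 2.33), 0)
  expect_equal(death_prob_untreated(0.3, 2.33), 0.699)
  expect_equal(death_prob_untreated(0.6, 2.33), 1)
  expect_error(death_prob_untreated(0.5, 0), "rr")
})

test_that("degenerate trees behave deterministically", {
  # full access, no deaths, no amputations: everyone indicated survives
  cp <- fixed_country(antivenom_courses = param_value(1e9),
                      p_death_treated = param_value(0),
                      rr_death_untreated = param_value(2.33),
                      p_amputation_survivor = param_value(0),
                      p_conventional_first = param_value(1))
  out <- run_tree(cp)
  expect_equal(out$deaths, 0)
  expect_equal(out$survivors_envenomed, out$indicated)
  expect_equal(out$amputations, 0)
  expect_equal(out$treated_antivenom, out$indicated)

  # nobody envenomed: no deaths, everyone alive
  cp2 <- fixed_country(p_indicated = param_value(0))
  out2 <- run_tree(cp2)
  expect_equal(out2$indicated, 0)
  expect_equal(out2$deaths, 0)
  expect_equal(out2$not_indicated, out2$victims_total)
})

test_that("path enumeration is exhaustive and matches run_tree", {
  for (seed in 1:200) {
    cp <- random_country(seed)
    paths <- enumerate_paths(cp)
    expect_equal(sum(paths$probability), 1, tolerance = 1e-12)
    agg <- aggregate_paths(paths, country_victims(cp))
    tree <- run_tree(cp)
    for (nm in names(agg)) {
      expect_equal(agg[[nm]], tree[[nm]],
                   tolerance = 1e-9, label = paste(seed, nm))
    }
  }
})

test_that("tree outcomes conserve the cohort", {
  for (seed in 201:400) {
    cp <- random_country(seed)
    out <- run_tree(cp)
    expect_equal(out$victims_total, out$not_indicated + out$indicated,
                 tolerance = 1e-12)
    expect_equal(out$indicated, out$treated_antivenom + out$untreated_indicated,
                 tolerance = 1e-12)
    expect_equal(out$deaths + out$survivors_envenomed, out$indicated,
                 tolerance = 1e-12)
    expect_lte(out$amputations, out$survivors_envenomed + 1e-12)
    expect_lte(out$adr_cases, out$treated_antivenom + 1e-12)
    counts <- unlist(out[c("victims_total", "not_indicated", "indicated",
                           "treated_antivenom", "untreated_indicated",
                           "adr_cases", "deaths", "survivors_envenomed",
                           "amputations")])
    expect_true(all(counts >= 0))
  }
})

test_that("stratum counts add up to country totals", {
  for (seed in c(3, 17, 99)) {
    cp <- random_country(seed)
    out <- run_tree(cp)
    for (nm in c("victims_total", "indicated", "deaths", "amputations",
                 "treated_antivenom")) {
      expect_equal(sum(out$strata[[nm]]), out[[nm]], tolerance = 1e-9)
    }
  }
})

test_that("more antivenom access never increases deaths; higher rr never decreases them", {
  cp <- fixed_country()
  v <- sapply(cp$params, `[[`, "point")
  deaths_at <- function(courses) {
    v2 <- v; v2[["antivenom_courses"]] <- courses
    run_tree(cp, v2)$deaths
  }
  supply <- seq(0, 600, by = 50)
  d <- vapply(supply, deaths_at, numeric(1))
  expect_true(all(diff(d) <= 1e-12))

  deaths_rr <- function(rr) {
    v2 <- v; v2[["rr_death_untreated"]] <- rr
    run_tree(cp, v2)$deaths
  }
  d2 <- vapply(seq(1, 4, by = 0.25), deaths_rr, numeric(1))
  expect_true(all(diff(d2) >= -1e-12))
})
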