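test_that("generation is deterministic under the seed", {
  a <- generate_country(123, "mid")
  b <- generate_country(123, "mid")
  expect_identical(sapply(a$params, `[[`, "point"),
                   sapply(b$params, `[[`, "point"))
  expect_identical(a$population, b$population)
  r1 <- generate_region(9, 4)
  r2 <- generate_region(9, 4)
  expect_identical(lapply(r1, base_values_of <- function(cp)
    sapply(cp$params, `[[`, "point")),
    lapply(r2, base_values_of))
})

test_that("archetypes produce the access and incidence they promise", {
  for (seed in 1:20) {
    ha <- generate_country(seed, "high_access_low_incidence")
    expect_gte(run_tree(ha)$access, 0.9)
    la <- generate_country(seed, "low_access_high_incidence")
    expect_lte(run_tree(la)$access, 0.25)
    expect_gte(la$params$incidence$point, 100)
    expect_lte(ha$params$incidence$point, 30)
  }
})

test_that("every generated country validates and runs end to end", {
  labels <- names(country_archetypes())
  for (seed in 1:100) {
    for (lab in labels) {
      cp <- generate_country(seed, lab)
      expect_s3_class(cp, "country_parameters")
      expect_true(cp$params$incidence$point >= 5 &&
                    cp$params$incidence$point <= 250)
      run <- run_country(cp)
      expect_true(is.finite(run$report$dalys))
      expect_true(is.finite(run$report$total_cost))
    }
  }
})

test_that("regions are additive and reporting ratios recover ground truth", {
  reg <- generate_region(77, 5)
  rr <- run_region(reg)
  expect_equal(rr$region$victims_total, sum(rr$reports$victims_total),
               tolerance = 1e-12)
  expect_error(generate_region(1, 0), "n_countries")
  # recovery: reported ratios reproduce the pipeline's own quantities exactly
  for (run in rr$countries) {
    rep <- run$report
    expect_equal(rep$mortality_per_100k,
                 run$outcome$deaths / run$params$population * 1e5,
                 tolerance = 1e-9)
    expect_equal(rep$pct_indicated_treated,
                 100 * run$outcome$treated_antivenom / run$outcome$indicated,
                 tolerance = 1e-9)
    expect_equal(rep$dalys_per_envenomed, run$dalys$dalys / run$outcome$indicated,
                 tolerance = 1e-9)
  }
})

test_that("the bundled synthetic region fixture loads and matches its generator", {
  idx <- system.file("extdata", "synthetic_region", "region.yaml",
                     package = "snakeburden")
  countries <- load_region_configs(idx)
  expect_length(countries, 7)
  regen <- generate_region(7100, 7)
  for (nm in names(countries)) {
    expect_identical(sapply(countries[[nm]]$params, `[[`, "point"),
                     sapply(regen[[nm]]$params, `[[`, "point"),
                     label = nm)
  }
})
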