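test_that("direct cost components follow unit-cost arithmetic", {
  # 10 treated at course 100 + logistics 20 (fx 1) -> 1,200 USD
  cp <- fixed_country(exchange_rate = 1,
                      cost_antivenom_course = param_value(100),
                      cost_antivenom_logistics = param_value(20))
  out <- run_tree(cp)
  out$treated_antivenom <- 10
  med <- direct_medical_costs(out, cp)
  expect_equal(med$antivenom, 1200)

  # zero conventional-care victims: all direct components vanish
  cp0 <- fixed_country(p_conventional_first = param_value(0),
                       p_switch_to_conventional = param_value(0))
  out0 <- run_tree(cp0)
  med0 <- direct_medical_costs(out0, cp0)
  expect_equal(med0$hospitalization + med0$antivenom + med0$adr_management, 0)
  nm0 <- direct_nonmedical_costs(out0, cp0)
  expect_equal(nm0$transport + nm0$food, 0)
})

test_that("food costs cover the victim plus one accompanying relative", {
  # 1 victim, LOS 3 days, food 5/day, fx 1 -> 2 persons x 3 days x 5 = 30
  cp <- fixed_country(exchange_rate = 1, cost_food_person_day = param_value(5),
                      los_indicated = param_value(3))
  out <- run_tree(cp)
  out$indicated_conventional <- 1
  out$not_indicated_conventional <- 0
  expect_equal(direct_nonmedical_costs(out, cp)$food, 30)
  # LOS 0 -> no food costs
  cpz <- fixed_country(los_indicated = param_value(0),
                       los_not_indicated = param_value(0))
  expect_equal(direct_nonmedical_costs(run_tree(cpz), cpz)$food, 0)
})

test_that("episode productivity losses value two persons' hospital days", {
  # GDP/capita 365 -> daily income 1; 1 victim + 1 relative, LOS 4 -> 8 USD
  cp <- fixed_country(gdp_per_capita = 365, los_indicated = param_value(4))
  out <- run_tree(cp)
  out$indicated_conventional <- 1
  out$not_indicated_conventional <- 0
  expect_equal(episode_productivity_loss(out, cp), 8)
})

test_that("premature death losses follow the discounted geometric series", {
  # age at or past retirement: no loss
  expect_equal(premature_death_loss(60, 1000, 0.05, 0.03), 0)
  expect_equal(premature_death_loss(75, 1000, 0.05, 0.03), 0)
  # growth cancels discounting: gdp x remaining years
  expect_equal(premature_death_loss(30, 1000, 0.03, 0.03), 30000)
  # closed-form geometric series at age 50, r = 3%, g = 0
  expect_equal(premature_death_loss(50, 1000, 0, 0.03),
               1000 * sum(1.03^-(0:9)), tolerance = 1e-12)
  expect_equal(premature_death_loss(50, 1000, 0, 0.03), 8786.11,
               tolerance = 1e-6)
})

test_that("premature death loss is monotone in its drivers", {
  ages <- 0:59
  loss <- premature_death_loss(ages, 2000, 0.02, 0.03)
  expect_true(all(diff(loss) < 0))  # strictly decreasing in age before 60
  rates <- seq(0, 0.1, by = 0.01)
  by_r <- vapply(rates, function(r) premature_death_loss(30, 2000, 0.02, r),
                 numeric(1))
  expect_true(all(diff(by_r) <= 0))
  by_g <- vapply(rates, function(g) premature_death_loss(30, 2000, g, 0.03),
                 numeric(1))
  expect_true(all(diff(by_g) >= 0))
  expect_lt(premature_death_loss(30, 1000, 0.02, 0.03),
            premature_death_loss(30, 2000, 0.02, 0.03))
})

test_that("cost breakdown matches an independent recomputation", {
  for (seed in c(5, 23, 77)) {
    cp <- random_country(seed)
    out <- run_tree(cp)
    v <- sapply(cp$params, `[[`, "point")
    cb <- total_costs(out, cp)
    # spreadsheet-style recomputation from first principles
    fx <- cp$exchange_rate
    hosp_days <- out$indicated_conventional * v[["los_indicated"]] +
      out$not_indicated_conventional * v[["los_not_indicated"]]
    expect_equal(cb$hospitalization, hosp_days * v[["cost_hospital_day"]] / fx)
    expect_equal(cb$antivenom, out$treated_antivenom *
                   (v[["cost_antivenom_course"]] + v[["cost_antivenom_logistics"]]) / fx)
    expect_equal(cb$adr_management, out$adr_cases * v[["cost_adr_management"]] / fx)
    expect_equal(cb$amputation, out$amputations * v[["cost_amputation"]] / fx)
    expect_equal(cb$transport, out$conventional_total * v[["cost_transport"]] / fx)
    expect_equal(cb$food, 2 * hosp_days * v[["cost_food_person_day"]] / fx)
    expect_equal(cb$productivity_episode,
                 2 * hosp_days * cp$gdp_per_capita / 365)
    premature <- sum(out$strata$deaths * vapply(
      out$strata$mean_age_at_death, function(a) {
        n <- floor(cp$retirement_age - a)
        if (n <= 0) 0 else cp$gdp_per_capita *
          sum(((1 + v[["gdp_growth"]]) / (1 + v[["discount_rate"]]))^(0:(n - 1)))
      }, numeric(1)))
    expect_equal(cb$productivity_premature_death, premature, tolerance = 1e-12)
    # component identities
    expect_equal(cb$direct_medical, cb$hospitalization + cb$antivenom +
                   cb$adr_management + cb$amputation)
    expect_equal(cb$direct_nonmedical, cb$transport + cb$food)
    expect_equal(cb$indirect,
                 cb$productivity_episode + cb$productivity_premature_death)
    expect_equal(cb$total, cb$direct_medical + cb$direct_nonmedical + cb$indirect)
  }
})

test_that("converting costs before or after aggregation is equivalent", {
  cp <- random_country(31)
  out <- run_tree(cp)
  cb <- total_costs(out, cp)
  # scale all local unit costs by fx first, then compute with fx = 1
  cp1 <- cp
  cp1$exchange_rate <- 1
  v <- sapply(cp$params, `[[`, "point")
  for (nm in grep("^cost_", names(v), value = TRUE)) {
    cp1$params[[nm]] <- param_value(v[[nm]] / cp$exchange_rate)
  }
  cb1 <- total_costs(run_tree(cp1), cp1)
  expect_equal(cb$total, cb1$total, tolerance = 1e-9)
})

test_that("an all-zero outcome costs nothing", {
  cp <- fixed_country(incidence = param_value(0))
  cb <- total_costs(run_tree(cp), cp)
  expect_equal(cb$total, 0)
  expect_equal(cb$direct_medical, 0)
  expect_equal(cb$indirect, 0)
})
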