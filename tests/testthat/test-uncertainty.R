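test_that("credible intervals use linear interpolation between order statistics", {
  expect_equal(credible_interval(1:1000, 0.95), c(25.975, 975.025))
  expect_equal(credible_interval(rep(7, 50), 0.95), c(7, 7))
  med <- credible_interval(1:11, 0)
  expect_equal(med, c(6, 6))  # degenerate level: both ends at the median
  expect_error(credible_interval(numeric(0)), "empty")
  expect_error(credible_interval(1:10, 1), "level")
})

test_that("the same seed reproduces a PSA bit for bit", {
  cp <- random_country(14)
  a <- run_psa(cp, n = 50, seed = 99)
  b <- run_psa(cp, n = 50, seed = 99)
  expect_identical(a$draws, b$draws)
  expect_identical(a$summary, b$summary)
  c2 <- run_psa(cp, n = 50, seed = 100)
  expect_false(identical(a$draws, c2$draws))
})

test_that("all-fixed parameters collapse the PSA onto the base case", {
  cp <- fixed_country()
  psa <- run_psa(cp, n = 25, seed = 1)
  base <- run_country(cp)$report
  for (q in c("victims_total", "deaths", "dalys", "total_cost")) {
    expect_equal(unique(psa$draws[[q]]), base[[q]][1], label = q)
    row <- psa$summary[psa$summary$quantity == q, ]
    expect_equal(row$lower, row$upper)
    expect_equal(row$lower, base[[q]][1])
  }
})

test_that("a single uncertain parameter's CrI matches the quantile transform", {
  # only p_death_treated uncertain; deaths are monotone increasing in it, so
  # the deaths CrI is the image of the beta's 2.5/97.5 percent quantiles
  pv <- param_value(0.1, 0.05, 0.2, "beta")
  cp <- fixed_country(p_death_treated = pv)
  psa <- run_psa(cp, n = 4000, seed = 42)
  s <- build_sampler(pv, "probability")
  q <- s$quantile(c(0.025, 0.975))
  deaths_at <- function(p) {
    v <- sapply(cp$params, `[[`, "point")
    v[["p_death_treated"]] <- p
    run_tree(cp, v)$deaths
  }
  expected <- vapply(q, deaths_at, numeric(1))
  got <- unlist(psa$summary[psa$summary$quantity == "deaths", c("lower", "upper")])
  expect_equal(unname(got), expected, tolerance = 0.05)
})

test_that("region PSA sums draws before taking quantiles", {
  reg <- generate_region(5, 3)
  psa <- run_region_psa(reg, n = 40, seed = 7)
  expect_equal(nrow(psa$draws), 40)
  # region point estimates equal summed country points
  rr <- run_region(reg)
  expect_equal(psa$summary$point[psa$summary$quantity == "dalys"],
               rr$region$dalys, tolerance = 1e-9)
  # quantiles of sums differ from sums of quantiles in general; at minimum the
  # interval must be ordered and contain the median draw
  row <- psa$summary[psa$summary$quantity == "total_cost", ]
  expect_lte(row$lower, row$upper)
  expect_gte(stats::median(psa$draws$total_cost), row$lower)
  expect_lte(stats::median(psa$draws$total_cost), row$upper)
})

test_that("one-way SA evaluates bounds deterministically and sorts by swing", {
  cp <- random_country(21)
  tor <- one_way_sa(cp, outputs = "dalys")
  expect_true(all(diff(tor$swing) <= 1e-12))
  expect_true(all(tor$swing >= 0))
  # no hidden randomness: same call, same table
  expect_identical(tor, one_way_sa(cp, outputs = "dalys"))
  # a parameter with low = high contributes zero swing
  cp2 <- fixed_country(p_indicated = list(point = 0.4, low = 0.3, high = 0.5))
  tor2 <- one_way_sa(cp2, parameters = c("p_indicated", "p_adr"),
                     outputs = "total_cost")
  expect_equal(tor2$swing[tor2$parameter == "p_adr"], 0)
  expect_gt(tor2$swing[tor2$parameter == "p_indicated"], 0)
  expect_warning(one_way_sa(cp, parameters = c("p_indicated", "nope")),
                 "nope")
})

test_that("lower discounting raises premature-death losses in the tornado", {
  cp <- fixed_country(p_death_treated = param_value(0.1),
                      discount_rate = param_value(0.03, 0.0, 0.06, "uniform"))
  tor <- one_way_sa(cp, parameters = "discount_rate", outputs = "total_cost")
  expect_gt(tor$output_low, tor$output_high)
})

test_that("CrI width shrinks as parameter ranges shrink", {
  cp_wide <- fixed_country(p_death_treated = param_value(0.1, 0.02, 0.3, "beta"))
  cp_narrow <- fixed_country(p_death_treated = param_value(0.1, 0.08, 0.12, "beta"))
  w <- run_psa(cp_wide, n = 400, seed = 3)$summary
  n <- run_psa(cp_narrow, n = 400, seed = 3)$summary
  width <- function(s, q) {
    r <- s[s$quantity == q, ]; r$upper - r$lower
  }
  expect_gt(width(w, "deaths"), width(n, "deaths"))
})
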