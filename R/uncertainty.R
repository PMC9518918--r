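# Quantities tracked per PSA draw, extracted from the report row.
psa_quantities <- function() {
  c("victims_total", "indicated", "treated_antivenom", "untreated_indicated",
    "deaths", "amputations", "ptsd_cases", "yll", "yld_episode",
    "yld_amputation", "yld_ptsd", "dalys", "direct_medical",
    "direct_nonmedical", "indirect", "total_cost", "pct_gdp")
}

# Sample an n x p matrix of parameter values for one country, consuming the
# current RNG stream. The discount rate is held at base case unless
# sample_discount = TRUE (it is explored in one-way SA instead).
psa_parameter_draws <- function(cp, n, scenario = FALSE, ptsd = ptsd_spec(),
                                sample_discount = FALSE) {
  kinds <- country_param_kinds()
  cols <- lapply(names(cp$params), function(nm) {
    pv <- cp$params[[nm]]
    if (nm == "discount_rate" && !sample_discount) {
      return(rep(pv$point, n))
    }
    s <- tryCatch(build_sampler(pv, kinds[[nm]]),
                  error = function(e) stop("sampler for parameter '", nm, "': ",
                                           conditionMessage(e), call. = FALSE))
    s$sample(n)
  })
  names(cols) <- names(cp$params)
  if (scenario) {
    cols$ptsd_p_env <- build_sampler(ptsd$p_after_envenoming,
                                     "probability")$sample(n)
    cols$ptsd_p_noenv <- build_sampler(ptsd$p_after_no_envenoming,
                                       "probability")$sample(n)
  }
  do.call(cbind, cols)
}

# Evaluate the full pipeline for each row of a parameter draw matrix.
evaluate_draws <- function(cp, draws, scenario = FALSE, ptsd = ptsd_spec(),
                           specs = default_disability_specs(),
                           table = default_life_table()) {
  qs <- psa_quantities()
  out <- matrix(NA_real_, nrow(draws), length(qs),
                dimnames = list(NULL, qs))
  for (i in seq_len(nrow(draws))) {
    run <- run_country(cp, scenario = scenario, ptsd = ptsd, specs = specs,
                       table = table, values = draws[i, ])
    out[i, ] <- unlist(run$report[1, qs])
  }
  as.data.frame(out)
}

#' Probabilistic sensitivity analysis for one country
#'
#' Propagates parameter uncertainty through the full pipeline (tree, costs,
#' DALYs) by Monte Carlo: each draw samples every uncertain parameter from its
#' moment-matched distribution and re-evaluates the model. Credible intervals
#' are empirical percentile intervals of the draws. The same seed always
#' reproduces the same result bit for bit.
#'
#' @param cp A [country_parameters] object.
#' @param n Number of draws (default 1,000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param level Credible level (default 0.95).
#' @param scenario Include the PTSD scenario (its post-envenoming probability
#'   is then sampled too)?
#' @param ptsd,specs,table Passed to [run_country].
#' @param sample_discount Also sample the discount rate? Off by default; the
#'   discount rate is explored in [one_way_sa].
#' @return A list of class `psa_result`: `n_draws`, `seed`, `level`,
#'   `draws` (data frame, one row per draw, one column per quantity),
#'   `summary` (quantity, point, lower, upper) and `families` (the sampling
#'   family actually used per parameter, recorded as run metadata).
#' @export
run_psa <- function(cp, n = 1000, seed = 1, level = 0.95, scenario = FALSE,
                    ptsd = ptsd_spec(), specs = default_disability_specs(),
                    table = default_life_table(), sample_discount = FALSE) {
  stopifnot(n >= 2)
  set.seed(seed)
  param_draws <- psa_parameter_draws(cp, n, scenario, ptsd, sample_discount)
  draws <- evaluate_draws(cp, param_draws, scenario, ptsd, specs, table)
  finish_psa(draws, cp, n, seed, level, scenario, ptsd, specs, table)
}

finish_psa <- function(draws, cp_or_list, n, seed, level, scenario, ptsd,
                       specs, table) {
  point <- if (inherits(cp_or_list, "country_parameters")) {
    run_country(cp_or_list, scenario = scenario, ptsd = ptsd, specs = specs,
                table = table)$report
  } else {
    run_region(cp_or_list, scenario = scenario, ptsd = ptsd, specs = specs,
               table = table)$region
  }
  qs <- psa_quantities()
  summ <- do.call(rbind, lapply(qs, function(q) {
    ci <- credible_interval(draws[[q]], level)
    data.frame(quantity = q, point = point[[q]][1], lower = ci[1],
               upper = ci[2])
  }))
  fams <- if (inherits(cp_or_list, "country_parameters")) {
    vapply(cp_or_list$params, `[[`, character(1), "family")
  } else {
    vapply(cp_or_list[[1]]$params, `[[`, character(1), "family")
  }
  structure(list(n_draws = n, seed = seed, level = level, scenario = scenario,
                 draws = draws, summary = summ, families = fams),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (seed %d, %.0f%% CrI%s)\n", x$n_draws,
              x$seed, 100 * x$level, if (x$scenario) ", PTSD scenario" else ""))
  show <- x$summary[x$summary$quantity %in%
                      c("victims_total", "deaths", "dalys", "total_cost"), ]
  print(show, row.names = FALSE)
  invisible(x)
}

#' Probabilistic sensitivity analysis for a region
#'
#' Countries are sampled independently within each draw; region quantities are
#' the draw-wise sums over countries (percentile intervals are then taken on
#' the summed draws — never by adding country intervals). Rates and
#' percent-of-GDP are recomputed per draw from the summed numerators and
#' denominators.
#'
#' @param countries List of [country_parameters].
#' @inheritParams run_psa
#' @return A `psa_result` for the region.
#' @export
run_region_psa <- function(countries, n = 1000, seed = 1, level = 0.95,
                           scenario = FALSE, ptsd = ptsd_spec(),
                           specs = default_disability_specs(),
                           table = default_life_table(),
                           sample_discount = FALSE) {
  stopifnot(length(countries) >= 1, n >= 2)
  set.seed(seed)
  qs <- psa_quantities()
  total <- NULL
  population <- 0; gdp_total <- 0
  for (cp in countries) {
    param_draws <- psa_parameter_draws(cp, n, scenario, ptsd, sample_discount)
    d <- evaluate_draws(cp, param_draws, scenario, ptsd, specs, table)
    population <- population + cp$population
    gdp_total <- gdp_total + cp$gdp_per_capita * cp$population
    total <- if (is.null(total)) d else total + d
  }
  # non-additive quantities recomputed from region denominators
  total$pct_gdp <- 100 * total$total_cost / gdp_total
  finish_psa(total, countries, n, seed, level, scenario, ptsd, specs, table)
}

#' Percentile credible interval
#'
#' Empirical quantiles at `(1 - level)/2` and `(1 + level)/2` with linear
#' interpolation between order statistics (`stats::quantile` type 7), the
#' convention documented so results are reproducible across implementations.
#'
#' @param draws Numeric vector of Monte Carlo draws (at least one value).
#' @param level Credible level in `[0, 1)`; `level = 0` degenerates to the
#'   median at both ends.
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' credible_interval(1:1000, 0.95)  # 25.975, 975.025
credible_interval <- function(draws, level = 0.95) {
  if (length(draws) == 0) stop("credible_interval: empty draw vector",
                               call. = FALSE)
  if (level < 0 || level >= 1) stop("credible_interval: level must be in [0, 1)",
                                    call. = FALSE)
  unname(stats::quantile(draws, c((1 - level) / 2, (1 + level) / 2),
                         type = 7, names = FALSE))
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the deterministic base-case pipeline with one parameter at a time
#' set to its low and high bound, all others at their point estimates, and
#' ranks parameters by the output swing `|high - low|`. For a region the
#' parameter is moved to its bound in every country simultaneously and the
#' region total is reported.
#'
#' @param x A [country_parameters] object or a list of them (region).
#' @param parameters Parameter names to vary; default: all with `low < high`.
#' @param outputs Report columns to analyse (default `"dalys"` and
#'   `"total_cost"`).
#' @param scenario,ptsd,specs,table Passed to [run_country].
#' @return Data frame of class `tornado` with columns `output`, `parameter`,
#'   `low`, `high`, `output_low`, `output_high`, `base`, `swing`, sorted by
#'   decreasing swing within each output.
#' @export
one_way_sa <- function(x, parameters = NULL,
                       outputs = c("dalys", "total_cost"), scenario = FALSE,
                       ptsd = ptsd_spec(), specs = default_disability_specs(),
                       table = default_life_table()) {
  countries <- if (inherits(x, "country_parameters")) list(x) else x
  stopifnot(length(countries) >= 1)

  eval_at <- function(bound = NULL, param = NULL) {
    reports <- do.call(rbind, lapply(countries, function(cp) {
      v <- base_values(cp)
      if (!is.null(param)) v[[param]] <- cp$params[[param]][[bound]]
      run_country(cp, scenario = scenario, ptsd = ptsd, specs = specs,
                  table = table, values = v)$report
    }))
    if (nrow(reports) == 1) reports else make_region_report(reports)
  }

  all_names <- names(countries[[1]]$params)
  if (is.null(parameters)) {
    varies <- vapply(all_names, function(nm) {
      any(vapply(countries, function(cp) {
        cp$params[[nm]]$low < cp$params[[nm]]$high
      }, logical(1)))
    }, logical(1))
    parameters <- all_names[varies]
  } else {
    bad <- setdiff(parameters, all_names)
    if (length(bad) > 0) {
      warning("one_way_sa: skipping unknown parameters: ",
              paste(bad, collapse = ", "), call. = FALSE)
      parameters <- intersect(parameters, all_names)
    }
  }

  base <- eval_at()
  rows <- list()
  for (nm in parameters) {
    lo <- eval_at("low", nm)
    hi <- eval_at("high", nm)
    for (q in outputs) {
      rows[[length(rows) + 1L]] <- data.frame(
        output = q, parameter = nm,
        low = countries[[1]]$params[[nm]]$low,
        high = countries[[1]]$params[[nm]]$high,
        output_low = lo[[q]][1], output_high = hi[[q]][1], base = base[[q]][1],
        swing = abs(hi[[q]][1] - lo[[q]][1]))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$output, -out$swing), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Tornado diagram
#'
#' Horizontal bar chart of one-way sensitivity results for one output,
#' parameters ordered by swing.
#'
#' @param tor A `tornado` data frame from [one_way_sa].
#' @param output Which output to plot (default: the first present).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tor, output = tor$output[1]) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_tornado requires ggplot2", call. = FALSE)
  }
  d <- tor[tor$output == output, ]
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = output_low, xend = output_high,
                                       y = parameter, yend = parameter),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = d$base[1], linetype = 2) +
    ggplot2::labs(x = output, y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}
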