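#' Run the full burden pipeline for one country
#'
#' Evaluates the decision tree, societal costs and DALYs at the base case (or
#' at supplied parameter values) and assembles the country report. With
#' `scenario = TRUE`, PTSD cases, YLD and productivity losses are added.
#'
#' @param cp A [country_parameters] object.
#' @param scenario Include the PTSD scenario?
#' @param ptsd A [ptsd_spec] (used when `scenario = TRUE`).
#' @param specs Disability specifications ([default_disability_specs]).
#' @param table Life table ([default_life_table]).
#' @param values Optional named numeric vector overriding base-case parameter
#'   values; may also carry `ptsd_p_env`/`ptsd_p_noenv` entries for the
#'   scenario probabilities.
#' @return A list of class `country_run` with `params`, `outcome`, `costs`,
#'   `dalys`, `ptsd` (cases/yld/productivity_cost, zeros outside the
#'   scenario) and `report` (one-row data frame, see [make_report]).
#' @export
run_country <- function(cp, scenario = FALSE, ptsd = ptsd_spec(),
                        specs = default_disability_specs(),
                        table = default_life_table(), values = NULL) {
  outcome <- run_tree(cp, values)
  pt <- list(cases = 0, yld = 0, productivity_cost = 0)
  if (scenario) {
    p_env <- if (!is.null(values) && "ptsd_p_env" %in% names(values)) {
      values[["ptsd_p_env"]]
    } else NULL
    p_noenv <- if (!is.null(values) && "ptsd_p_noenv" %in% names(values)) {
      values[["ptsd_p_noenv"]]
    } else NULL
    cases <- ptsd_cases(outcome, ptsd, p_env = p_env, p_noenv = p_noenv)
    pt <- c(list(cases = cases), ptsd_burden(cases, ptsd, cp))
  }
  costs <- total_costs(outcome, cp, values, ptsd_cost = pt$productivity_cost)
  dalys <- total_dalys(outcome, specs, table, ptsd_yld = pt$yld)
  report <- make_report(outcome, costs, dalys, cp, ptsd_cases = pt$cases)
  structure(list(params = cp, outcome = outcome, costs = costs, dalys = dalys,
                 ptsd = pt, report = report),
            class = "country_run")
}

#' @export
print.country_run <- function(x, ...) {
  cat(sprintf("<country_run> %s\n", x$params$name))
  print(x$outcome)
  print(x$costs)
  print(x$dalys)
  invisible(x)
}

#' Run the pipeline for every country of a region
#'
#' @param countries Named list of [country_parameters] (e.g. from
#'   [load_region_configs] or [generate_region]).
#' @param ... Passed to [run_country].
#' @return A list of class `region_run` with `countries` (list of
#'   `country_run`), `reports` (row-bound country reports) and `region`
#'   (the [make_region_report] row).
#' @export
run_region <- function(countries, ...) {
  runs <- lapply(countries, run_country, ...)
  reports <- do.call(rbind, lapply(runs, `[[`, "report"))
  rownames(reports) <- NULL
  structure(list(countries = runs, reports = reports,
                 region = make_region_report(reports)),
            class = "region_run")
}

#' @export
print.region_run <- function(x, ...) {
  cat(sprintf("<region_run> %d countries\n", length(x$countries)))
  cols <- c("name", "victims_total", "indicated", "deaths", "dalys",
            "total_cost", "pct_gdp")
  print(rbind(x$reports[, cols], x$region[, cols]), row.names = FALSE)
  invisible(x)
}
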