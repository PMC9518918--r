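#' Assemble the report row for one country
#'
#' Derives every reported rate and share from a tree outcome, a cost
#' breakdown, a DALY breakdown and the country parameters: per-100,000 rates,
#' per-envenomed-victim burden, percentage of GDP, percent of indicated
#' victims treated, and cost shares. All quantities are kept at full
#' precision; rounding happens only when tables are serialized.
#'
#' Inputs may be the package's own objects or plain lists carrying the same
#' field names (e.g. values transcribed from a published table), which makes
#' the reporting layer usable for consistency checks on printed results.
#'
#' @param outcome `tree_outcome` or list with the count fields.
#' @param costs `cost_breakdown` or list with the cost fields (USD).
#' @param dalys `daly_breakdown` or list with `yll`, `yld_episode`,
#'   `yld_amputation`, `yld_ptsd` (missing YLD terms are treated as 0; the
#'   `dalys` total is recomputed as the sum when absent).
#' @param params `country_parameters` or list with `name`, `population` and
#'   `gdp_per_capita` (and optionally `gdp_total`).
#' @param ptsd_cases Expected PTSD cases (scenario analyses), default 0.
#' @return One-row data frame.
#' @export
make_report <- function(outcome, costs, dalys, params, ptsd_cases = 0) {
  g <- function(x, nm, default = NA_real_) {
    if (!is.null(x[[nm]])) as.numeric(x[[nm]]) else default
  }
  population <- g(params, "population")
  if (!is.na(population) && population <= 0) {
    stop("make_report: population must be > 0", call. = FALSE)
  }
  gdp_total <- g(params, "gdp_total")
  if (is.na(gdp_total)) gdp_total <- g(params, "gdp_per_capita") * population
  if (!is.na(gdp_total) && gdp_total <= 0) {
    stop("make_report: GDP must be > 0", call. = FALSE)
  }

  victims <- g(outcome, "victims_total")
  indicated <- g(outcome, "indicated")
  deaths <- g(outcome, "deaths")
  treated <- g(outcome, "treated_antivenom")

  yll_v <- g(dalys, "yll", 0)
  yld_episode <- g(dalys, "yld_episode", 0)
  yld_amputation <- g(dalys, "yld_amputation", 0)
  yld_ptsd <- g(dalys, "yld_ptsd", 0)
  dalys_total <- g(dalys, "dalys")
  if (is.na(dalys_total)) {
    dalys_total <- yll_v + yld_episode + yld_amputation + yld_ptsd
  }

  total_cost <- g(costs, "total")
  # Table-2-style components: antivenom-related merges course+logistics+ADR
  antivenom_related <- g(costs, "antivenom", 0) + g(costs, "adr_management", 0)
  components <- c(
    healthcare = g(costs, "hospitalization", 0),
    antivenom_related = antivenom_related,
    amputation = g(costs, "amputation", 0),
    transport = g(costs, "transport", 0),
    food = g(costs, "food", 0),
    productivity_episode = g(costs, "productivity_episode", 0),
    productivity_premature_death = g(costs, "productivity_premature_death", 0),
    productivity_ptsd = g(costs, "productivity_ptsd", 0)
  )
  if (is.na(total_cost)) total_cost <- sum(components)

  ratio <- function(num, den) {
    if (is.na(den) || den == 0) NA_real_ else num / den
  }
  per_100k <- function(count) {
    if (is.na(population)) NA_real_ else count / population * 1e5
  }
  shares <- if (!is.na(total_cost) && total_cost > 0) {
    100 * components / total_cost
  } else {
    rep(NA_real_, length(components))
  }
  names(shares) <- paste0("share_", names(components))

  row <- data.frame(
    name = if (!is.null(params$name)) params$name else NA_character_,
    population = population,
    gdp_total = gdp_total,
    victims_total = victims,
    not_indicated = g(outcome, "not_indicated"),
    indicated = indicated,
    treated_antivenom = treated,
    untreated_indicated = g(outcome, "untreated_indicated"),
    deaths = deaths,
    amputations = g(outcome, "amputations"),
    adr_cases = g(outcome, "adr_cases"),
    ptsd_cases = ptsd_cases,
    yll = yll_v,
    yld_episode = yld_episode,
    yld_amputation = yld_amputation,
    yld_ptsd = yld_ptsd,
    dalys = dalys_total,
    cost_healthcare = components[["healthcare"]],
    cost_antivenom_related = components[["antivenom_related"]],
    cost_amputation = components[["amputation"]],
    cost_transport = components[["transport"]],
    cost_food = components[["food"]],
    cost_productivity_episode = components[["productivity_episode"]],
    cost_productivity_premature_death = components[["productivity_premature_death"]],
    cost_productivity_ptsd = components[["productivity_ptsd"]],
    direct_medical = g(costs, "direct_medical"),
    direct_nonmedical = g(costs, "direct_nonmedical"),
    indirect = g(costs, "indirect"),
    total_cost = total_cost,
    incidence_per_100k = per_100k(victims),
    mortality_per_100k = per_100k(deaths),
    dalys_per_100k = per_100k(dalys_total),
    pct_gdp = 100 * ratio(total_cost, gdp_total),
    pct_indicated_treated = 100 * ratio(treated, indicated),
    mortality_per_envenomed = ratio(deaths, indicated),
    amputation_per_envenomed = ratio(g(outcome, "amputations"), indicated),
    dalys_per_envenomed = ratio(dalys_total, indicated),
    cost_per_envenomed = ratio(total_cost, indicated),
    stringsAsFactors = FALSE
  )
  for (nm in names(shares)) row[[nm]] <- shares[[nm]]
  # degenerate country: no victims -> rates zero, shares undefined
  if (!is.na(victims) && victims == 0) {
    row$incidence_per_100k <- 0
    row$mortality_per_100k <- 0
    row$dalys_per_100k <- 0
  }
  rownames(row) <- NULL
  row
}

# Columns summed across countries when forming the region row.
additive_report_columns <- function() {
  c("population", "gdp_total", "victims_total", "not_indicated", "indicated",
    "treated_antivenom", "untreated_indicated", "deaths", "amputations",
    "adr_cases", "ptsd_cases", "yll", "yld_episode", "yld_amputation",
    "yld_ptsd", "dalys",
    "cost_healthcare", "cost_antivenom_related", "cost_amputation",
    "cost_transport", "cost_food", "cost_productivity_episode",
    "cost_productivity_premature_death", "cost_productivity_ptsd",
    "direct_medical", "direct_nonmedical", "indirect", "total_cost")
}

#' Aggregate country report rows into a region report
#'
#' Counts, DALYs and costs are summed; every rate, share and per-victim
#' quantity is recomputed from the summed numerators and denominators (never
#' averaged across countries).
#'
#' @param reports Data frame of country rows from [make_report].
#' @param name Region label.
#' @return One-row data frame with the same columns.
#' @export
make_region_report <- function(reports, name = "Total") {
  if (is.null(reports) || nrow(reports) == 0) {
    stop("make_region_report: need at least one country report", call. = FALSE)
  }
  sums <- lapply(additive_report_columns(), function(cl) sum(reports[[cl]]))
  names(sums) <- additive_report_columns()
  make_report(
    outcome = sums, costs = list(
      hospitalization = sums$cost_healthcare,
      antivenom = sums$cost_antivenom_related, adr_management = 0,
      amputation = sums$cost_amputation, transport = sums$cost_transport,
      food = sums$cost_food,
      productivity_episode = sums$cost_productivity_episode,
      productivity_premature_death = sums$cost_productivity_premature_death,
      productivity_ptsd = sums$cost_productivity_ptsd,
      direct_medical = sums$direct_medical,
      direct_nonmedical = sums$direct_nonmedical,
      indirect = sums$indirect, total = sums$total_cost),
    dalys = sums[c("yll", "yld_episode", "yld_amputation", "yld_ptsd", "dalys")],
    params = list(name = name, population = sums$population,
                  gdp_total = sums$gdp_total),
    ptsd_cases = sums$ptsd_cases
  )
}

#' Write the report tables of a region run to CSV
#'
#' Emits full-precision per-country and region CSVs plus display tables that
#' follow the usual reporting conventions: counts rounded to integers
#' (`table_burden.csv`) and costs in thousand USD to one decimal
#' (`table_costs.csv`).
#'
#' @param rr A `region_run` from [run_region].
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_region_outputs <- function(rr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_rows <- rbind(rr$reports, rr$region)
  f1 <- file.path(dir, "countries_full_precision.csv")
  utils::write.csv(format(all_rows, digits = 15, scientific = FALSE,
                          trim = TRUE), f1, row.names = FALSE, quote = FALSE)

  burden <- data.frame(
    name = all_rows$name,
    victims = round(all_rows$victims_total),
    antivenom_indicated = round(all_rows$indicated),
    treated_antivenom = round(all_rows$treated_antivenom),
    untreated_indicated = round(all_rows$untreated_indicated),
    deaths = round(all_rows$deaths),
    amputations = round(all_rows$amputations),
    yll = round(all_rows$yll),
    yld = round(all_rows$yld_episode + all_rows$yld_amputation +
                  all_rows$yld_ptsd),
    dalys = round(all_rows$dalys),
    dalys_per_100k = round(all_rows$dalys_per_100k, 1),
    pct_indicated_treated = round(all_rows$pct_indicated_treated, 1)
  )
  f2 <- file.path(dir, "table_burden.csv")
  utils::write.csv(burden, f2, row.names = FALSE, quote = FALSE)

  k <- function(x) round(x / 1000, 1)
  costs <- data.frame(
    name = all_rows$name,
    healthcare_kusd = k(all_rows$cost_healthcare),
    antivenom_related_kusd = k(all_rows$cost_antivenom_related),
    amputation_kusd = k(all_rows$cost_amputation),
    transport_kusd = k(all_rows$cost_transport),
    food_kusd = k(all_rows$cost_food),
    productivity_episode_kusd = k(all_rows$cost_productivity_episode),
    productivity_premature_death_kusd = k(all_rows$cost_productivity_premature_death),
    productivity_ptsd_kusd = k(all_rows$cost_productivity_ptsd),
    total_kusd = k(all_rows$total_cost),
    pct_gdp = round(all_rows$pct_gdp, 3)
  )
  f3 <- file.path(dir, "table_costs.csv")
  utils::write.csv(costs, f3, row.names = FALSE, quote = FALSE)
  invisible(c(f1, f2, f3))
}
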