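#' Expected annual number of snakebite victims
#'
#' @param incidence Victims per 100,000 population per year.
#' @param population Population (persons).
#' @return Expected victims: `incidence * population / 100000`.
#' @export
#' @examples
#' expected_victims(100, 100000)  # 100
expected_victims <- function(incidence, population) {
  if (any(incidence < 0) || any(population <= 0)) {
    stop("expected_victims: incidence must be >= 0 and population > 0",
         call. = FALSE)
  }
  incidence * population / 1e5
}

#' Level of access to antivenom
#'
#' Antivenom treatment courses available divided by the number of victims
#' indicated for antivenom treatment, capped at 1. With no indicated victims
#' access is complete by convention.
#'
#' @param antivenom_courses Treatment courses available per year.
#' @param indicated Victims indicated for antivenom (systemic envenoming).
#' @return Fraction in \[0, 1\].
#' @export
access_level <- function(antivenom_courses, indicated) {
  if (any(antivenom_courses < 0) || any(indicated < 0)) {
    stop("access_level: inputs must be non-negative", call. = FALSE)
  }
  ifelse(indicated == 0, 1, pmin(1, antivenom_courses / indicated))
}

#' Probability of death without antivenom treatment
#'
#' Scales the probability of death under antivenom treatment by the relative
#' risk of death when untreated, capped at 1.
#'
#' @param p_death_treated Probability of death if treated.
#' @param rr Relative risk of death if untreated (> 0).
#' @return `min(1, rr * p_death_treated)`.
#' @export
#' @examples
#' death_prob_untreated(0.3, 2.33)  # 0.699
death_prob_untreated <- function(p_death_treated, rr) {
  if (any(p_death_treated < 0 | p_death_treated > 1)) {
    stop("death_prob_untreated: p_death_treated must be in [0, 1]", call. = FALSE)
  }
  if (any(rr <= 0)) stop("death_prob_untreated: rr must be > 0", call. = FALSE)
  pmin(1, rr * p_death_treated)
}

#' Evaluate the snakebite decision tree as a cohort expectation
#'
#' Victims seek conventional care first or a traditional healer first (with a
#' possible later switch to conventional care); a fraction has systemic
#' envenoming indicated for antivenom; indicated victims reaching conventional
#' care receive antivenom at the country's access level (and may experience an
#' adverse drug reaction); indicated victims die with probability
#' `p_death_treated` if treated, or `min(1, rr * p_death_treated)` if not;
#' survivors of envenoming may undergo amputation. Non-envenomed victims
#' always survive. Counts are expected values (fractional persons).
#'
#' @param cp A [country_parameters] object.
#' @param values Optional named numeric vector of parameter values overriding
#'   the base-case points (used by the sensitivity analyses).
#' @return A list of class `tree_outcome`; see Details for fields. Includes a
#'   `strata` data frame replicating the counts per demographic stratum.
#' @details Fields: `victims_total`, `not_indicated`, `indicated`,
#'   `indicated_conventional`, `indicated_traditional_only`,
#'   `treated_antivenom`, `untreated_indicated`, `adr_cases`, `deaths`,
#'   `survivors_envenomed`, `amputations`, `not_indicated_conventional`,
#'   `conventional_total`, `access`, `p_death_untreated`.
#' @export
run_tree <- function(cp, values = NULL) {
  v <- if (is.null(values)) base_values(cp) else values
  victims <- expected_victims(v[["incidence"]], cp$population)

  p_conv <- v[["p_conventional_first"]]
  p_switch <- v[["p_switch_to_conventional"]]
  p_ind <- v[["p_indicated"]]
  probs <- c(p_conv, p_switch, p_ind, v[["p_adr"]], v[["p_death_treated"]],
             v[["p_amputation_survivor"]])
  if (any(probs < 0 | probs > 1)) {
    stop("run_tree: a branch probability lies outside [0, 1]", call. = FALSE)
  }

  conv_frac <- p_conv + (1 - p_conv) * p_switch
  indicated <- victims * p_ind
  not_indicated <- victims * (1 - p_ind)
  indicated_conventional <- indicated * conv_frac
  indicated_traditional_only <- indicated * (1 - conv_frac)
  not_indicated_conventional <- not_indicated * conv_frac

  acc <- access_level(v[["antivenom_courses"]], indicated)
  treated <- indicated_conventional * acc
  untreated_indicated <- indicated - treated
  adr_cases <- treated * v[["p_adr"]]

  p_du <- death_prob_untreated(v[["p_death_treated"]], v[["rr_death_untreated"]])
  deaths <- treated * v[["p_death_treated"]] + untreated_indicated * p_du
  survivors_envenomed <- indicated - deaths
  amputations <- survivors_envenomed * v[["p_amputation_survivor"]]

  totals <- list(
    victims_total = victims,
    not_indicated = not_indicated,
    indicated = indicated,
    indicated_conventional = indicated_conventional,
    indicated_traditional_only = indicated_traditional_only,
    treated_antivenom = treated,
    untreated_indicated = untreated_indicated,
    adr_cases = adr_cases,
    deaths = deaths,
    survivors_envenomed = survivors_envenomed,
    amputations = amputations,
    not_indicated_conventional = not_indicated_conventional,
    conventional_total = victims * conv_frac,
    access = unname(acc),
    p_death_untreated = unname(p_du)
  )

  count_fields <- c("victims_total", "not_indicated", "indicated",
                    "indicated_conventional", "indicated_traditional_only",
                    "treated_antivenom", "untreated_indicated", "adr_cases",
                    "deaths", "survivors_envenomed", "amputations",
                    "not_indicated_conventional", "conventional_total")
  strata <- cp$profile
  for (f in count_fields) strata[[f]] <- strata$share * totals[[f]]
  totals$strata <- strata
  structure(totals, class = "tree_outcome")
}

#' @export
print.tree_outcome <- function(x, ...) {
  cat("<tree_outcome>\n")
  cat(sprintf("  victims %.1f | indicated %.1f | treated %.1f (access %.3f)\n",
              x$victims_total, x$indicated, x$treated_antivenom, x$access))
  cat(sprintf("  deaths %.2f | survivors of envenoming %.2f | amputations %.2f | ADR %.2f\n",
              x$deaths, x$survivors_envenomed, x$amputations, x$adr_cases))
  invisible(x)
}

#' Enumerate all root-to-leaf paths of the decision tree
#'
#' Audit/oracle view of the tree: every leaf with its path probability and
#' terminal state. Leaf probabilities sum to 1 (law of total probability).
#'
#' @param cp A [country_parameters] object.
#' @param values Optional parameter override as in [run_tree].
#' @return A data frame with columns `path` (label), `seek`
#'   (`conventional_first`/`traditional_switch`/`traditional_only`),
#'   `indicated`, `antivenom`, `adr`, `dead`, `amputated` (logicals) and
#'   `probability`.
#' @export
enumerate_paths <- function(cp, values = NULL) {
  v <- if (is.null(values)) base_values(cp) else values
  victims <- expected_victims(v[["incidence"]], cp$population)
  indicated_total <- victims * v[["p_indicated"]]
  acc <- access_level(v[["antivenom_courses"]], indicated_total)
  p_du <- death_prob_untreated(v[["p_death_treated"]], v[["rr_death_untreated"]])

  seek <- data.frame(
    seek = c("conventional_first", "traditional_switch", "traditional_only"),
    p_seek = c(v[["p_conventional_first"]],
               (1 - v[["p_conventional_first"]]) * v[["p_switch_to_conventional"]],
               (1 - v[["p_conventional_first"]]) * (1 - v[["p_switch_to_conventional"]])),
    conventional = c(TRUE, TRUE, FALSE)
  )

  rows <- list()
  add <- function(seek, p, indicated, antivenom, adr, dead, amputated) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seek = seek, indicated = indicated, antivenom = antivenom, adr = adr,
      dead = dead, amputated = amputated, probability = p)
  }

  for (i in seq_len(nrow(seek))) {
    s <- seek$seek[i]; ps <- seek$p_seek[i]
    # not indicated: alive, no further branching
    add(s, ps * (1 - v[["p_indicated"]]), FALSE, FALSE, FALSE, FALSE, FALSE)
    p_ind <- ps * v[["p_indicated"]]
    arms <- if (seek$conventional[i]) {
      list(list(p = acc, antivenom = TRUE, p_death = v[["p_death_treated"]]),
           list(p = 1 - acc, antivenom = FALSE, p_death = p_du))
    } else {
      list(list(p = 1, antivenom = FALSE, p_death = p_du))
    }
    for (arm in arms) {
      if (arm$p == 0) next
      adr_branches <- if (arm$antivenom) {
        list(list(p = v[["p_adr"]], adr = TRUE),
             list(p = 1 - v[["p_adr"]], adr = FALSE))
      } else {
        list(list(p = 1, adr = FALSE))
      }
      for (ab in adr_branches) {
        if (ab$p == 0) next
        base <- p_ind * arm$p * ab$p
        add(s, base * arm$p_death, TRUE, arm$antivenom, ab$adr, TRUE, FALSE)
        surv <- base * (1 - arm$p_death)
        add(s, surv * v[["p_amputation_survivor"]], TRUE, arm$antivenom, ab$adr,
            FALSE, TRUE)
        add(s, surv * (1 - v[["p_amputation_survivor"]]), TRUE, arm$antivenom,
            ab$adr, FALSE, FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$path <- paste0(out$seek,
                     ifelse(out$indicated, "/indicated", "/not_indicated"),
                     ifelse(out$indicated,
                            ifelse(out$antivenom, "/antivenom", "/no_antivenom"), ""),
                     ifelse(out$adr, "/adr", ""),
                     ifelse(out$indicated,
                            ifelse(out$dead, "/dead",
                                   ifelse(out$amputated, "/amputated", "/alive")),
                            "/alive"))
  out[, c("path", "seek", "indicated", "antivenom", "adr", "dead", "amputated",
          "probability")]
}

#' Aggregate an enumerated path table into tree-outcome counts
#'
#' Independent aggregation route used to cross-check [run_tree]: multiplies
#' each leaf probability by the victim count and sums leaves into the outcome
#' fields.
#'
#' @param paths Data frame from [enumerate_paths].
#' @param victims Total victims to distribute over the leaves.
#' @return A named numeric vector of outcome counts.
#' @export
aggregate_paths <- function(paths, victims) {
  n <- victims * paths$probability
  conv <- paths$seek %in% c("conventional_first", "traditional_switch")
  c(victims_total = sum(n),
    not_indicated = sum(n[!paths$indicated]),
    indicated = sum(n[paths$indicated]),
    indicated_conventional = sum(n[paths$indicated & conv]),
    indicated_traditional_only = sum(n[paths$indicated & !conv]),
    treated_antivenom = sum(n[paths$antivenom]),
    untreated_indicated = sum(n[paths$indicated & !paths$antivenom]),
    adr_cases = sum(n[paths$adr]),
    deaths = sum(n[paths$dead]),
    survivors_envenomed = sum(n[paths$indicated & !paths$dead]),
    amputations = sum(n[paths$amputated]),
    not_indicated_conventional = sum(n[!paths$indicated & conv]),
    conventional_total = sum(n[conv]))
}
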