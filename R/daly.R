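#' Load a standard life table
#'
#' Reads a CSV with columns `age` (years, strictly increasing) and
#' `expectancy` (residual life expectancy in years). Residual expectancy
#' between knots is obtained by linear interpolation. The bundled default
#' (`life_table_synthetic.csv`) is a reconstruction of a global standard life
#' table of the kind used in WHO/GBD DALY templates, not the original values.
#'
#' @param path CSV file; defaults to the bundled reconstruction.
#' @return A data frame of class `life_table`.
#' @export
load_life_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "life_table_synthetic.csv",
                        package = "snakeburden", mustWork = TRUE)
  }
  lt <- utils::read.csv(path)
  if (!all(c("age", "expectancy") %in% names(lt))) {
    stop("life table must have columns 'age' and 'expectancy'", call. = FALSE)
  }
  if (any(diff(lt$age) <= 0)) stop("life table ages must be strictly increasing",
                                   call. = FALSE)
  if (any(lt$expectancy <= 0)) stop("life expectancies must be positive",
                                    call. = FALSE)
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Bundled default life table
#' @return A `life_table` data frame.
#' @export
default_life_table <- function() load_life_table()

#' Residual life expectancy at a given age
#'
#' @param age Age(s) in years; must lie within the table's age span.
#' @param table A [load_life_table] data frame.
#' @return Residual life expectancy in years (linear interpolation).
#' @export
residual_life_expectancy <- function(age, table) {
  if (any(age < min(table$age)) || any(age > max(table$age))) {
    stop("residual_life_expectancy: age outside the life table span",
         call. = FALSE)
  }
  stats::approx(table$age, table$expectancy, xout = age)$y
}

#' Disability specification for a health state
#'
#' @param condition `"episode"`, `"amputation"` or `"ptsd"`.
#' @param weight Disability weight in (0, 1).
#' @param duration Duration in years, or `"lifelong"` (residual life
#'   expectancy at the age of onset).
#' @return A list of class `disability_spec`.
#' @export
disability_spec <- function(condition, weight, duration) {
  condition <- match.arg(condition, c("episode", "amputation", "ptsd"))
  if (!(is.numeric(weight) && weight > 0 && weight < 1)) {
    stop("disability_spec: weight must be in (0, 1)", call. = FALSE)
  }
  lifelong <- identical(duration, "lifelong")
  if (!lifelong && !(is.numeric(duration) && duration > 0)) {
    stop("disability_spec: duration must be > 0 or 'lifelong'", call. = FALSE)
  }
  structure(list(condition = condition, weight = weight,
                 duration = if (lifelong) NA_real_ else duration,
                 lifelong = lifelong),
            class = "disability_spec")
}

#' Bundled default disability specifications
#'
#' Reads the packaged `disability_weights_synthetic.csv` (a reconstruction of
#' GBD-2013-style values: a short severe acute episode, a lifelong amputation
#' weight, a one-year PTSD weight). Editable: pass your own CSV with columns
#' `condition`, `weight`, `duration_years`, `lifelong`.
#'
#' @param path Optional CSV path.
#' @return Named list of [disability_spec] objects.
#' @export
default_disability_specs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "disability_weights_synthetic.csv",
                        package = "snakeburden", mustWork = TRUE)
  }
  dw <- utils::read.csv(path)
  specs <- lapply(seq_len(nrow(dw)), function(i) {
    disability_spec(dw$condition[i], dw$weight[i],
                    if (isTRUE(dw$lifelong[i])) "lifelong" else dw$duration_years[i])
  })
  stats::setNames(specs, dw$condition)
}

#' Years of life lost
#'
#' @param deaths_by_age Data frame with columns `age` and `count`.
#' @param table A life table.
#' @return Total YLL: sum of deaths times residual life expectancy at the age
#'   of death.
#' @export
yll <- function(deaths_by_age, table) {
  if (nrow(deaths_by_age) == 0) return(0)
  sum(deaths_by_age$count * residual_life_expectancy(deaths_by_age$age, table))
}

#' Years lived with disability for one condition
#'
#' @param count Number of cases.
#' @param spec A [disability_spec].
#' @param age Age at onset (years); required for lifelong conditions.
#' @param table Life table; required for lifelong conditions.
#' @return `count * weight * duration`, with duration equal to the residual
#'   life expectancy at onset when the condition is lifelong.
#' @export
yld <- function(count, spec, age = NULL, table = NULL) {
  stopifnot(inherits(spec, "disability_spec"))
  dur <- if (spec$lifelong) {
    if (is.null(age) || is.null(table)) {
      stop("yld: lifelong condition requires age and life table", call. = FALSE)
    }
    residual_life_expectancy(age, table)
  } else {
    spec$duration
  }
  sum(count * spec$weight * dur)
}

#' DALY breakdown for one country
#'
#' YLL from deaths (per stratum, at the stratum mean age at death) plus
#' YLD for the acute envenoming episode (all envenomed victims), lifelong
#' amputation YLD, and — in the PTSD scenario — PTSD YLD. DALYs are
#' undiscounted and not age-weighted; a discounting switch would be applied
#' upstream on counts, not here.
#'
#' @param outcome A `tree_outcome` from [run_tree].
#' @param specs Disability specs as from [default_disability_specs].
#' @param table A life table.
#' @param ptsd_yld PTSD years lived with disability to include (scenario
#'   analyses); 0 outside the scenario.
#' @return A list of class `daly_breakdown` with `yll`, `yld_episode`,
#'   `yld_amputation`, `yld_ptsd` and their sum `dalys` (years).
#' @export
total_dalys <- function(outcome, specs = default_disability_specs(),
                        table = default_life_table(), ptsd_yld = 0) {
  st <- outcome$strata
  y_ll <- yll(data.frame(age = st$mean_age_at_death, count = st$deaths), table)
  y_episode <- yld(outcome$indicated, specs$episode)
  y_amp <- yld(st$amputations, specs$amputation, age = st$mean_age_at_death,
               table = table)
  out <- list(yll = y_ll, yld_episode = y_episode, yld_amputation = y_amp,
              yld_ptsd = ptsd_yld)
  out$dalys <- y_ll + y_episode + y_amp + ptsd_yld
  structure(out, class = "daly_breakdown")
}

#' @export
print.daly_breakdown <- function(x, ...) {
  cat("<daly_breakdown> (years)\n")
  cat(sprintf("  YLL %.1f | YLD episode %.2f | YLD amputation %.2f | YLD PTSD %.2f\n",
              x$yll, x$yld_episode, x$yld_amputation, x$yld_ptsd))
  cat(sprintf("  DALYs %.1f\n", x$dalys))
  invisible(x)
}
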