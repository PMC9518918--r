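#' Uncertain model parameter: point estimate with a plausible range
#'
#' A `param_value` couples a base-case point estimate with a plausible range
#' (interpreted as a central 95% interval unless stated otherwise) and the
#' distribution family used when the parameter is sampled in probabilistic
#' sensitivity analysis.
#'
#' @param point Base-case value.
#' @param low,high Plausible range bounds; default to `point` (a fixed
#'   parameter). Must satisfy `low <= point <= high`.
#' @param family Sampling family, one of `"beta"`, `"gamma"`, `"lognormal"`,
#'   `"dirichlet_share"`, `"uniform"`, `"fixed"`. `"fixed"` requires
#'   `low == point == high`.
#'
#' @return An object of class `param_value`.
#' @export
#' @examples
#' param_value(2.33, 1.26, 4.06, family = "lognormal")
param_value <- function(point, low = point, high = point, family = "fixed") {
  families <- c("beta", "gamma", "lognormal", "dirichlet_share", "uniform", "fixed")
  family <- match.arg(family, families)
  stopifnot(is.numeric(point), length(point) == 1L, is.finite(point))
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L, length(high) == 1L)
  if (!(low <= point && point <= high)) {
    stop("param_value: requires low <= point <= high (got ",
         low, " / ", point, " / ", high, ")", call. = FALSE)
  }
  if (family == "fixed" && !(low == point && high == point)) {
    stop("param_value: family 'fixed' requires low == point == high", call. = FALSE)
  }
  if (family == "beta" && (low < 0 || high > 1)) {
    stop("param_value: family 'beta' is only valid on [0, 1]", call. = FALSE)
  }
  structure(list(point = point, low = low, high = high, family = family),
            class = "param_value")
}

#' @export
print.param_value <- function(x, ...) {
  cat(sprintf("<param_value> %g [%g, %g] (%s)\n", x$point, x$low, x$high, x$family))
  invisible(x)
}

is_param_value <- function(x) inherits(x, "param_value")

#' Coerce a configuration entry to a `param_value`
#'
#' Scalars become fixed parameters; lists with `point` (and optionally `low`,
#' `high`, `family`) become uncertain parameters. When `family` is absent a
#' default is chosen from the parameter kind: beta for probabilities, gamma
#' for positive quantities, lognormal for relative risks, uniform otherwise.
#'
#' @param x Scalar, list, or `param_value`.
#' @param kind One of `"probability"`, `"positive"`, `"relative_risk"`,
#'   `"share"`, `"real"`; drives validation and the default family.
#' @param name Parameter name used in error messages.
#' @return A `param_value`.
#' @export
as_param_value <- function(x, kind = "positive", name = "parameter") {
  if (is_param_value(x)) {
    pv <- x
  } else if (is.numeric(x) && length(x) == 1L) {
    pv <- param_value(x)
  } else if (is.list(x)) {
    allowed <- c("point", "low", "high", "family")
    unknown <- setdiff(names(x), allowed)
    if (length(unknown) > 0) {
      stop(sprintf("%s: unknown keys in parameter entry: %s",
                   name, paste(unknown, collapse = ", ")), call. = FALSE)
    }
    if (is.null(x$point)) {
      stop(sprintf("%s: parameter entry must have a 'point' value", name),
           call. = FALSE)
    }
    fam <- x$family
    if (is.null(fam)) {
      has_range <- !is.null(x$low) || !is.null(x$high)
      fam <- if (!has_range) "fixed" else default_family(kind)
    }
    pv <- param_value(x$point,
                      low = if (is.null(x$low)) x$point else x$low,
                      high = if (is.null(x$high)) x$point else x$high,
                      family = fam)
  } else {
    stop(sprintf("%s: cannot interpret value of class '%s' as a parameter",
                 name, class(x)[1]), call. = FALSE)
  }
  validate_param_kind(pv, kind, name)
  pv
}

default_family <- function(kind) {
  switch(kind,
         probability  = "beta",
         share        = "dirichlet_share",
         positive     = "gamma",
         relative_risk = "lognormal",
         real         = "uniform",
         stop("unknown parameter kind: ", kind, call. = FALSE))
}

validate_param_kind <- function(pv, kind, name) {
  if (kind %in% c("probability", "share")) {
    if (pv$low < 0 || pv$high > 1) {
      stop(sprintf("%s: probability must lie in [0, 1] (got [%g, %g])",
                   name, pv$low, pv$high), call. = FALSE)
    }
  }
  if (kind %in% c("positive", "relative_risk") && pv$low < 0) {
    stop(sprintf("%s: must be non-negative (got low = %g)", name, pv$low),
         call. = FALSE)
  }
  if (kind == "relative_risk" && pv$point <= 0) {
    stop(sprintf("%s: relative risk must be > 0", name), call. = FALSE)
  }
  invisible(pv)
}

# Serialize a param_value back to the configuration representation.
param_value_to_config <- function(pv) {
  if (pv$family == "fixed") return(pv$point)
  list(point = pv$point, low = pv$low, high = pv$high, family = pv$family)
}
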