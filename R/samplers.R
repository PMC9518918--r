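#' Construct a sampler for a model parameter
#'
#' Moment-matches a distribution to a [param_value]: the sampler's mean equals
#' the point estimate and its central 95% mass approximates `[low, high]`
#' (ranges are interpreted as 95% central intervals).
#'
#' Families:
#' \describe{
#'   \item{beta}{probabilities; mean = point, sd = (high - low)/3.92,
#'     shape parameters by the method of moments.}
#'   \item{gamma}{positive quantities (costs, lengths of stay, counts);
#'     mean = point, sd = (high - low)/3.92.}
#'   \item{lognormal}{relative risks; meanlog = log(point),
#'     sdlog = (log(high) - log(low))/3.92, so the geometric mean of draws is
#'     the point estimate, matching how relative risks are reported.}
#'   \item{uniform}{fallback on `[low, high]`.}
#'   \item{fixed}{degenerate at the point estimate.}
#'   \item{dirichlet_share}{handled jointly across a profile's strata; a
#'     single share is sampled as its beta marginal.}
#' }
#'
#' When the requested family cannot be moment-matched (e.g. a beta whose
#' implied variance exceeds the maximum for its mean), the sampler falls back
#' to a uniform on `[low, high]` with a warning rather than failing the run.
#'
#' @param p A [param_value].
#' @param kind One of `"probability"`, `"positive"`, `"relative_risk"`,
#'   `"share"`, `"real"`; used for support validation.
#' @return A list of class `sampler` with elements `sample(n)` (draws `n`
#'   values using the current RNG stream), `quantile(q)`, `family` (the family
#'   actually used) and `mean`.
#' @export
#' @examples
#' s <- build_sampler(param_value(0.2, 0.1, 0.3, "beta"), "probability")
#' set.seed(1); mean(s$sample(1e4))
build_sampler <- function(p, kind = "positive") {
  stopifnot(is_param_value(p))
  if (kind %in% c("probability", "share") && p$high > 1) {
    stop("build_sampler: probability range exceeds 1", call. = FALSE)
  }
  if (kind %in% c("positive", "relative_risk") && p$low < 0) {
    stop("build_sampler: negative lower bound for a positive quantity",
         call. = FALSE)
  }

  degenerate <- function(value) {
    list(sample = function(n) rep(value, n),
         quantile = function(q) rep(value, length(q)),
         family = "fixed", mean = value)
  }
  uniform_fallback <- function(reason) {
    warning(sprintf("falling back to uniform on [%g, %g]: %s",
                    p$low, p$high, reason), call. = FALSE)
    make_uniform(p)
  }

  out <- switch(p$family,
    fixed = degenerate(p$point),
    uniform = make_uniform(p),
    beta = {
      m <- p$point
      s <- (p$high - p$low) / (2 * stats::qnorm(0.975))
      if (s <= 0) degenerate(m)
      else if (m <= 0 || m >= 1) uniform_fallback("beta mean not in (0,1)")
      else if (s^2 >= m * (1 - m)) {
        uniform_fallback("range too wide for a beta with this mean")
      } else {
        nu <- m * (1 - m) / s^2 - 1
        a <- m * nu; b <- (1 - m) * nu
        list(sample = function(n) stats::rbeta(n, a, b),
             quantile = function(q) stats::qbeta(q, a, b),
             family = "beta", mean = m)
      }
    },
    gamma = {
      m <- p$point
      s <- (p$high - p$low) / (2 * stats::qnorm(0.975))
      if (s <= 0) degenerate(m)
      else if (m <= 0) uniform_fallback("gamma mean must be positive")
      else {
        shape <- m^2 / s^2; rate <- m / s^2
        list(sample = function(n) stats::rgamma(n, shape, rate),
             quantile = function(q) stats::qgamma(q, shape, rate),
             family = "gamma", mean = m)
      }
    },
    lognormal = {
      if (p$point <= 0 || p$low <= 0) {
        uniform_fallback("lognormal requires positive point and bounds")
      } else {
        mu <- log(p$point)
        sdlog <- (log(p$high) - log(p$low)) / (2 * stats::qnorm(0.975))
        if (sdlog <= 0) degenerate(p$point)
        else list(sample = function(n) stats::rlnorm(n, mu, sdlog),
                  quantile = function(q) stats::qlnorm(q, mu, sdlog),
                  family = "lognormal", mean = exp(mu + sdlog^2 / 2))
      }
    },
    dirichlet_share = {
      # marginal of a share: beta with the same mean/spread
      build_sampler(param_value(p$point, p$low, p$high, "beta"), "share")
    },
    stop("unknown family: ", p$family, call. = FALSE)
  )
  class(out) <- "sampler"
  out
}

make_uniform <- function(p) {
  if (p$low == p$high) {
    list(sample = function(n) rep(p$point, n),
         quantile = function(q) rep(p$point, length(q)),
         family = "fixed", mean = p$point)
  } else {
    list(sample = function(n) stats::runif(n, p$low, p$high),
         quantile = function(q) p$low + q * (p$high - p$low),
         family = "uniform", mean = (p$low + p$high) / 2)
  }
}

#' Sample demographic stratum shares from a Dirichlet distribution
#'
#' Draws share vectors around the base-case shares using a Dirichlet with
#' concentration `conc`: alpha = shares * conc. Larger `conc` means tighter
#' sampling around the base case.
#'
#' @param n Number of draws.
#' @param shares Base-case shares (must sum to 1).
#' @param conc Total concentration (default 100).
#' @return An `n` x `length(shares)` matrix; rows sum to 1.
#' @export
sample_shares <- function(n, shares, conc = 100) {
  stopifnot(abs(sum(shares) - 1) < 1e-9, all(shares >= 0), conc > 0)
  alpha <- shares * conc
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}
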