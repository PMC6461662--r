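#' @keywords internal
"_PACKAGE"

#' Derive a named RNG sub-stream seed from a master seed
#'
#' Each pipeline stage (cohort draw, reader perturbation, cross-validation,
#' bootstrap) consumes its own seed so that, e.g., changing the bootstrap
#' count cannot perturb the cohort draw.
#'
#' @param seed master integer seed
#' @param stream character stream name
#' @return an integer seed < 2^31
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) + 1000003 * h) %% .Machine$integer.max)
}

#' Trapezoidal quadrature weights on a uniform grid
#' @param x grid values (strictly increasing)
#' @return weights w with sum(w * f) approximating the integral of f
#' @keywords internal
trapz_weights <- function(x) {
  n <- length(x)
  stopifnot(n >= 2L)
  w <- c(diff(x), 0) / 2 + c(0, diff(x)) / 2
  w
}

#' Trapezoidal integral
#' @keywords internal
trapz <- function(x, y) sum(trapz_weights(x) * y)

#' Cumulative trapezoidal integral (same length as input, starts at 0)
#' @keywords internal
cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Solve log-normal parameters from a target median and inter-quartile range
#'
#' For X log-normal, median = exp(mu) and IQR = 2 * median * sinh(z75 * sigma)
#' with z75 = qnorm(0.75), giving a closed form for both parameters.
#'
#' @param median,iqr positive targets on the natural scale
#' @return list(meanlog, sdlog)
#' @export
lognormal_from_median_iqr <- function(median, iqr) {
  stopifnot(median > 0, iqr > 0)
  list(meanlog = log(median), sdlog = asinh(iqr / (2 * median)) / stats::qnorm(0.75))
}

#' Solve the logit-normal scale from a target median and IQR
#'
#' X = plogis(mu + sigma * Z); the median is plogis(mu) so mu is closed-form,
#' and sigma solves plogis(mu + z75 s) - plogis(mu - z75 s) = iqr by
#' monotone root finding.
#'
#' @param median target median in (0, 1)
#' @param iqr target inter-quartile range in (0, 1)
#' @return list(mu, sigma)
#' @export
logitnormal_from_median_iqr <- function(median, iqr) {
  stopifnot(median > 0, median < 1, iqr > 0, iqr < 1)
  mu <- stats::qlogis(median)
  z75 <- stats::qnorm(0.75)
  f <- function(s) stats::plogis(mu + z75 * s) - stats::plogis(mu - z75 * s) - iqr
  sigma <- stats::uniroot(f, c(1e-6, 50), tol = 1e-10)$root
  list(mu = mu, sigma = sigma)
}

#' Sample from a normal distribution truncated to [lo, hi]
#'
#' Inverse-CDF construction: consumes exactly one uniform deviate per draw,
#' which keeps cohort generation reproducible draw-for-draw.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  clamp(stats::qnorm(u, mean, sd), lo, hi)
}
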