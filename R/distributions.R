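#' Moment-matched beta shape parameters
#'
#' Converts a (mean, standard error) pair into the `shape1`/`shape2`
#' parameters of a beta distribution by the method of moments. Used to turn
#' printed parameter tables (mean with SE and a named parametric family)
#' into sampling distributions for probabilistic sensitivity analysis.
#'
#' @param mean Target mean, strictly inside (0, 1).
#' @param se Target standard error (standard deviation of the
#'   distribution), with `se^2 < mean * (1 - mean)`.
#' @param name Parameter name used in error messages.
#' @return Named numeric vector `c(shape1, shape2)`.
#' @examples
#' beta_from_moments(0.768, 0.10)   # utility of normoglycaemia
#' @export
beta_from_moments <- function(mean, se, name = "parameter") {
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    stop(sprintf("'%s': beta mean must lie strictly in (0, 1), got %g",
                 name, mean), call. = FALSE)
  }
  if (!is.finite(se) || se <= 0) {
    stop(sprintf("'%s': beta SE must be positive, got %g", name, se),
         call. = FALSE)
  }
  v <- se^2
  if (v >= mean * (1 - mean)) {
    stop(sprintf(
      "'%s': infeasible SE for a beta distribution (se^2 = %g >= mean(1-mean) = %g)",
      name, v, mean * (1 - mean)), call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Moment-matched gamma parameters
#'
#' Method-of-moments fit of a gamma distribution: `shape * scale = mean`,
#' `shape * scale^2 = se^2`.
#'
#' @inheritParams beta_from_moments
#' @param mean Target mean, > 0.
#' @param se Target standard error, > 0.
#' @return Named numeric vector `c(shape, scale)`.
#' @examples
#' gamma_from_moments(773, 102.63)  # annual cost of normoglycaemia, GBP 2015
#' @export
gamma_from_moments <- function(mean, se, name = "parameter") {
  if (!is.finite(mean) || mean <= 0) {
    stop(sprintf("'%s': gamma mean must be positive, got %g", name, mean),
         call. = FALSE)
  }
  if (!is.finite(se) || se <= 0) {
    stop(sprintf("'%s': gamma SE must be positive, got %g", name, se),
         call. = FALSE)
  }
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Moment-matched lognormal parameters
#'
#' Fits `meanlog`/`sdlog` so that the natural-scale mean and standard
#' deviation of the lognormal equal the inputs:
#' `sdlog^2 = log(1 + (se/mean)^2)`, `meanlog = log(mean) - sdlog^2 / 2`.
#' An SE of zero returns a degenerate point mass (`sdlog = 0`).
#'
#' Relative risks printed with a lognormal family and natural-scale SE are
#' fitted this way, keeping the configured mean on the ratio scale.
#'
#' @inheritParams beta_from_moments
#' @param mean Target natural-scale mean, > 0.
#' @param se Target natural-scale standard error, >= 0.
#' @return Named numeric vector `c(meanlog, sdlog)`.
#' @examples
#' lognormal_from_moments(0.74, 0.11)  # RR of T2DM during pragmatic lifestyle
#' @export
lognormal_from_moments <- function(mean, se, name = "parameter") {
  if (!is.finite(mean) || mean <= 0) {
    stop(sprintf("'%s': lognormal mean must be positive, got %g", name, mean),
         call. = FALSE)
  }
  if (!is.finite(se) || se < 0) {
    stop(sprintf("'%s': lognormal SE must be non-negative, got %g", name, se),
         call. = FALSE)
  }
  if (se == 0) {
    return(c(meanlog = log(mean), sdlog = 0))
  }
  s2 <- log(1 + (se / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Draw Monte-Carlo samples from a parameter specification
#'
#' Samples `n` values from the distribution implied by a [param_spec()]:
#' beta, gamma or lognormal fitted by the method of moments, or a constant
#' stream for `family = "fixed"` (and for any family with `se = 0`).
#'
#' @param spec A [param_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_param <- function(spec, n) {
  stopifnot(inherits(spec, "param_spec"), n >= 1)
  if (spec$family == "fixed" || spec$se == 0) {
    return(rep(spec$mean, n))
  }
  switch(spec$family,
    beta = {
      sh <- beta_from_moments(spec$mean, spec$se, spec$name)
      stats::rbeta(n, sh[["shape1"]], sh[["shape2"]])
    },
    gamma = {
      sh <- gamma_from_moments(spec$mean, spec$se, spec$name)
      stats::rgamma(n, shape = sh[["shape"]], scale = sh[["scale"]])
    },
    lognormal = {
      sh <- lognormal_from_moments(spec$mean, spec$se, spec$name)
      stats::rlnorm(n, meanlog = sh[["meanlog"]], sdlog = sh[["sdlog"]])
    },
    stop(sprintf("'%s': unknown distribution family '%s'",
                 spec$name, spec$family), call. = FALSE)
  )
}
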