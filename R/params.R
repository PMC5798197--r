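#' Scalar model parameter with a sampling distribution
#'
#' A `param_spec` couples a point estimate (used by the deterministic model)
#' with the standard error and parametric family used to sample it in
#' probabilistic sensitivity analysis, and records whether the value comes
#' from the published evidence tables (`source = "published"`) or is a
#' documented placeholder (`source = "imputed"`).
#'
#' Invariants enforced at construction:
#' * `family = "beta"`: `0 <= mean <= 1` and (`se = 0` or
#'   `se^2 < mean * (1 - mean)`);
#' * `family` in `"gamma"`/`"lognormal"`: `mean > 0`;
#' * `family = "fixed"`: `se = 0`.
#'
#' @param name Identifier, unique within a parameter registry.
#' @param mean Point estimate.
#' @param se Standard error of the sampling distribution (0 for fixed).
#' @param family One of `"fixed"`, `"beta"`, `"gamma"`, `"lognormal"`.
#' @param source `"published"` or `"imputed"`.
#' @return An object of class `param_spec`.
#' @export
param_spec <- function(name, mean, se = 0,
                       family = c("fixed", "beta", "gamma", "lognormal"),
                       source = c("published", "imputed")) {
  family <- match.arg(family)
  source <- match.arg(source)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean)) {
    stop(sprintf("'%s': mean must be a finite number", name), call. = FALSE)
  }
  if (!is.numeric(se) || length(se) != 1L || !is.finite(se) || se < 0) {
    stop(sprintf("'%s': se must be a finite non-negative number", name),
         call. = FALSE)
  }
  if (family == "fixed" && se != 0) {
    stop(sprintf("'%s': family 'fixed' requires se = 0", name), call. = FALSE)
  }
  if (family == "beta") {
    if (mean < 0 || mean > 1) {
      stop(sprintf("'%s': beta mean must lie in [0, 1], got %g", name, mean),
           call. = FALSE)
    }
    if (se > 0 && se^2 >= mean * (1 - mean)) {
      stop(sprintf(
        "'%s': infeasible SE for a beta distribution (se^2 = %g >= mean(1-mean) = %g)",
        name, se^2, mean * (1 - mean)), call. = FALSE)
    }
  }
  if (family %in% c("gamma", "lognormal") && mean <= 0) {
    stop(sprintf("'%s': family '%s' requires mean > 0, got %g",
                 name, family, mean), call. = FALSE)
  }
  structure(
    list(name = name, mean = as.numeric(mean), se = as.numeric(se),
         family = family, source = source),
    class = "param_spec"
  )
}

#' @export
print.param_spec <- function(x, ...) {
  cat(sprintf("<param_spec> %s = %g (SE %g, %s, %s)\n",
              x$name, x$mean, x$se, x$family, x$source))
  invisible(x)
}

#' Extract the point estimates of a parameter registry
#'
#' @param params Named list of [param_spec()] objects.
#' @return Named numeric vector of means.
#' @export
param_means <- function(params) {
  vapply(params, function(s) s$mean, numeric(1))
}

#' Names of imputed parameters in a registry
#'
#' @param params Named list of [param_spec()] objects.
#' @return Character vector of parameter names with `source = "imputed"`.
#' @export
imputed_names <- function(params) {
  names(params)[vapply(params, function(s) identical(s$source, "imputed"),
                       logical(1))]
}
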