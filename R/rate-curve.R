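#' Age-dependent rate-curve parameters
#'
#' The package's central model for daily oviposition rate, predation rate
#' and egg volume is the four-parameter curve
#' \deqn{y(t) = a \, t^{b} \, e^{c t + d t^2},}{y(t) = a t^b exp(c t + d t^2),}
#' where `t` is female age in days since eclosion.  With `b > 0` and
#' `c < 0`, `d = 0` the curve is gamma-shaped: zero at eclosion, rising to a
#' single interior peak and declining thereafter — the canonical shape of
#' age-specific fecundity in fast-developing arthropods.  With `b = 0` the
#' curve is a (log-)quadratic trend used for egg volumes, and with
#' `b = d = 0` a simple exponential decline used for predation rates.
#'
#' `rate_curve_params()` builds the parameter container used throughout the
#' package: by the synthetic-cohort generator (as generating truth), by
#' [fit_rate_curve()] and [fit_rate_gee()] (as estimates), and by
#' [eval_curve()] / [peak_age()].
#'
#' @param a scale parameter, must be > 0 (units of the response).
#' @param b power exponent (dimensionless); 0 means the `t^b` term is
#'   dropped from the model.
#' @param c linear exponent coefficient, per day.
#' @param d quadratic exponent coefficient, per day^2; 0 means dropped.
#' @param se optional named numeric vector of standard errors for a subset
#'   of `c("a","b","c","d")`; dropped terms must not carry an SE.
#' @param response_kind one of `"oviposition"`, `"predation"`,
#'   `"egg_volume"`.  Egg-volume curves are expressed in units of
#'   1e6 um^3 (the scale of the reported estimates).
#' @param r_squared optional fit diagnostic, `1 - SSE/SST` on the response
#'   scale of the fit.
#' @return An object of class `rate_curve_params`.
#' @examples
#' # predator oviposition under extreme heat waves (reported estimates)
#' p <- rate_curve_params(a = 0.8970, b = 1.8765, c = -0.3223)
#' eval_curve(p, 3.5:12.5)
#' peak_age(p)                     # ~5.82 days
#' @export
rate_curve_params <- function(a, b = 0, c = 0, d = 0, se = NULL,
                              response_kind = c("oviposition", "predation",
                                                "egg_volume"),
                              r_squared = NA_real_) {
  response_kind <- match.arg(response_kind)
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L,
            is.numeric(c), length(c) == 1L,
            is.numeric(d), length(d) == 1L)
  # a = 0 is admitted as the degenerate null curve (used to switch a
  # response off in simulations); fitted scales are always positive
  if (a < 0) stop("scale parameter 'a' must be >= 0", call. = FALSE)
  if (!is.na(r_squared) && r_squared > 1)
    stop("r_squared cannot exceed 1", call. = FALSE)
  included <- c("b", "c", "d")[c(b != 0, c != 0, d != 0)]
  if (!is.null(se)) {
    if (is.null(names(se)) || !all(names(se) %in% c("a", "b", "c", "d")))
      stop("'se' must be named with a subset of a, b, c, d", call. = FALSE)
    dropped <- setdiff(c("b", "c", "d"), included)
    if (any(names(se) %in% dropped))
      stop("dropped terms carry no standard error", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d, se = se,
                 included_terms = included,
                 response_kind = response_kind,
                 r_squared = r_squared),
            class = "rate_curve_params")
}

#' @export
print.rate_curve_params <- function(x, ...) {
  cat(sprintf("Age-dependent %s curve: y(t) = a t^b exp(c t + d t^2)\n",
              x$response_kind))
  est <- c(a = x$a, b = x$b, c = x$c, d = x$d)
  keep <- c("a", x$included_terms)
  out <- data.frame(estimate = est[keep])
  if (!is.null(x$se)) out$se <- unname(x$se[keep])
  print(format(out, digits = 5))
  if (!is.na(x$r_squared))
    cat(sprintf("R-squared (response scale): %.3f\n", x$r_squared))
  invisible(x)
}

#' @export
coef.rate_curve_params <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c, d = object$d)
}

#' Evaluate the age-dependent rate curve
#'
#' Computes `a * t^b * exp(c*t + d*t^2)` at ages `t`.  The model is
#' positive for all `t > 0`, and zero at `t = 0` whenever `b > 0`.
#'
#' @param params a [rate_curve_params()] object.
#' @param t vector of ages (days since eclosion); must be > 0 when `b != 0`.
#' @return Numeric vector of predicted rates (or volumes, in the curve's
#'   scaled units).
#' @export
eval_curve <- function(params, t) {
  stopifnot(inherits(params, "rate_curve_params"), is.numeric(t))
  if (params$b != 0 && any(t <= 0))
    stop("ages must be > 0 when the power term t^b is present",
         call. = FALSE)
  params$a * t^params$b * exp(params$c * t + params$d * t^2)
}

#' @export
predict.rate_curve_params <- function(object, newdata = NULL, t = NULL, ...) {
  if (is.null(t)) {
    if (!is.null(newdata) && !is.null(newdata$t)) t <- newdata$t
    else stop("supply ages via 't' or 'newdata$t'", call. = FALSE)
  }
  eval_curve(object, t)
}

#' Age at the curve's interior maximum
#'
#' Solves `d/dt log y(t) = b/t + c + 2 d t = 0` on `t > 0`.  With `d = 0`
#' the peak is at `-b/c` (requiring `b > 0`, `c < 0`); with a quadratic term
#' the stationary points solve `2 d t^2 + c t + b = 0` and the one that is a
#' local maximum is returned.  Returns `NA` when the curve has no interior
#' maximum (monotone or minimum-only).
#'
#' @param params a [rate_curve_params()] object.
#' @return Age in days, or `NA_real_`.
#' @export
peak_age <- function(params) {
  stopifnot(inherits(params, "rate_curve_params"))
  b <- params$b; cc <- params$c; d <- params$d
  if (d == 0) {
    if (b > 0 && cc < 0) return(-b / cc)
    if (b == 0) return(NA_real_)          # pure exponential: monotone
    return(NA_real_)                      # c >= 0, b > 0: increasing
  }
  disc <- cc^2 - 8 * d * b
  if (disc < 0) {
    # no real stationary point; with d < 0 and b = 0 the exponent is a
    # parabola whose vertex -c/(2d) is the maximum when c > 0
    if (b == 0 && d < 0 && cc > 0) return(-cc / (2 * d))
    return(NA_real_)
  }
  roots <- (-cc + c(-1, 1) * sqrt(disc)) / (4 * d)
  roots <- roots[roots > 0]
  if (b == 0 && d < 0) {
    v <- -cc / (2 * d)
    return(if (v > 0) v else NA_real_)
  }
  # second derivative of log y: -b/t^2 + 2d ; keep maxima only
  roots <- roots[-b / roots^2 + 2 * d < 0]
  if (!length(roots)) return(NA_real_)
  min(roots)
}
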