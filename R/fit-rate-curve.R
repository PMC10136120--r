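#' Fit the age-dependent rate curve by nonlinear least squares
#'
#' Fits \eqn{y(t) = a t^b e^{ct+dt^2}} to female-day (or egg) data on the
#' natural response scale by Levenberg-Marquardt least squares.  All
#' observations are pooled within a stratum (each female-day is one row);
#' starting values come from a back-transformed log-linear regression, so
#' fits are deterministic.
#'
#' @param formula a two-sided formula `response ~ age`, naming the response
#'   column and the age column of `data`.
#' @param data data frame of observations; one row per female-day (rates)
#'   or per egg (volumes).
#' @param include character subset of `c("b","c","d")`: which shape terms
#'   the model carries.  Excluded terms are fixed at 0.
#' @param strata optional character vector of grouping columns; one curve
#'   is fitted per stratum combination.
#' @param response_kind passed to [rate_curve_params()].
#' @param control passed to [minpack.lm::nls.lm.control()]; default uses
#'   `ftol = 1e-10`.
#' @return For `strata = NULL`, an object of class `rate_curve_fit`; else a
#'   named list of such objects (class `rate_curve_fits`).  Each fit stores
#'   the estimated [rate_curve_params()] (with SEs and R-squared), fitted
#'   values, residuals and a convergence flag.
#' @seealso [fit_rate_gee()] for the cluster-robust log-linear formulation.
#' @export
fit_rate_curve <- function(formula, data, include = c("b", "c"),
                           strata = NULL,
                           response_kind = c("oviposition", "predation",
                                             "egg_volume"),
                           control = minpack.lm::nls.lm.control(ftol = 1e-10,
                                                                maxiter = 200)) {
  response_kind <- match.arg(response_kind)
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  include <- match.arg(include, c("b", "c", "d"), several.ok = TRUE)
  vars <- all.vars(formula)
  if (length(vars) != 2L)
    stop("formula must be of the form response ~ age", call. = FALSE)
  if (!all(vars %in% names(data)))
    stop("columns not found in data: ",
         paste(setdiff(vars, names(data)), collapse = ", "), call. = FALSE)

  if (!is.null(strata)) {
    miss <- setdiff(strata, names(data))
    if (length(miss))
      stop("strata columns not found: ", paste(miss, collapse = ", "),
           call. = FALSE)
    groups <- interaction(data[strata], drop = TRUE, sep = ":")
    fits <- lapply(split(data, groups), function(d)
      fit_rate_curve(formula, d, include = include, strata = NULL,
                     response_kind = response_kind, control = control))
    class(fits) <- "rate_curve_fits"
    return(fits)
  }

  y <- data[[vars[1]]]
  t <- data[[vars[2]]]
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]; t <- t[ok]
  if (any(y < 0)) stop("responses must be nonnegative", call. = FALSE)
  if (any(t <= 0)) stop("ages must be positive", call. = FALSE)
  n_par <- 1L + length(include)
  if (length(unique(t)) < n_par + 1L)
    stop("rank deficiency: need at least ", n_par + 1L,
         " distinct ages to fit ", n_par, " parameters", call. = FALSE)

  start <- .rc_start(y, t, include, response_kind)
  has_b <- "b" %in% include
  has_c <- "c" %in% include
  has_d <- "d" %in% include
  rhs <- paste0("exp(loga",
                if (has_b) " + b*log(t)",
                if (has_c) " + c*t",
                if (has_d) " + d*I(t^2)", ")")
  fml <- stats::as.formula(paste("y ~", rhs))
  df <- data.frame(y = y, t = t)
  fit <- minpack.lm::nlsLM(fml, data = df, start = start, control = control)
  conv <- fit$convInfo$isConv
  est <- stats::coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) rep(NA_real_, length(est)))
  a <- exp(est[["loga"]])
  # delta method: SE(a) = a * SE(log a)
  se <- c(a = a * unname(ses[["loga"]]))
  if (has_b) se <- c(se, b = unname(ses[["b"]]))
  if (has_c) se <- c(se, c = unname(ses[["c"]]))
  if (has_d) se <- c(se, d = unname(ses[["d"]]))
  fitted_y <- stats::fitted(fit)
  sse <- sum((y - fitted_y)^2)
  sst <- sum((y - mean(y))^2)
  params <- rate_curve_params(
    a = a,
    b = if (has_b) est[["b"]] else 0,
    c = if (has_c) est[["c"]] else 0,
    d = if (has_d) est[["d"]] else 0,
    se = se, response_kind = response_kind,
    r_squared = 1 - sse / sst)
  structure(list(params = params, nls = fit, converged = conv,
                 n = length(y), fitted = as.numeric(fitted_y),
                 residuals = as.numeric(y - fitted_y),
                 call = match.call()),
            class = "rate_curve_fit")
}

# log-linear starting values, back-transformed; +1 offset guards log(0)
# for count/rate responses, small floor for volumes
.rc_start <- function(y, t, include, response_kind) {
  z <- if (response_kind == "egg_volume") log(pmax(y, 1e-8)) else log1p(y)
  X <- cbind(`(Intercept)` = 1,
             if ("b" %in% include) log(t),
             if ("c" %in% include) t,
             if ("d" %in% include) t^2)
  beta <- unname(qr.coef(qr(X), z))
  start <- list(loga = beta[1])
  i <- 2L
  for (term in c("b", "c", "d")) {
    if (term %in% include) { start[[term]] <- beta[i]; i <- i + 1L }
  }
  start
}

#' @export
print.rate_curve_fit <- function(x, ...) {
  cat("Nonlinear least-squares rate-curve fit",
      if (!x$converged) "(NOT CONVERGED: best iterate shown)", "\n")
  print(x$params)
  cat(sprintf("n = %d observations\n", x$n))
  invisible(x)
}

#' @export
print.rate_curve_fits <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]])
    cat("\n")
  }
  invisible(x)
}

#' @export
coef.rate_curve_fit <- function(object, ...) coef(object$params)

#' @export
predict.rate_curve_fit <- function(object, newdata = NULL, t = NULL, ...)
  predict(object$params, newdata = newdata, t = t, ...)

#' @export
residuals.rate_curve_fit <- function(object, ...) object$residuals

#' @export
fitted.rate_curve_fit <- function(object, ...) object$fitted

#' @export
summary.rate_curve_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
vcov.rate_curve_fit <- function(object, ...) stats::vcov(object$nls)

#' @export
plot.rate_curve_fit <- function(x, ...) {
  t <- eval(quote(t), envir = x$nls$m$getEnv())
  y <- x$residuals + x$fitted
  graphics::plot(t, y, xlab = "age (days)", ylab = "response",
                 col = "grey40", ...)
  tt <- seq(min(t), max(t), length.out = 200)
  graphics::lines(tt, eval_curve(x$params, tt), lwd = 2)
  invisible(x)
}
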