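#' Cluster-robust log-linear fit of the age-dependent rate model
#'
#' The log-linearization of the rate curve,
#' \deqn{\ln y(t) = \beta_0 + \beta_1 \ln t + \beta_2 t + \beta_3 t^2 +
#'   \varepsilon,}
#' is fitted as a repeated-measures model: each female contributes one row
#' per alive day, coefficients are estimated by working-independence
#' estimating equations (ordinary least squares on the log scale), and the
#' covariance is the cluster-robust sandwich over females.  This reproduces
#' Wald-type between-subject tests without positing a particular
#' within-female correlation structure.  Treatment factors (heat-wave
#' regime, acclimation, egg sex) enter as sum-to-zero main effects, i.e. as
#' multiplicative shifts of the scale parameter `a`; interactions with the
#' age terms can be requested.
#'
#' For oviposition and predation rates, 1 is added to the response before
#' taking logarithms (daily counts of 0 are common); egg volumes are logged
#' directly.  Per-term Wald chi-square statistics use Type-III (sum-to-zero)
#' coding; when `eliminate = TRUE`, non-significant terms (p > `alpha`) are
#' removed stepwise, largest p first, never removing a term that is part of
#' a retained interaction, and the elimination trace is kept.
#'
#' @param formula `response ~ age`, naming columns of `data`.
#' @param data female-day (or egg) data frame.
#' @param factors character vector of factor column names entering as main
#'   effects.
#' @param interactions character vector of extra interaction terms, written
#'   with the age aliases `lnt`, `t`, `t2` (e.g. `"regime:t"`,
#'   `"acclimated:sex"`).
#' @param cluster name of the female-identifier column (the repeated-
#'   measures unit).
#' @param include which age terms the full model carries (`"b"` = `lnt`,
#'   `"c"` = `t`, `"d"` = `t2`).
#' @param response_kind as in [rate_curve_params()]; decides the +1 offset.
#' @param eliminate logical; run backward elimination.
#' @param alpha retention threshold for elimination (default 0.05).
#' @return An object of class `rate_gee_fit` with components
#'   `coefficients`, `vcov` (clustered), `terms_table` (term, chi_square,
#'   df, p, retained), `trace` (elimination steps), `offset_plus_one`,
#'   `model` (the final `lm`), and `n_clusters`.
#' @seealso [as_rate_curve_params()] to map the age coefficients back to
#'   the natural-scale parameters.
#' @export
fit_rate_gee <- function(formula, data, factors = character(),
                         interactions = character(),
                         cluster = "female_id",
                         include = c("b", "c", "d"),
                         response_kind = c("oviposition", "predation",
                                           "egg_volume"),
                         eliminate = TRUE, alpha = 0.05) {
  response_kind <- match.arg(response_kind)
  include <- match.arg(include, c("b", "c", "d"), several.ok = TRUE)
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  vars <- all.vars(formula)
  if (length(vars) != 2L)
    stop("formula must be of the form response ~ age", call. = FALSE)
  need <- c(vars, factors, cluster)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("columns not found in data: ", paste(miss, collapse = ", "),
         call. = FALSE)

  offset_plus_one <- response_kind %in% c("oviposition", "predation")
  y <- data[[vars[1]]]
  if (any(!is.finite(y)) || any(y < 0))
    stop("responses must be finite and nonnegative", call. = FALSE)
  if (all(y == 0))
    stop("degenerate fit: all responses are zero", call. = FALSE)
  if (!offset_plus_one && any(y <= 0))
    stop("egg volumes must be strictly positive", call. = FALSE)

  df <- data.frame(
    .y = if (offset_plus_one) log1p(y) else log(y),
    lnt = log(data[[vars[2]]]),
    t = data[[vars[2]]],
    t2 = data[[vars[2]]]^2,
    .cluster = factor(data[[cluster]]))
  for (f in factors) {
    fac <- factor(data[[f]])
    stats::contrasts(fac) <- stats::contr.sum(nlevels(fac))
    df[[f]] <- fac
  }

  age_terms <- c(b = "lnt", c = "t", d = "t2")[include]
  full_terms <- c(unname(age_terms), factors, interactions)
  if (!length(full_terms)) full_terms <- "1"

  fit_one <- function(terms) {
    fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    m <- stats::lm(fml, data = df)
    if (any(is.na(stats::coef(m)))) {
      bad <- names(stats::coef(m))[is.na(stats::coef(m))]
      stop("singular design; aliased coefficients: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    V <- sandwich::vcovCL(m, cluster = df$.cluster)
    asg <- attr(stats::model.matrix(m), "assign")
    labs <- attr(stats::terms(m), "term.labels")
    tab <- do.call(rbind, lapply(seq_along(labs), function(j) {
      idx <- which(asg == j)
      b <- stats::coef(m)[idx]
      W <- drop(crossprod(b, solve(V[idx, idx, drop = FALSE], b)))
      data.frame(term = labs[j], chi_square = W, df = length(idx),
                 p = stats::pchisq(W, length(idx), lower.tail = FALSE))
    }))
    list(model = m, vcov = V, table = tab)
  }

  removable <- function(terms) {
    # a term is removable only if no retained interaction contains it
    sapply(terms, function(tm) {
      inter <- terms[grepl(":", terms) & terms != tm]
      parts <- unlist(strsplit(inter, ":", fixed = TRUE))
      !(tm %in% parts)
    })
  }

  terms <- full_terms
  trace <- character()
  res <- fit_one(terms)
  if (eliminate && !identical(terms, "1")) {
    repeat {
      tab <- res$table
      # use the fitted model's canonical term labels (R may reorder
      # interaction factors, e.g. regime:t -> t:regime)
      terms <- tab$term
      cand <- tab[tab$p > alpha & removable(tab$term), , drop = FALSE]
      if (!nrow(cand)) break
      drop_term <- cand$term[which.max(cand$p)]
      trace <- c(trace,
                 sprintf("dropped %s (chi2 = %.3f, p = %.4f)", drop_term,
                         cand$chi_square[which.max(cand$p)],
                         max(cand$p)))
      terms <- setdiff(terms, drop_term)
      if (!length(terms)) terms <- "1"
      res <- fit_one(terms)
      if (identical(terms, "1")) break
    }
  }
  tab <- res$table
  if (!is.null(tab)) tab$retained <- TRUE
  canon <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                              function(p) paste(sort(p), collapse = ":"), "")
  kept <- if (is.null(tab)) character() else tab$term
  dropped <- full_terms[!canon(full_terms) %in% canon(kept)]
  dropped <- setdiff(dropped, "1")
  structure(list(coefficients = stats::coef(res$model),
                 vcov = res$vcov,
                 terms_table = tab,
                 dropped_terms = dropped,
                 trace = trace,
                 offset_plus_one = offset_plus_one,
                 response_kind = response_kind,
                 include = include,
                 model = res$model,
                 n = nrow(df),
                 n_clusters = nlevels(df$.cluster),
                 call = match.call()),
            class = "rate_gee_fit")
}

#' @export
print.rate_gee_fit <- function(x, ...) {
  cat(sprintf("Log-linear rate model (%s%s), %d obs in %d female clusters\n",
              x$response_kind,
              if (x$offset_plus_one) ", ln(y+1)" else ", ln(y)",
              x$n, x$n_clusters))
  cat("Cluster-robust Type-III Wald tests (retained terms):\n")
  print(x$terms_table, row.names = FALSE, digits = 4)
  if (length(x$dropped_terms))
    cat("Eliminated:", paste(x$dropped_terms, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.rate_gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.rate_gee_fit <- function(object, ...) object$vcov

#' @export
summary.rate_gee_fit <- function(object, ...) {
  print(object)
  se <- sqrt(diag(object$vcov))
  cat("\nCoefficients (robust SE):\n")
  print(cbind(estimate = object$coefficients, se = se), digits = 4)
  if (length(object$trace)) {
    cat("\nElimination trace:\n")
    cat(paste0("  ", object$trace, collapse = "\n"), "\n")
  }
  invisible(object)
}

#' Predict on the response scale from a log-linear rate fit
#'
#' Back-transforms the linear predictor (`exp`), subtracting the +1 offset
#' where one was applied.
#'
#' @param object a [fit_rate_gee()] result.
#' @param newdata data frame with an age column named `t` (aliases `lnt`,
#'   `t2` are derived) plus any retained factor columns.
#' @param ... unused.
#' @export
predict.rate_gee_fit <- function(object, newdata, ...) {
  newdata$lnt <- log(newdata$t)
  newdata$t2 <- newdata$t^2
  eta <- unname(stats::predict(object$model, newdata = newdata))
  if (object$offset_plus_one) exp(eta) - 1 else exp(eta)
}

#' Map log-linear coefficients back to natural-scale curve parameters
#'
#' Reads `exp(intercept)` as the scale `a` and the `lnt`, `t`, `t2`
#' coefficients as `b`, `c`, `d`.  With sum-to-zero factor coding the
#' intercept is the grand mean on the log scale, so `a` is the geometric-
#' mean scale across factor levels.  Robust SEs are carried over (delta
#' method for `a`).
#'
#' @param fit a [fit_rate_gee()] result.
#' @return A [rate_curve_params()] object.
#' @export
as_rate_curve_params <- function(fit) {
  stopifnot(inherits(fit, "rate_gee_fit"))
  cf <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  a <- exp(cf[["(Intercept)"]])
  ses <- c(a = a * se[["(Intercept)"]])
  get <- function(nm) if (nm %in% names(cf)) cf[[nm]] else 0
  for (nm in c("lnt", "t", "t2"))
    if (nm %in% names(cf))
      ses[c(lnt = "b", t = "c", t2 = "d")[[nm]]] <- se[[nm]]
  rate_curve_params(a = a, b = get("lnt"), c = get("t"), d = get("t2"),
                    se = ses, response_kind = fit$response_kind,
                    r_squared = suppressWarnings(
                      summary(fit$model)$r.squared))
}
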