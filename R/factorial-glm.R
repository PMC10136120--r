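#' Factorial GLM with overdispersion scaling and Type-III tests
#'
#' Fits female-level summaries (10-day mean feeding damage, 2-day egg
#' totals, per-female offspring sex counts) against crossed treatment
#' factors.  Three families are supported, matching the analyses the
#' design calls for:
#' \describe{
#'   \item{`normal`}{identity link; classical two-way ANOVA.}
#'   \item{`quasi_poisson`}{log link; Poisson-type counts with the
#'     covariance scaled by the Pearson chi-square / df dispersion
#'     estimate, guarding the type-I error against extra-Poisson
#'     variation.}
#'   \item{`quasi_binomial`}{logit link for proportions
#'     (`cbind(successes, failures)` response), likewise
#'     dispersion-scaled.}
#' }
#' Factors use sum-to-zero coding and each term is tested by a Type-III
#' Wald statistic on the dispersion-scaled covariance (reported as F for
#' the normal family, scaled chi-square otherwise).  With
#' `eliminate = TRUE`, non-significant terms are removed stepwise
#' (interactions first, largest p first).
#'
#' @param formula model formula, e.g. `damage ~ regime * acclimated` or
#'   `cbind(n_female, n_male) ~ regime * acclimated`.
#' @param data female-level data frame; character/logical predictors are
#'   converted to factors.
#' @param family `"normal"`, `"quasi_poisson"` or `"quasi_binomial"`.
#' @param eliminate run backward elimination (default `TRUE`).
#' @param alpha retention threshold (default 0.05).
#' @return Object of class `factorial_glm`: the final `glm` fit plus
#'   `dispersion` (Pearson chi-square / df), `terms_table`
#'   (term, statistic, df, p, retained), `trace`, and `family_label`.
#' @export
fit_factorial <- function(formula, data,
                          family = c("normal", "quasi_poisson",
                                     "quasi_binomial"),
                          eliminate = TRUE, alpha = 0.05) {
  family <- match.arg(family)
  fam <- switch(family,
                normal = stats::gaussian(),
                quasi_poisson = stats::quasipoisson(link = "log"),
                quasi_binomial = stats::quasibinomial(link = "logit"))
  stopifnot(inherits(formula, "formula"))
  data <- as.data.frame(data)
  pred_vars <- all.vars(formula[[3]])
  miss <- setdiff(all.vars(formula), names(data))
  if (length(miss))
    stop("columns not found in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (v in pred_vars) {
    if (!is.numeric(data[[v]]) || length(unique(data[[v]])) <= 8) {
      f <- factor(data[[v]])
      if (nlevels(f) < 2)
        stop("predictor '", v, "' is constant in the data", call. = FALSE)
      stats::contrasts(f) <- stats::contr.sum(nlevels(f))
      data[[v]] <- f
    }
  }

  fit_one <- function(fml) {
    m <- suppressWarnings(stats::glm(fml, data = data, family = fam))
    if (!m$converged)
      stop("IRLS did not converge for ", deparse(fml), call. = FALSE)
    if (any(is.na(stats::coef(m)))) {
      bad <- names(stats::coef(m))[is.na(stats::coef(m))]
      stop("aliased coefficients (empty cells?): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    disp <- if (family == "normal")
      sum(stats::residuals(m, "deviance")^2) / m$df.residual
    else
      sum(stats::residuals(m, "pearson")^2) / m$df.residual
    # a numerically exact fit gives zero dispersion (and a saturated fit
    # none at all); floor it so the Wald quadratic forms stay defined
    if (!is.finite(disp)) disp <- 1
    V <- summary(m)$cov.unscaled * max(disp, 1e-12)
    asg <- attr(stats::model.matrix(m), "assign")
    labs <- attr(stats::terms(m), "term.labels")
    tab <- do.call(rbind, lapply(seq_along(labs), function(j) {
      idx <- which(asg == j)
      b <- stats::coef(m)[idx]
      W <- drop(crossprod(b, solve(V[idx, idx, drop = FALSE], b)))
      q <- length(idx)
      if (family == "normal") {
        data.frame(term = labs[j], statistic = W / q, df = q,
                   p = stats::pf(W / q, q, m$df.residual,
                                 lower.tail = FALSE))
      } else {
        data.frame(term = labs[j], statistic = W, df = q,
                   p = stats::pchisq(W, q, lower.tail = FALSE))
      }
    }))
    list(model = m, dispersion = disp, vcov = V, table = tab)
  }

  terms_now <- attr(stats::terms(formula), "term.labels")
  lhs <- deparse(formula[[2]])
  build <- function(tms) stats::as.formula(
    paste(lhs, "~", if (length(tms)) paste(tms, collapse = " + ") else "1"))
  res <- fit_one(build(terms_now))
  trace <- character()
  if (eliminate && length(terms_now)) {
    repeat {
      tab <- res$table
      if (is.null(tab) || !nrow(tab)) break
      rem <- vapply(tab$term, function(tm) {
        inter <- tab$term[grepl(":", tab$term) & tab$term != tm]
        !(tm %in% unlist(strsplit(inter, ":", fixed = TRUE)))
      }, logical(1))
      cand <- tab[tab$p > alpha & rem, , drop = FALSE]
      if (!nrow(cand)) break
      dr <- cand$term[which.max(cand$p)]
      trace <- c(trace, sprintf("dropped %s (p = %.4f)", dr, max(cand$p)))
      terms_now <- setdiff(terms_now, dr)
      res <- fit_one(build(terms_now))
      if (!length(terms_now)) break
    }
  }
  tab <- res$table
  if (!is.null(tab) && nrow(tab)) tab$retained <- TRUE
  structure(list(model = res$model, dispersion = res$dispersion,
                 vcov = res$vcov, terms_table = tab, trace = trace,
                 family_label = family, alpha = alpha,
                 call = match.call()),
            class = "factorial_glm")
}

#' @export
print.factorial_glm <- function(x, ...) {
  cat(sprintf("Factorial %s GLM (dispersion = %.3f)\n", x$family_label,
              x$dispersion))
  if (!is.null(x$terms_table) && nrow(x$terms_table)) {
    cat("Type-III tests (retained terms):\n")
    print(x$terms_table, row.names = FALSE, digits = 4)
  } else cat("Intercept-only model (all terms eliminated)\n")
  if (length(x$trace)) cat(paste0("  ", x$trace, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
coef.factorial_glm <- function(object, ...) stats::coef(object$model)

#' @export
vcov.factorial_glm <- function(object, ...) object$vcov

#' @export
summary.factorial_glm <- function(object, ...) {
  print(object)
  cat("\nCoefficients (dispersion-scaled SE):\n")
  print(cbind(estimate = stats::coef(object$model),
              se = sqrt(diag(object$vcov))), digits = 4)
  invisible(object)
}

#' @export
predict.factorial_glm <- function(object, newdata, type = "response", ...)
  stats::predict(object$model, newdata = newdata, type = type, ...)

# link-scale EMM rows for one factor's levels: intercept + own contrast
# columns, every other term's columns at 0 (= average under sum coding)
.emm_rows <- function(fit, factor_name) {
  m <- fit$model
  X <- stats::model.matrix(m)
  asg <- attr(X, "assign")
  labs <- attr(stats::terms(m), "term.labels")
  if (!factor_name %in% labs)
    stop("factor '", factor_name, "' not retained in the fit",
         call. = FALSE)
  fac <- m$model[[factor_name]]
  lv <- levels(fac)
  C <- stats::contrasts(fac)
  L <- matrix(0, length(lv), ncol(X), dimnames = list(lv, colnames(X)))
  L[, asg == 0] <- 1
  own <- which(asg == which(labs == factor_name))
  L[, own] <- C
  L
}

#' Post-hoc contrasts between factor levels
#'
#' All pairwise differences of the factor's estimated marginal means on
#' the link scale (other factors averaged out under sum-to-zero coding).
#' For the normal family, pairwise p-values use the exact Tukey
#' studentized-range distribution on the residual df; for quasi families,
#' dispersion-scaled Wald z tests with a Holm step-down adjustment are
#' used (labelled `"tukey-analogue"`).  `adjustment = "dunnett_style"`
#' restricts to control-versus-others contrasts (the first factor level is
#' the control), Holm-adjusted.
#'
#' @param fit a [fit_factorial()] result.
#' @param factor_name name of a retained factor with >= 2 levels.
#' @param adjustment `"tukey"`, `"dunnett_style"` or `"holm"`.
#' @return Data frame of class `contrast_table`: `contrast`, `estimate`
#'   (link scale), `se`, `statistic`, `p_raw`, `p_adj`.
#' @export
posthoc_contrasts <- function(fit, factor_name,
                              adjustment = c("tukey", "dunnett_style",
                                             "holm")) {
  adjustment <- match.arg(adjustment)
  stopifnot(inherits(fit, "factorial_glm"))
  L <- .emm_rows(fit, factor_name)
  lv <- rownames(L)
  V <- fit$vcov
  b <- stats::coef(fit$model)
  pairs <- if (adjustment == "dunnett_style")
    lapply(lv[-1], function(l) c(lv[1], l))
  else utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    l <- L[pr[1], ] - L[pr[2], ]
    est <- drop(l %*% b)
    se <- sqrt(drop(t(l) %*% V %*% l))
    stat <- est / se
    data.frame(contrast = paste(pr[1], "-", pr[2]), estimate = est,
               se = se, statistic = stat, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  df_res <- fit$model$df.residual
  if (fit$family_label == "normal") {
    out$p_raw <- 2 * stats::pt(-abs(out$statistic), df_res)
    if (adjustment == "tukey") {
      out$p_adj <- stats::ptukey(sqrt(2) * abs(out$statistic),
                                 nmeans = length(lv), df = df_res,
                                 lower.tail = FALSE)
    } else {
      out$p_adj <- stats::p.adjust(out$p_raw, "holm")
    }
  } else {
    out$p_raw <- 2 * stats::pnorm(-abs(out$statistic))
    out$p_adj <- stats::p.adjust(out$p_raw, "holm")
  }
  out$p_adj <- pmax(out$p_adj, out$p_raw)
  attr(out, "adjustment") <- if (fit$family_label != "normal" &&
                                 adjustment == "tukey")
    "tukey-analogue (Holm)" else adjustment
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' @export
print.contrast_table <- function(x, ...) {
  cat("Post-hoc contrasts (", attr(x, "adjustment"), " adjustment):\n",
      sep = "")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Offspring sex-ratio analysis
#'
#' Aggregates sexed eggs to per-female counts of female and male offspring
#' over the observation period and fits a dispersion-scaled logistic
#' (quasi-binomial) model of the female proportion on the treatment
#' factors.  Pooled female proportions are reported overall and per factor
#' level.  If a `females` table is supplied, only mothers that survived
#' the whole period (`fate == "survived"`) are kept, matching the source
#' analysis population.
#'
#' @param eggs egg-observation table with `female_id`, `sex`
#'   (`"female"`/`"male"`; other values are treated as unsexed and
#'   dropped) and the factor columns.
#' @param factors character vector of factor columns (default
#'   `c("regime", "acclimated")`).
#' @param females optional female(-day) table used to restrict to
#'   survivors.
#' @param eliminate,alpha passed to [fit_factorial()].
#' @return A list of class `sex_ratio_analysis`: `fit` (a
#'   [fit_factorial()] result, or `NULL` at a boundary), `pooled`
#'   (overall n sexed, n female, proportion), `by_level` (per factor
#'   level), `boundary` (`TRUE` when the pooled proportion is 0 or 1).
#' @export
sex_ratio_analysis <- function(eggs, factors = c("regime", "acclimated"),
                               females = NULL, eliminate = TRUE,
                               alpha = 0.05) {
  stopifnot(is.data.frame(eggs), "sex" %in% names(eggs),
            "female_id" %in% names(eggs))
  miss <- setdiff(factors, names(eggs))
  if (length(miss))
    stop("factor columns not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sexed <- eggs[eggs$sex %in% c("female", "male"), , drop = FALSE]
  if (!is.null(females)) {
    surv <- unique(females$female_id[females$fate == "survived"])
    sexed <- sexed[sexed$female_id %in% surv, , drop = FALSE]
  }
  if (!nrow(sexed)) stop("no sexed eggs", call. = FALSE)

  agg <- stats::aggregate(cbind(n_female = sex == "female",
                                n_male = sex == "male") ~ female_id,
                          data = sexed, FUN = sum)
  fac_per_female <- sexed[!duplicated(sexed$female_id),
                          c("female_id", factors), drop = FALSE]
  agg <- merge(agg, fac_per_female, by = "female_id")

  n_f <- sum(agg$n_female); n_tot <- sum(agg$n_female + agg$n_male)
  pooled <- data.frame(n_sexed = n_tot, n_female = n_f,
                       prop_female = n_f / n_tot)
  by_level <- do.call(rbind, lapply(factors, function(f) {
    do.call(rbind, lapply(split(agg, agg[[f]]), function(d) {
      nf <- sum(d$n_female); nt <- sum(d$n_female + d$n_male)
      data.frame(factor = f, level = as.character(d[[f]][1]),
                 n_sexed = nt, n_female = nf, prop_female = nf / nt)
    }))
  }))
  rownames(by_level) <- NULL

  boundary <- pooled$prop_female %in% c(0, 1)
  fit <- NULL
  if (!boundary) {
    # factors that actually vary among the sexed mothers; the interaction
    # is only estimable when every factor-level cell holds a mother
    varying <- factors[vapply(factors, function(f)
      length(unique(agg[[f]])) > 1, logical(1))]
    rhs <- if (!length(varying)) "1"
    else if (length(varying) > 1 &&
             all(table(agg[varying]) > 0))
      paste(varying, collapse = " * ")
    else paste(varying, collapse = " + ")
    fml <- stats::as.formula(paste("cbind(n_female, n_male) ~", rhs))
    fit <- fit_factorial(fml, agg, family = "quasi_binomial",
                         eliminate = eliminate, alpha = alpha)
  }
  structure(list(fit = fit, pooled = pooled, by_level = by_level,
                 boundary = boundary, n_mothers = nrow(agg)),
            class = "sex_ratio_analysis")
}

#' @export
print.sex_ratio_analysis <- function(x, ...) {
  cat(sprintf("Sex ratio: %d of %d sexed eggs female (%.1f%%), %d mothers\n",
              x$pooled$n_female, x$pooled$n_sexed,
              100 * x$pooled$prop_female, x$n_mothers))
  print(x$by_level, row.names = FALSE, digits = 3)
  if (x$boundary) cat("Boundary fit: all eggs of one sex; no GLM fitted\n")
  else print(x$fit)
  invisible(x)
}
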