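#' Ratio of two treatment means with delta-method confidence limits
#'
#' Summarizes a heat-wave effect as the ratio `m = a/b` of the mean daily
#' oviposition rate under extreme conditions (`a`) to that under mild
#' conditions (`b`), with a first-order delta-method (Taylor) standard
#' error for the ratio of two independent means:
#' \deqn{SE(m) = m\sqrt{(SE_a/a)^2 + (SE_b/b)^2},}
#' and a 95% confidence interval `m +/- t(0.975, n_a + n_b - 2) SE(m)`.
#' The approximation is accurate when the denominator's coefficient of
#' variation is small (roughly `SE_b/b < 0.1`), which holds for the
#' group sizes used here.
#'
#' @param a_mean,a_se,a_n numerator group mean, its standard error, and
#'   group size.
#' @param b_mean,b_se,b_n denominator group likewise; `b_mean` must be
#'   nonzero.
#' @param censoring `"censored"` (only females alive at day 10) or
#'   `"uncensored"` (all females) — a label recording which data entered
#'   the means; it does not alter the computation.
#' @return An object of class `ratio_result` with fields `m`, `se`,
#'   `ci` (length 2), the inputs, and `censoring`.
#' @examples
#' ratio_of_means(3.199, 0.115, 93, 1.788, 0.111, 86)  # m = 1.789, SE = 0.128
#' @export
ratio_of_means <- function(a_mean, a_se, a_n, b_mean, b_se, b_n,
                           censoring = c("uncensored", "censored")) {
  censoring <- match.arg(censoring)
  stopifnot(is.numeric(a_mean), is.numeric(b_mean),
            a_se >= 0, b_se >= 0, a_n >= 2, b_n >= 2)
  if (b_mean == 0)
    stop("undefined ratio: denominator mean is zero", call. = FALSE)
  m <- a_mean / b_mean
  se <- abs(m) * sqrt((a_se / a_mean)^2 + (b_se / b_mean)^2)
  df <- a_n + b_n - 2
  tq <- stats::qt(0.975, df)
  structure(list(m = m, se = se, ci = c(m - tq * se, m + tq * se), df = df,
                 a_mean = a_mean, a_se = a_se, a_n = a_n,
                 b_mean = b_mean, b_se = b_se, b_n = b_n,
                 censoring = censoring),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("Ratio of means (%s): m = %.3f +/- %.3f (95%% CI %.3f-%.3f)\n",
              x$censoring, x$m, x$se, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Test the difference between two ratios of means
#'
#' Two independent ratio estimates are compared by
#' `t = (m1 - m2) / sqrt(SE1^2 + SE2^2)` on `df` degrees of freedom
#' (default: the total of the four group sizes minus 4), two-sided.
#'
#' @param r1,r2 [ratio_of_means()] results.
#' @param df degrees of freedom; defaults to
#'   `r1$a_n + r1$b_n + r2$a_n + r2$b_n - 4`.
#' @return An object of classes `ratio_comparison` and `htest`.
#' @export
compare_ratios <- function(r1, r2, df = NULL) {
  stopifnot(inherits(r1, "ratio_result"), inherits(r2, "ratio_result"))
  if (r1$se <= 0 || r2$se <= 0)
    stop("both ratios must have positive SEs", call. = FALSE)
  if (is.null(df)) df <- r1$a_n + r1$b_n + r2$a_n + r2$b_n - 4
  diff <- r1$m - r2$m
  se <- sqrt(r1$se^2 + r2$se^2)
  tval <- diff / se
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(statistic = c(t = tval), parameter = c(df = df),
                 p.value = p, estimate = c(difference = diff, se = se),
                 method = "difference between two ratios of means (delta method)",
                 data.name = sprintf("m1 = %.3f vs m2 = %.3f", r1$m, r2$m)),
            class = c("ratio_comparison", "htest"))
}

#' Percent change between two means
#'
#' `100 * (a - b) / b`, the relative gain of the extreme-regime mean `a`
#' over the mild-regime mean `b`.
#'
#' @param a_mean,b_mean the two means; `b_mean` must be nonzero.
#' @return Percent change (a bare number, e.g. `25.22`).
#' @export
percent_change <- function(a_mean, b_mean) {
  if (any(b_mean == 0)) stop("zero denominator", call. = FALSE)
  100 * (a_mean - b_mean) / b_mean
}
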