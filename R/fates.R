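#' Tally final fates per group
#'
#' Counts escaped, died and surviving females per group and recomputes the
#' percentages (100 * count / n).  Works from a female-day table (one
#' `fate` per `female_id`) or from a pre-collapsed one-row-per-female
#' table.
#'
#' @param females female(-day) data frame with columns `female_id` and
#'   `fate` (`survived`/`escaped`/`died`).
#' @param group_by character vector of grouping columns (default none:
#'   a single pooled tally).
#' @return A data frame of class `fate_tally`: one row per group with
#'   `n_total`, `n_escaped`, `n_died`, `n_survived` and the matching
#'   `pct_*` columns (percentages are `NA` when `n_total` is 0).
#' @examples
#' ## the pooled predator tally reported for the source experiment:
#' ## 134 escaped of 188 -> 71.28 %
#' @export
tally_fates <- function(females, group_by = character()) {
  stopifnot(is.data.frame(females),
            all(c("female_id", "fate") %in% names(females)))
  miss <- setdiff(group_by, names(females))
  if (length(miss))
    stop("grouping columns not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  per_female <- females[!duplicated(females$female_id),
                        c("female_id", "fate", group_by), drop = FALSE]
  if (!all(per_female$fate %in% c("survived", "escaped", "died")))
    stop("unresolved fates in input", call. = FALSE)
  grp <- if (length(group_by))
    interaction(per_female[group_by], drop = FALSE, sep = ":")
  else factor(rep("all", nrow(per_female)))
  tab <- lapply(levels(grp), function(g) {
    f <- per_female$fate[grp == g]
    n <- length(f)
    counts <- c(escaped = sum(f == "escaped"), died = sum(f == "died"),
                survived = sum(f == "survived"))
    pct <- if (n > 0) 100 * counts / n else rep(NA_real_, 3)
    data.frame(group = g, n_total = n,
               n_escaped = counts[["escaped"]], n_died = counts[["died"]],
               n_survived = counts[["survived"]],
               pct_escaped = pct[[1]], pct_died = pct[[2]],
               pct_survived = pct[[3]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tab)
  class(out) <- c("fate_tally", "data.frame")
  out
}

#' @export
print.fate_tally <- function(x, ...) {
  y <- as.data.frame(x)
  for (cc in grep("^pct_", names(y))) y[[cc]] <- round(y[[cc]], 2)
  print(y, row.names = FALSE)
  invisible(x)
}

# collapse a female-day table to one (time, event) row per female for a
# given endpoint; the competing fate censors at its day, survivors censor
# at the last observation day
.km_data <- function(females, endpoint, restrict = FALSE) {
  stopifnot(all(c("female_id", "fate") %in% names(females)))
  per <- females[!duplicated(females$female_id), , drop = FALSE]
  n_days <- if ("day" %in% names(females)) max(females$day) else 10L
  other <- if (endpoint == "escape") "died" else "escaped"
  target <- if (endpoint == "escape") "escaped" else "died"
  if (restrict) per <- per[per$fate != other, , drop = FALSE]
  time <- ifelse(is.na(per$fate_day), n_days, per$fate_day)
  event <- as.integer(per$fate == target)
  data.frame(female_id = per$female_id, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier escape or survival function
#'
#' Product-limit estimate of `f(t)`, the probability of still residing on
#' the leaf arena (endpoint `"escape"`) or of being alive among
#' non-escapers (endpoint `"death"`), with `f(0) = 1` and daily (integer)
#' event resolution.  The competing fate censors: deaths censor the escape
#' endpoint at the fate day and vice versa.  For the death endpoint the
#' default follows the source convention of conditioning on never-escapers
#' (`restrict = TRUE` drops escaped females entirely); set
#' `restrict = FALSE` to keep escapers as censored observations instead.
#' Estimation is delegated to [survival::survfit()].
#'
#' @param females female(-day) data frame (see [simulate_cohort()] for the
#'   layout); needs `female_id`, `fate`, `fate_day` and (optionally) `day`.
#' @param endpoint `"escape"` or `"death"`.
#' @param restrict drop females with the competing fate rather than
#'   censoring them (default `TRUE` for `endpoint = "death"`, `FALSE`
#'   otherwise).
#' @return Object of class `km_curve`: data frame with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `estimate`, plus attributes `endpoint` and
#'   `n`.
#' @export
km_curve <- function(females, endpoint = c("escape", "death"),
                     restrict = NULL) {
  endpoint <- match.arg(endpoint)
  if (is.null(restrict)) restrict <- endpoint == "death"
  d <- .km_data(females, endpoint, restrict)
  if (!nrow(d)) stop("no females at risk for endpoint ", endpoint,
                     call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    estimate = sf$surv)
  structure(out, class = c("km_curve", "data.frame"),
            endpoint = endpoint, n = nrow(d), restrict = restrict)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier %s function, n = %d females\n",
              attr(x, "endpoint"), attr(x, "n")))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  t <- c(0, as.data.frame(x)$time)
  f <- c(1, as.data.frame(x)$estimate)
  graphics::plot(t, f, type = "s", ylim = c(0, 1), xlab = "day",
                 ylab = sprintf("f(t), %s endpoint", attr(x, "endpoint")),
                 ...)
  invisible(x)
}

#' Evaluate a KM step function at given times
#'
#' @param curve a [km_curve()].
#' @param t times (days).
#' @return `f(t)`; 1 before the first event.
#' @export
km_at <- function(curve, t) {
  df <- as.data.frame(curve)
  vapply(t, function(tt) {
    i <- which(df$time <= tt)
    if (!length(i)) 1 else df$estimate[max(i)]
  }, numeric(1))
}

# Gehan-Breslow machinery on (time, event, group) ---------------------------

# per-event-time risk/event breakdown across k groups
.risk_table <- function(time, event, group) {
  g <- levels(group)
  ts <- sort(unique(time[event == 1]))
  lapply(ts, function(tt) {
    at_risk <- time >= tt
    list(time = tt,
         n = sum(at_risk),
         d = sum(event == 1 & time == tt),
         n_g = vapply(g, function(gg) sum(at_risk & group == gg), 0),
         d_g = vapply(g, function(gg)
           sum(event == 1 & time == tt & group == gg), 0))
  })
}

# weighted observed-minus-expected vector and hypergeometric covariance;
# weights w_i = total number at risk (the Gehan-Breslow choice)
.gehan_stat <- function(time, event, group) {
  rt <- .risk_table(time, event, group)
  k <- nlevels(group)
  U <- numeric(k)
  V <- matrix(0, k, k)
  for (e in rt) {
    w <- e$n
    E <- e$d * e$n_g / e$n
    U <- U + w * (e$d_g - E)
    if (e$n > 1) {
      p <- e$n_g / e$n
      hyper <- e$d * (e$n - e$d) / (e$n - 1)
      # multivariate hypergeometric: Cov(d_g, d_h) =
      #   d(n-d)/(n-1) * (diag(p) - p p'),  p = n_g/n
      V <- V + w^2 * hyper * (diag(p, nrow = k) - tcrossprod(p))
    }
  }
  list(U = U, V = V)
}

#' Gehan-Breslow (generalized Wilcoxon) test for homogeneity of KM functions
#'
#' Compares two or more groups' escape or survival experiences with the
#' Breslow weighting: each distinct event time contributes its
#' observed-minus-expected events weighted by the total number at risk, so
#' early differences (when many are at risk) weigh most — appropriate for
#' daily fate data in which most events happen early.  The covariance is
#' the conditional permutation (hypergeometric) form; the statistic is the
#' quadratic form `U' V^- U` on `k - 1` degrees of freedom.
#'
#' Because the chi-square reference is asymptotic, an exact/Monte-Carlo
#' permutation p-value (relabelling group membership) is available via
#' `p_method = "permutation"` and is preferable for very small samples.
#'
#' @param time,event,group event day, event indicator (1 = endpoint event,
#'   0 = censored), and group factor, one entry per female.  Alternatively
#'   pass a data frame as `time` with columns `time`, `event`, `group`.
#' @param p_method `"asymptotic"` (chi-square, default) or
#'   `"permutation"`.
#' @param n_perm Monte-Carlo permutations when `p_method = "permutation"`
#'   and exhaustive enumeration is infeasible (default `1e4`).
#' @param exhaustive_limit enumerate all group relabellings exactly when
#'   the number of distinct two-group assignments is at most this
#'   (default 20000, two-group data only).
#' @return Object of classes `breslow_test` and `htest` with `statistic`
#'   (chi-square), `parameter` (df), `p.value`, and `group_labels`.
#' @export
breslow_test <- function(time, event = NULL, group = NULL,
                         p_method = c("asymptotic", "permutation"),
                         n_perm = 10000L, exhaustive_limit = 20000L) {
  p_method <- match.arg(p_method)
  if (is.data.frame(time)) {
    df <- time
    stopifnot(all(c("time", "event", "group") %in% names(df)))
    time <- df$time; event <- df$event; group <- df$group
  }
  group <- droplevels(factor(group))
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (nlevels(group) < 2)
    stop("need at least two groups", call. = FALSE)
  if (sum(event) == 0)
    stop("no events in any group: statistic undefined", call. = FALSE)

  chisq_of <- function(grp) {
    st <- .gehan_stat(time, event, grp)
    k <- nlevels(grp)
    Um <- st$U[-k]
    Vm <- st$V[-k, -k, drop = FALSE]
    Vinv <- tryCatch(solve(Vm), error = function(e) MASS::ginv(Vm))
    drop(crossprod(Um, Vinv %*% Um))
  }
  chi <- chisq_of(group)
  df <- nlevels(group) - 1L
  if (p_method == "asymptotic") {
    p <- stats::pchisq(chi, df, lower.tail = FALSE)
  } else {
    # permutation test: relabel group membership and recompute the weighted
    # statistic.  For two groups the permuted statistic is |U_1| (the
    # first group's weighted observed-minus-expected events) — the classic
    # Gehan permutation test; for k > 2 the chi-square form is permuted.
    two <- nlevels(group) == 2L
    stat_of <- if (two) {
      function(grp) abs(.gehan_stat(time, event, grp)$U[1])
    } else chisq_of
    obs <- stat_of(group)
    n <- length(group)
    sizes <- table(group)
    if (two && choose(n, sizes[1]) <= exhaustive_limit) {
      combs <- utils::combn(n, sizes[1])
      stats_all <- apply(combs, 2, function(idx) {
        g <- factor(ifelse(seq_len(n) %in% idx, levels(group)[1],
                           levels(group)[2]), levels = levels(group))
        stat_of(g)
      })
      p <- mean(stats_all >= obs - 1e-12)
    } else {
      stats_all <- replicate(n_perm, stat_of(
        factor(sample(as.character(group)), levels = levels(group))))
      p <- (1 + sum(stats_all >= obs - 1e-12)) / (n_perm + 1)
    }
  }
  structure(list(statistic = c(`chi-square` = chi),
                 parameter = c(df = df), p.value = p,
                 method = paste0("Gehan-Breslow generalized Wilcoxon test (",
                                 p_method, " p)"),
                 data.name = paste(levels(group), collapse = " vs "),
                 group_labels = levels(group)),
            class = c("breslow_test", "htest"))
}
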