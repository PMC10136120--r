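# shared fixtures and independent oracles, all built in code

# reported curve estimates used as generating truths in recovery checks
pred_extreme_ovi <- function() rate_curve_params(0.8970, 1.8765, -0.3223)
prey_mild_ovi <- function() rate_curve_params(0.5416, 2.8919, -0.3723)
prey_mild_eggsize <- function() list(
  female = rate_curve_params(0.9490, 0, 0.0747, -0.0044,
                             response_kind = "egg_volume"),
  male = rate_curve_params(0.9722, 0, 0.0559, -0.0028,
                           response_kind = "egg_volume"))

# minimal per-female fate table in the female-day layout (one row per
# female suffices for fate/KM operations)
make_fate_table <- function(fate, fate_day = NA_integer_,
                            regime = "mild", species = "prey",
                            n_days = 10L) {
  n <- length(fate)
  data.frame(female_id = sprintf("F%03d", seq_len(n)),
             species = species, acclimated = FALSE,
             regime = rep_len(regime, n),
             day = pmin(ifelse(is.na(fate_day), n_days, fate_day), n_days),
             age = 3.5, status = ifelse(fate == "survived", "alive", fate),
             eggs = 0, consumption = 0,
             fate = fate, fate_day = fate_day,
             stringsAsFactors = FALSE)
}

# independent Gehan statistic via pairwise definite-ordering scores
# (Mantel identity: |score sum over group 1| equals the |weighted O-E|)
gehan_pairwise_W <- function(time, event, group) {
  n <- length(time)
  lev <- levels(factor(group))
  c_i <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[j] == 1 &&
        (time[i] > time[j] || (time[i] == time[j] && event[i] == 0)))
      c_i[i] <- c_i[i] + 1
    if (event[i] == 1 &&
        (time[j] > time[i] || (time[i] == time[j] && event[j] == 0)))
      c_i[i] <- c_i[i] - 1
  }
  sum(c_i[group == lev[1]])
}

# exhaustive permutation p-value of |pairwise Gehan W| for two groups
gehan_perm_oracle <- function(time, event, group) {
  group <- factor(group)
  n <- length(time)
  n1 <- sum(group == levels(group)[1])
  obs <- abs(gehan_pairwise_W(time, event, group))
  combs <- utils::combn(n, n1)
  stats <- apply(combs, 2, function(idx) {
    g <- factor(ifelse(seq_len(n) %in% idx, levels(group)[1],
                       levels(group)[2]), levels = levels(group))
    abs(gehan_pairwise_W(time, event, g))
  })
  mean(stats >= obs - 1e-12)
}

# exact fate-fraction recursion for the daily competing-hazard process:
# escape drawn first, then death, over n_days days
competing_fate_probs <- function(h_escape, h_death, n_days = 10L) {
  p_alive <- 1
  p_esc <- 0
  p_die <- 0
  for (d in seq_len(n_days)) {
    p_esc <- p_esc + p_alive * h_escape
    p_die <- p_die + p_alive * (1 - h_escape) * h_death
    p_alive <- p_alive * (1 - h_escape) * (1 - h_death)
  }
  c(escape = p_esc, death = p_die, survive = p_alive)
}
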