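test_that("configs validate hazards, probabilities and sizes", {
  expect_error(cohort_config("prey", daily_escape_hazard = 1.2, seed = 1),
               "hazards")
  expect_error(cohort_config("prey", p_female = -0.1, seed = 1),
               "p_female")
  expect_error(cohort_config("prey", n_females = 0, seed = 1),
               "n_females")
  expect_error(cohort_config("prey", count_dispersion = 0.5, seed = 1),
               "dispersion")
  expect_error(cohort_config("prey", n_females = 5), "seed")
})

test_that("a fixed seed gives bit-identical cohorts", {
  cfg <- cohort_config("predator", regime = "extreme", n_females = 30,
                       daily_escape_hazard = 0.1, daily_death_hazard = 0.03,
                       oviposition_params = pred_extreme_ovi(),
                       eggsize_params = list(
                         female = rate_curve_params(4.0776, 0, -0.0116,
                                                    0.00095,
                                                    response_kind = "egg_volume"),
                         male = rate_curve_params(3.7318, 0, -0.0334,
                                                  0.00033,
                                                  response_kind = "egg_volume")),
                       seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$females, s2$females)
  expect_identical(s1$eggs, s2$eggs)
})

test_that("zero hazards keep every female alive for all ten days", {
  cfg <- cohort_config("prey", n_females = 25, seed = 4,
                       oviposition_params = prey_mild_ovi())
  s <- simulate_cohort(cfg)
  expect_true(all(s$females$fate == "survived"))
  expect_equal(sum(s$females$status == "alive"), 25 * 10)
  expect_true(all(table(s$females$female_id) == 10))
})

test_that("a null oviposition curve yields no eggs and no observations", {
  cfg <- cohort_config("prey", n_females = 20, seed = 5,
                       oviposition_params = rate_curve_params(0, 2.9, -0.37),
                       eggsize_params = prey_mild_eggsize())
  s <- simulate_cohort(cfg)
  expect_true(all(s$females$eggs[s$females$status == "alive"] == 0))
  expect_equal(nrow(s$eggs), 0L)
})

test_that("fates are absorbing and eggs stop strictly before the fate day", {
  cfg <- cohort_config("predator", regime = "extreme", n_females = 200,
                       daily_escape_hazard = 0.12, daily_death_hazard = 0.05,
                       oviposition_params = pred_extreme_ovi(), seed = 8)
  f <- simulate_cohort(cfg)$females
  expect_true(all(is.na(f$fate_day) | f$day <= f$fate_day))
  ev <- !is.na(f$fate_day) & f$day == f$fate_day
  expect_true(all(f$status[ev] %in% c("escaped", "died")))
  expect_true(all(is.na(f$eggs[ev])))
  last <- f[!duplicated(f$female_id, fromLast = TRUE), ]
  expect_true(all((last$fate == "survived") == (last$status == "alive")))
})

test_that("10-day fate fractions match the competing-hazard recursion", {
  he <- 0.05; hd <- 0.02
  cfg <- cohort_config("prey", n_females = 10000, seed = 21,
                       daily_escape_hazard = he, daily_death_hazard = hd)
  per <- simulate_cohort(cfg)$females
  per <- per[!duplicated(per$female_id), ]
  truth <- competing_fate_probs(he, hd)
  for (fate in c("escaped", "died", "survived")) {
    p_hat <- mean(per$fate == fate)
    p0 <- truth[[c(escaped = "escape", died = "death",
                   survived = "survive")[[fate]]]]
    se <- sqrt(p0 * (1 - p0) / 10000)
    expect_lt(abs(p_hat - p0), 3 * se)
  }
})

test_that("age-binned mean egg counts converge to the generating curve", {
  cfg <- cohort_config("prey", n_females = 3000, seed = 31,
                       oviposition_params = prey_mild_ovi())
  f <- simulate_cohort(cfg)$females
  for (ag in c(3.5, 6.5, 9.5, 12.5)) {
    d <- f$eggs[f$age == ag & f$status == "alive"]
    mu <- eval_curve(prey_mild_ovi(), ag)
    # NB dispersion 2 plus lognormal frailty (sd 0.2) on the mean
    v <- 2 * mu + (exp(0.2^2) - 1) * mu^2
    expect_lt(abs(mean(d) - mu), 3 * sqrt(v / length(d)))
  }
})

test_that("calibrated hazards reproduce target fate fractions exactly", {
  for (tgt in list(c(0.7, 0.1), c(0.2, 0.3), c(0.05, 0), c(0, 0.4))) {
    hz <- calibrate_hazards(tgt[1], tgt[2])
    got <- competing_fate_probs(hz[["escape"]], hz[["death"]])
    expect_equal(unname(got[c("escape", "death")]), tgt, tolerance = 1e-12)
  }
})

test_that("default cell configs carry the reported design", {
  cfgs <- default_cohort_configs(seed = 1)
  expect_length(cfgs, 8L)
  expect_equal(cfgs[["predator:non:extreme"]]$oviposition_params$a, 0.8970)
  expect_equal(cfgs[["prey:acc:mild"]]$oviposition_params$b, 2.8919)
  ns <- vapply(cfgs, `[[`, 0L, "n_females")
  expect_true(all(ns >= 39 & ns <= 54))
  expect_equal(sum(ns[grepl("^predator", names(ns))]), 188L)
  expect_equal(sum(ns[grepl("^prey", names(ns))]), 181L)
  # expected lost fraction in the predator non-acclimated extreme cell is
  # 41/47 (6 of 47 expected to remain alive on the leaf)
  cc <- cfgs[["predator:non:extreme"]]
  pr <- competing_fate_probs(cc$daily_escape_hazard, cc$daily_death_hazard)
  expect_equal(unname(pr[["escape"]] + pr[["death"]]), 41 / 47,
               tolerance = 1e-10)
  expect_equal(unname(pr[["survive"]]), 6 / 47, tolerance = 1e-10)
})

test_that("simulated fate tallies recover the input hazards", {
  he <- 0.08; hd <- 0.03
  cfg <- cohort_config("prey", n_females = 5000, seed = 13,
                       daily_escape_hazard = he, daily_death_hazard = hd)
  tl <- tally_fates(simulate_cohort(cfg)$females)
  truth <- competing_fate_probs(he, hd)
  se_esc <- sqrt(truth[["escape"]] * (1 - truth[["escape"]]) / 5000)
  expect_lt(abs(tl$pct_escaped / 100 - truth[["escape"]]), 2 * se_esc)
  se_die <- sqrt(truth[["death"]] * (1 - truth[["death"]]) / 5000)
  expect_lt(abs(tl$pct_died / 100 - truth[["death"]]), 2 * se_die)
})
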