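test_that("curve evaluation matches direct scalar arithmetic", {
  p <- pred_extreme_ovi()
  t0 <- 5.822215
  expect_equal(eval_curve(p, t0),
               0.8970 * t0^1.8765 * exp(-0.3223 * t0), tolerance = 1e-12)
  expect_equal(eval_curve(p, t0), 3.7456, tolerance = 1e-4)

  # reported prey mild female egg-volume curve at first assessment age
  pv <- rate_curve_params(0.9490, 0, 0.0747, -0.0044,
                          response_kind = "egg_volume")
  expect_equal(eval_curve(pv, 3.5),
               0.9490 * exp(0.0747 * 3.5 - 0.0044 * 3.5^2),
               tolerance = 1e-12)
  expect_equal(eval_curve(pv, 3.5), 1.1679, tolerance = 1e-4)

  # degenerate constant curve
  pc <- rate_curve_params(2.5, 0, 0, 0)
  expect_equal(eval_curve(pc, c(1, 5, 20)), rep(2.5, 3))

  expect_error(eval_curve(p, 0), "ages")
  expect_error(eval_curve(p, -1), "ages")
})

test_that("the curve is positive for t > 0 and vanishes at eclosion when b > 0", {
  p <- prey_mild_ovi()
  tt <- seq(0.01, 40, length.out = 500)
  expect_true(all(eval_curve(p, tt) > 0))
  expect_lt(eval_curve(p, 1e-8), 1e-12)
})

test_that("peak ages solve the stationarity condition", {
  expect_equal(peak_age(prey_mild_ovi()), 2.8919 / 0.3723,
               tolerance = 1e-12)  # 7.768 days
  expect_equal(peak_age(pred_extreme_ovi()), 1.8765 / 0.3223,
               tolerance = 1e-12)  # 5.822 days
  # monotone increasing curve has no interior peak
  expect_true(is.na(peak_age(rate_curve_params(1, 2, 0.1))))
  # numeric argmax agreement, including quadratic-exponent volume curves
  for (p in list(pred_extreme_ovi(), prey_mild_ovi(),
                 rate_curve_params(0.9490, 0, 0.0747, -0.0044,
                                   response_kind = "egg_volume"),
                 rate_curve_params(2, 1.5, -0.1, -0.02))) {
    pk <- peak_age(p)
    if (is.na(pk)) next
    num <- stats::optimize(function(t) eval_curve(p, t),
                           c(1e-6, 50), maximum = TRUE,
                           tol = 1e-10)$maximum
    expect_equal(pk, num, tolerance = 1e-6)
  }
})

test_that("parameter container enforces its invariants", {
  expect_error(rate_curve_params(-1, 1, -0.3), "'a'")
  expect_error(rate_curve_params(1, 1, -0.3, r_squared = 1.2), "r_squared")
  expect_error(rate_curve_params(1, 0, -0.3, se = c(b = 0.1)), "dropped")
  p <- rate_curve_params(1, 2, -0.3)
  expect_equal(p$included_terms, c("b", "c"))
})

test_that("NLS refits noiseless data to machine precision", {
  truth <- prey_mild_ovi()
  d <- expand.grid(age = seq(3.5, 12.5, by = 1), rep = 1:3)
  d$eggs <- eval_curve(truth, d$age)
  fit <- fit_rate_curve(eggs ~ age, d, include = c("b", "c"))
  expect_true(fit$converged)
  est <- coef(fit)[c("a", "b", "c")]
  tru <- coef(truth)[c("a", "b", "c")]
  expect_lt(max(abs(est - tru) / abs(tru)), 1e-6)
  expect_equal(fit$params$r_squared, 1, tolerance = 1e-12)
})

test_that("single-age data are rejected as rank deficient", {
  d <- data.frame(age = rep(5, 30), eggs = rpois(30, 3))
  expect_error(fit_rate_curve(eggs ~ age, d, include = c("b", "c")),
               "rank deficiency")
})

test_that("NLS recovers generating parameters from a noisy cohort", {
  truth <- pred_extreme_ovi()
  cfg <- cohort_config("predator", regime = "extreme", n_females = 200,
                       oviposition_params = truth, seed = 501)
  f <- simulate_cohort(cfg)$females
  fit <- fit_rate_curve(eggs ~ age, f[f$status == "alive", ],
                        include = c("b", "c"))
  est <- coef(fit)[c("a", "b", "c")]
  se <- fit$params$se[c("a", "b", "c")]
  expect_true(all(abs(est - coef(truth)[c("a", "b", "c")]) <= 3 * se))
  expect_true(all(se > 0))
})

test_that("stratified fitting returns one curve per stratum", {
  d <- rbind(
    data.frame(age = rep(seq(3.5, 12.5), 2), regime = "mild",
               eggs = eval_curve(prey_mild_ovi(), rep(seq(3.5, 12.5), 2))),
    data.frame(age = rep(seq(3.5, 12.5), 2), regime = "extreme",
               eggs = eval_curve(rate_curve_params(1.46, 2.3705, -0.3230),
                                 rep(seq(3.5, 12.5), 2))))
  fits <- fit_rate_curve(eggs ~ age, d, include = c("b", "c"),
                         strata = "regime")
  expect_named(fits, c("extreme", "mild"))
  expect_equal(coef(fits[["mild"]])[["b"]], 2.8919, tolerance = 1e-5)
  expect_equal(coef(fits[["extreme"]])[["b"]], 2.3705, tolerance = 1e-5)
})

test_that("R-squared is invariant to row order", {
  cfg <- cohort_config("prey", n_females = 60, seed = 77,
                       oviposition_params = prey_mild_ovi())
  f <- simulate_cohort(cfg)$females
  f <- f[f$status == "alive", ]
  r1 <- fit_rate_curve(eggs ~ age, f, include = c("b", "c"))$params$r_squared
  r2 <- fit_rate_curve(eggs ~ age, f[rev(seq_len(nrow(f))), ],
                       include = c("b", "c"))$params$r_squared
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("the log-linear fit is exact on noiseless log-scale data", {
  beta <- c(b0 = log(0.95), c = 0.0747, d = -0.0044)
  d <- expand.grid(age = seq(3.5, 12.5), female_id = sprintf("F%02d", 1:20))
  d$vol <- exp(beta[["b0"]] + beta[["c"]] * d$age + beta[["d"]] * d$age^2)
  fit <- suppressWarnings(      # zero residuals: sandwich warns on bread
    fit_rate_gee(vol ~ age, d, include = c("c", "d"),
                 response_kind = "egg_volume", eliminate = FALSE))
  expect_equal(unname(coef(fit)), unname(c(beta[1], beta[2], beta[3])),
               tolerance = 1e-10)
  p <- as_rate_curve_params(fit)
  expect_equal(p$a, 0.95, tolerance = 1e-10)
  # response-scale predictions agree with the natural-scale curve
  expect_equal(predict(fit, data.frame(t = c(4, 8, 12))),
               eval_curve(p, c(4, 8, 12)), tolerance = 1e-10)
})

test_that("a known regime effect is recovered within two robust SEs", {
  set.seed(321)
  n_per <- 150
  delta <- 0.30   # log-scale shift between regimes
  mk <- function(regime, shift, ids) {
    d <- expand.grid(age = seq(3.5, 12.5), female_id = ids)
    u <- stats::rnorm(length(ids), 0, 0.15)           # female frailty
    d$vol <- exp(log(1.0) + 0.05 * d$age - 0.003 * d$age^2 + shift +
                   u[match(d$female_id, ids)] +
                   stats::rnorm(nrow(d), 0, 0.1))
    d$regime <- regime
    d
  }
  d <- rbind(mk("extreme", delta / 2, sprintf("E%03d", 1:n_per)),
             mk("mild", -delta / 2, sprintf("M%03d", 1:n_per)))
  fit <- fit_rate_gee(vol ~ age, d, factors = "regime",
                      include = c("c", "d"),
                      response_kind = "egg_volume", eliminate = FALSE)
  # sum-to-zero coding: the regime coefficient is half the group contrast
  i <- grep("regime", names(coef(fit)))
  est <- 2 * abs(coef(fit)[i])
  se <- 2 * sqrt(diag(fit$vcov))[i]
  expect_lt(abs(est - delta), 2 * se)
})

test_that("backward elimination drops a null factor about 95% of the time", {
  set.seed(11)
  n_sim <- 200
  dropped <- logical(n_sim)
  ids <- sprintf("F%03d", 1:40)
  grid <- expand.grid(age = seq(3.5, 12.5), female_id = ids)
  null_factor <- rep(c("x", "y"), each = 20)
  for (s in seq_len(n_sim)) {
    d <- grid
    d$grp <- null_factor[match(d$female_id, ids)]
    d$vol <- exp(0.1 + 0.05 * d$age + stats::rnorm(nrow(d), 0, 0.2))
    fit <- fit_rate_gee(vol ~ age, d, factors = "grp", include = "c",
                        response_kind = "egg_volume")
    dropped[s] <- "grp" %in% fit$dropped_terms
  }
  expect_gte(mean(dropped), 0.90)
  expect_lte(mean(dropped), 0.99)
})

test_that("degenerate responses are rejected with clear messages", {
  d <- data.frame(age = rep(seq(3.5, 12.5), 2), eggs = 0,
                  female_id = "F1")
  expect_error(fit_rate_gee(eggs ~ age, d), "degenerate")
  d2 <- data.frame(age = 5, vol = c(1, 2), female_id = c("a", "b"))
  expect_error(fit_rate_gee(vol ~ age, d2, include = c("c", "d"),
                            response_kind = "egg_volume",
                            eliminate = FALSE), "singular|aliased")
})
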