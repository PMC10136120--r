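# balanced 2x2 layout builder
mk_twoway <- function(mu, a_eff, b_eff, ab_eff = 0, n_cell = 10,
                      noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                   rep = seq_len(n_cell))
  sa <- ifelse(g$A == "a1", 1, -1)
  sb <- ifelse(g$B == "b1", 1, -1)
  g$y <- mu + a_eff * sa + b_eff * sb + ab_eff * sa * sb +
    stats::rnorm(nrow(g), 0, noise_sd)
  g
}

test_that("a noiseless balanced layout is recovered exactly", {
  d <- mk_twoway(10, 2, -1, 0.5)
  fit <- fit_factorial(y ~ A * B, d, family = "normal", eliminate = FALSE)
  cf <- coef(fit)
  expect_equal(unname(cf[["(Intercept)"]]), 10, tolerance = 1e-10)
  expect_equal(unname(cf[["A1"]]), 2, tolerance = 1e-10)
  expect_equal(unname(cf[["B1"]]), -1, tolerance = 1e-10)
  expect_equal(unname(cf[["A1:B1"]]), 0.5, tolerance = 1e-10)
})

test_that("normal-family Type-III F matches a hand-computed ANOVA", {
  d <- mk_twoway(5, 1.2, 0.4, 0, n_cell = 8, noise_sd = 1, seed = 42)
  fit <- fit_factorial(y ~ A * B, d, family = "normal", eliminate = FALSE)
  # textbook balanced two-way sums of squares
  n_cell <- 8
  gm <- mean(d$y)
  ss_a <- sum(tapply(d$y, d$A, function(v) length(v) * (mean(v) - gm)^2))
  ss_b <- sum(tapply(d$y, d$B, function(v) length(v) * (mean(v) - gm)^2))
  cell_means <- tapply(d$y, interaction(d$A, d$B), mean)
  ss_cells <- n_cell * sum((cell_means - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_err <- sum((d$y - ave(d$y, interaction(d$A, d$B)))^2)
  df_err <- nrow(d) - 4
  tab <- fit$terms_table
  expect_equal(tab$statistic[tab$term == "A"],
               (ss_a / 1) / (ss_err / df_err), tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "B"],
               (ss_b / 1) / (ss_err / df_err), tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "A:B"],
               (ss_ab / 1) / (ss_err / df_err), tolerance = 1e-8)
  # normal-family dispersion is the residual mean square
  expect_equal(fit$dispersion, ss_err / df_err, tolerance = 1e-10)
})

test_that("quasi-Poisson coefficients equal plain Poisson IRLS exactly", {
  set.seed(5)
  d <- mk_twoway(0, 0.3, 0.2, n_cell = 25)
  d$y <- stats::rpois(nrow(d), exp(d$y))
  fit <- fit_factorial(y ~ A * B, d, family = "quasi_poisson",
                       eliminate = FALSE)
  ref <- stats::glm(y ~ A * B, data = fit$model$model,
                    family = stats::poisson(),
                    contrasts = list(A = "contr.sum", B = "contr.sum"))
  expect_equal(unname(coef(fit)), unname(stats::coef(ref)),
               tolerance = 1e-12)
})

test_that("dispersion scaling restores the nominal type-I error", {
  set.seed(88)
  n_sim <- 300
  rej_scaled <- rej_plain <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    d <- data.frame(grp = rep(c("a", "b"), each = 40))
    mu <- 5
    d$y <- stats::rnbinom(80, size = mu, mu = mu)   # dispersion ~2
    fit <- fit_factorial(y ~ grp, d, family = "quasi_poisson",
                         eliminate = FALSE)
    rej_scaled[s] <- fit$terms_table$p[1] < 0.05
    plain <- stats::glm(y ~ grp, data = d, family = stats::poisson())
    rej_plain[s] <- summary(plain)$coefficients[2, 4] < 0.05
  }
  expect_gte(mean(rej_scaled), 0.02)
  expect_lte(mean(rej_scaled), 0.09)
  expect_gt(mean(rej_plain), 0.09)   # unscaled test is anticonservative
})

test_that("post-hoc contrasts behave on identical and shifted groups", {
  # four groups with exactly identical sample means (same values
  # replicated): every pairwise contrast is 0 and every adjusted p is 1
  set.seed(3)
  block <- stats::rnorm(30, 10, 1)
  d0 <- data.frame(risk = rep(c("control", "low", "high", "both"),
                              each = 30),
                   y = rep(block, 4))
  f0 <- fit_factorial(y ~ risk, d0, family = "normal", eliminate = FALSE)
  ct0 <- posthoc_contrasts(f0, "risk", "tukey")
  expect_equal(nrow(ct0), 6L)
  expect_equal(ct0$estimate, rep(0, 6), tolerance = 1e-10)
  expect_true(all(ct0$p_adj > 1 - 1e-8))
  expect_true(all(ct0$p_adj >= ct0$p_raw))

  # three-level factor gives three pairwise rows
  d3 <- data.frame(g = rep(c("x", "y", "z"), each = 15),
                   y = stats::rnorm(45))
  f3 <- fit_factorial(y ~ g, d3, family = "normal", eliminate = FALSE)
  expect_equal(nrow(posthoc_contrasts(f3, "g", "tukey")), 3L)

  # a known 0.12 log-scale shift of the high-risk group is detected
  set.seed(14)
  d1 <- data.frame(risk = rep(c("control", "high"), each = 40))
  d1$y <- stats::rpois(80, exp(log(60) +
                                 ifelse(d1$risk == "high", -0.12, 0)))
  f1 <- fit_factorial(y ~ risk, d1, family = "quasi_poisson",
                      eliminate = FALSE)
  ct1 <- posthoc_contrasts(f1, "risk", "dunnett_style")
  expect_equal(nrow(ct1), 1L)
  expect_gt(ct1$estimate, 0)        # control minus high, log scale
  # oracle: two-sample z on log cell means
  z_ref <- local({
    m1 <- mean(d1$y[d1$risk == "control"]); m2 <- mean(d1$y[d1$risk == "high"])
    v <- function(x) stats::var(x) / length(x) / mean(x)^2
    (log(m1) - log(m2)) /
      sqrt(v(d1$y[d1$risk == "control"]) + v(d1$y[d1$risk == "high"]))
  })
  expect_equal(unname(ct1$statistic), z_ref, tolerance = 0.25)
  expect_lt(ct1$p_adj, 0.05)
})

test_that("Holm adjustment is monotone in the raw p-values", {
  set.seed(21)
  d <- data.frame(g = rep(letters[1:4], each = 12),
                  y = stats::rnorm(48) + rep(c(0, 0.2, 0.5, 1), each = 12))
  f <- fit_factorial(y ~ g, d, family = "normal", eliminate = FALSE)
  ct <- posthoc_contrasts(f, "g", "holm")
  o <- order(ct$p_raw)
  expect_true(all(diff(ct$p_adj[o]) >= -1e-12))
})

test_that("sex-ratio analysis recovers a uniform female proportion", {
  set.seed(777)
  n_mothers <- 150
  eggs <- do.call(rbind, lapply(seq_len(n_mothers), function(i) {
    m <- 1 + stats::rpois(1, 9)
    data.frame(female_id = sprintf("F%03d", i), day = 1,
               regime = sample(c("mild", "extreme"), 1),
               acclimated = sample(c(TRUE, FALSE), 1),
               sex = ifelse(stats::rbinom(m, 1, 0.651) == 1,
                            "female", "male"))
  }))
  sr <- sex_ratio_analysis(eggs)
  expect_equal(sr$pooled$prop_female, 0.651, tolerance = 0.03)
  # with no real factor effects the model collapses to the intercept,
  # which estimates logit(0.651) = 0.623
  expect_length(sr$fit$trace, 3L)
  expect_equal(unname(coef(sr$fit)[["(Intercept)"]]),
               stats::qlogis(0.651), tolerance = 0.15)
})

test_that("an all-female egg table is flagged as a boundary", {
  eggs <- data.frame(female_id = rep(c("F1", "F2"), each = 4), day = 1,
                     regime = "mild", acclimated = FALSE, sex = "female")
  sr <- sex_ratio_analysis(eggs)
  expect_true(sr$boundary)
  expect_null(sr$fit)
  expect_equal(sr$pooled$prop_female, 1)
})

test_that("survivor restriction drops non-surviving mothers", {
  eggs <- data.frame(female_id = rep(c("F001", "F002"), each = 6), day = 1,
                     regime = "mild", acclimated = FALSE,
                     sex = rep(c("female", "male"), 6))
  females <- make_fate_table(c("survived", "died"),
                             fate_day = c(NA, 5L))
  sr <- sex_ratio_analysis(eggs, females = females, eliminate = FALSE)
  expect_equal(sr$n_mothers, 1L)
  expect_equal(sr$pooled$n_sexed, 6)
})
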