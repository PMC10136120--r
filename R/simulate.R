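#' Configuration of one synthetic experimental cell
#'
#' One cell of the factorial design (species x acclimation x heat-wave
#' regime) is simulated as a cohort of individually caged females observed
#' once per day for `n_days` days, ages running from `age_at_start` (3.5
#' days: females eclose over one day, so the first assessment age is the
#' cohort average) to `age_at_start + n_days - 1` (12.5 days).
#'
#' Each day a female is at risk of two competing fates, drawn in a fixed
#' order: escape from the leaf arena (probability `daily_escape_hazard`),
#' otherwise death (probability `daily_death_hazard`).  While alive she
#' lays a negative-binomially distributed number of eggs with age-dependent
#' mean given by her cohort's oviposition curve times a female-level
#' lognormal frailty (inducing the within-female day-to-day correlation
#' that the repeated-measures analyses assume), and consumes prey
#' (predator: prey eggs/day from a consumption curve; prey: leaf damage in
#' mm^2/day, normal truncated at zero).  Up to `eggs_sexed_per_day` of her
#' eggs that day are measured (volume with lognormal noise of coefficient
#' of variation `eggsize_cv` around the per-sex egg-volume curve) and
#' sexed (`sex ~ Bernoulli(p_female)`).
#'
#' @param species `"predator"` (ellipsoid eggs, egg-consumption rates) or
#'   `"prey"` (spherical eggs, leaf-damage rates).
#' @param acclimated logical: did juvenile development occur under the same
#'   heat-wave regime later experienced as an adult?
#' @param regime `"mild"` or `"extreme"` adult heat-wave regime.
#' @param n_females cohort size (>= 1).
#' @param n_days observation days (default 10).
#' @param age_at_start mean age at first assessment (default 3.5 days).
#' @param daily_escape_hazard,daily_death_hazard per-day probabilities in
#'   `[0, 1]`.
#' @param oviposition_params [rate_curve_params()] for eggs/female/day.
#' @param count_dispersion variance inflation of daily counts
#'   (`Var = dispersion * mean`); 1 means Poisson.
#' @param frailty_sd SD of the female-level lognormal frailty on the log
#'   scale (0 switches frailty off).
#' @param eggsize_params list with elements `female` and `male`, each a
#'   [rate_curve_params()] for egg volume in 1e6 um^3 (power term `b`
#'   fixed at 0).
#' @param eggsize_cv lognormal coefficient of variation of individual egg
#'   volumes around the curve.
#' @param p_female probability that an egg is female.
#' @param consumption_params [rate_curve_params()] (predator) for prey
#'   eggs eaten/day.
#' @param damage_mean,damage_sd prey leaf damage rate, mm^2/day.
#' @param eggs_sexed_per_day daily sexing subsample cap (default 2).
#' @param egg_aspect_ratio semi-major/semi-minor axis ratio used to
#'   reconstruct predator egg axes from a volume (default 1.3).
#' @param seed integer seed; required, every cohort draw is a pure function
#'   of (config, seed).
#' @return An object of class `cohort_config`.
#' @seealso [simulate_cohort()], [default_cohort_configs()],
#'   [calibrate_hazards()]
#' @export
cohort_config <- function(species = c("predator", "prey"),
                          acclimated = FALSE,
                          regime = c("mild", "extreme"),
                          n_females = 50L,
                          n_days = 10L,
                          age_at_start = 3.5,
                          daily_escape_hazard = 0,
                          daily_death_hazard = 0,
                          oviposition_params = NULL,
                          count_dispersion = 2,
                          frailty_sd = 0.2,
                          eggsize_params = NULL,
                          eggsize_cv = 0.05,
                          p_female = 0.6,
                          consumption_params = NULL,
                          damage_mean = NULL, damage_sd = NULL,
                          eggs_sexed_per_day = 2L,
                          egg_aspect_ratio = 1.3,
                          seed) {
  species <- match.arg(species)
  regime <- match.arg(regime)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an integer 'seed' is required", call. = FALSE)
  if (daily_escape_hazard < 0 || daily_escape_hazard > 1 ||
      daily_death_hazard < 0 || daily_death_hazard > 1)
    stop("hazards must lie in [0, 1]", call. = FALSE)
  if (p_female < 0 || p_female > 1)
    stop("p_female must lie in [0, 1]", call. = FALSE)
  if (n_females < 1) stop("n_females must be >= 1", call. = FALSE)
  if (count_dispersion < 1)
    stop("count_dispersion must be >= 1", call. = FALSE)
  if (!is.null(oviposition_params))
    stopifnot(inherits(oviposition_params, "rate_curve_params"))
  if (!is.null(eggsize_params)) {
    stopifnot(is.list(eggsize_params),
              all(c("female", "male") %in% names(eggsize_params)))
    for (s in c("female", "male")) {
      stopifnot(inherits(eggsize_params[[s]], "rate_curve_params"))
      if (eggsize_params[[s]]$b != 0)
        stop("egg-size curves carry no power term (b must be 0)",
             call. = FALSE)
    }
  }
  if (species == "predator" && !is.null(damage_mean))
    stop("damage rates apply to prey only", call. = FALSE)
  structure(list(species = species, acclimated = isTRUE(acclimated),
                 regime = regime, n_females = as.integer(n_females),
                 n_days = as.integer(n_days), age_at_start = age_at_start,
                 daily_escape_hazard = daily_escape_hazard,
                 daily_death_hazard = daily_death_hazard,
                 oviposition_params = oviposition_params,
                 count_dispersion = count_dispersion,
                 frailty_sd = frailty_sd,
                 eggsize_params = eggsize_params,
                 eggsize_cv = eggsize_cv,
                 p_female = p_female,
                 consumption_params = consumption_params,
                 damage_mean = damage_mean, damage_sd = damage_sd,
                 eggs_sexed_per_day = as.integer(eggs_sexed_per_day),
                 egg_aspect_ratio = egg_aspect_ratio,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "Cohort config: %s, %s, %s | n = %d females x %d days (ages %.1f-%.1f)\n",
    x$species, if (x$acclimated) "acclimated" else "non-acclimated",
    x$regime, x$n_females, x$n_days, x$age_at_start,
    x$age_at_start + x$n_days - 1))
  cat(sprintf("  daily hazards: escape %.4f, death %.4f | seed %d\n",
              x$daily_escape_hazard, x$daily_death_hazard, x$seed))
  invisible(x)
}

#' Daily hazards matching 10-day fate fractions
#'
#' Inverts the competing-fate recursion: with a constant daily escape
#' hazard `h_e` (drawn first) and death hazard `h_d` (drawn if no escape),
#' the per-day continuation probability is `s = (1-h_e)(1-h_d)` and the
#' `n`-day fate fractions are
#' `P(escape) = h_e (1-s^n)/(1-s)`, `P(death) = (1-h_e) h_d (1-s^n)/(1-s)`,
#' `P(survive) = s^n`.  Given target escape and death fractions the system
#' has the closed-form solution implemented here, which is exact (the
#' returned hazards reproduce the targets under the forward recursion).
#'
#' @param p_escape,p_death target fractions over the observation window
#'   (`p_escape + p_death < 1`).
#' @param n_days window length (default 10).
#' @return Named numeric vector `c(escape = h_e, death = h_d)`.
#' @export
calibrate_hazards <- function(p_escape, p_death, n_days = 10L) {
  stopifnot(p_escape >= 0, p_death >= 0, p_escape + p_death < 1)
  if (p_escape == 0 && p_death == 0)
    return(c(escape = 0, death = 0))
  ps <- 1 - p_escape - p_death
  s <- ps^(1 / n_days)
  K <- (1 - ps) / (1 - s)      # sum_{j=0}^{n-1} s^j
  h_e <- p_escape / K
  h_d <- p_death / ((1 - h_e) * K)
  c(escape = h_e, death = h_d)
}

#' Simulate one cohort of females and their measured eggs
#'
#' Individual-based forward simulation of a [cohort_config()]: see that
#' help page for the generative model.  With a fixed seed the output is
#' bit-reproducible.
#'
#' @param config a [cohort_config()].
#' @return A list of class `cohort_tables` with two data frames:
#' \describe{
#'   \item{`females`}{one row per female-day up to and including the fate
#'     day: `female_id`, `species`, `acclimated`, `regime`, `day` (1-based),
#'     `age`, `status` (`alive`/`escaped`/`died`), `eggs`, `consumption`,
#'     `fate` (`survived`/`escaped`/`died`), `fate_day` (`NA` for
#'     survivors).  Event-day rows carry `NA` eggs and consumption.}
#'   \item{`eggs`}{one row per measured (sexing-subsample) egg:
#'     `female_id`, `day`, `maternal_age`, `species`, `acclimated`,
#'     `regime`, `shape`, `a_um`, `b_um`, `r_um`, `volume_um3`, `sex`.}
#' }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_females
  nd <- config$n_days
  ages <- config$age_at_start + seq_len(nd) - 1

  frailty <- if (config$frailty_sd > 0)
    stats::rlnorm(n, -config$frailty_sd^2 / 2, config$frailty_sd)
  else rep(1, n)

  he <- config$daily_escape_hazard
  hd <- config$daily_death_hazard
  p_event <- he + (1 - he) * hd
  if (p_event > 0) {
    event_day <- stats::rgeom(n, p_event) + 1L     # day the fate strikes
    is_escape <- stats::rbinom(n, 1L, he / p_event) == 1L
  } else {
    event_day <- rep(Inf, n)
    is_escape <- rep(FALSE, n)
  }
  fate <- ifelse(event_day > nd, "survived",
                 ifelse(is_escape, "escaped", "died"))
  fate_day <- ifelse(event_day > nd, NA_integer_, event_day)
  last_day <- pmin(event_day, nd)                  # last emitted row
  alive_days <- ifelse(is.finite(event_day) & event_day <= nd,
                       event_day - 1L, nd)

  # female-day grid up to the fate day
  fid <- rep(seq_len(n), last_day)
  day <- unlist(lapply(last_day, seq_len), use.names = FALSE)
  alive <- day <= rep(alive_days, last_day)
  age <- ages[day]
  status <- rep(fate, last_day)
  status[alive] <- "alive"

  m <- length(fid)
  eggs <- rep(NA_real_, m)
  cons <- rep(NA_real_, m)
  ia <- which(alive)

  draw_counts <- function(mu) {
    out <- numeric(length(mu))
    pos <- mu > 0
    if (any(pos)) {
      if (config$count_dispersion == 1) {
        out[pos] <- stats::rpois(sum(pos), mu[pos])
      } else {
        size <- mu[pos] / (config$count_dispersion - 1)
        out[pos] <- stats::rnbinom(sum(pos), size = size, mu = mu[pos])
      }
    }
    out
  }

  if (!is.null(config$oviposition_params)) {
    mu <- frailty[fid[ia]] * eval_curve(config$oviposition_params, age[ia])
    eggs[ia] <- draw_counts(mu)
  } else {
    eggs[ia] <- 0
  }

  if (config$species == "predator" && !is.null(config$consumption_params)) {
    mu <- frailty[fid[ia]] * eval_curve(config$consumption_params, age[ia])
    cons[ia] <- draw_counts(mu)
  } else if (config$species == "prey" && !is.null(config$damage_mean)) {
    cons[ia] <- pmax(0, stats::rnorm(length(ia), config$damage_mean,
                                     if (is.null(config$damage_sd)) 0
                                     else config$damage_sd))
  } else {
    cons[ia] <- 0
  }

  id_str <- sprintf("%s_%s_%s_F%03d", substr(config$species, 1, 4),
                    config$regime, if (config$acclimated) "acc" else "non",
                    fid)
  females <- data.frame(
    female_id = id_str, species = config$species,
    acclimated = config$acclimated, regime = config$regime,
    day = day, age = age, status = status,
    eggs = eggs, consumption = cons,
    fate = rep(fate, last_day),
    fate_day = rep(fate_day, last_day),
    stringsAsFactors = FALSE)

  # sexing subsample: up to k eggs per ovipositing female-day are measured
  egg_rows <- NULL
  if (!is.null(config$eggsize_params)) {
    k <- pmin(config$eggs_sexed_per_day, eggs[ia])
    sel <- which(k > 0)
    if (length(sel)) {
      reps <- k[sel]
      e_fid <- fid[ia][sel]
      e_day <- rep(day[ia][sel], reps)
      e_age <- rep(age[ia][sel], reps)
      e_id <- rep(id_str[ia][sel], reps)
      ne <- length(e_day)
      sex <- ifelse(stats::rbinom(ne, 1L, config$p_female) == 1L,
                    "female", "male")
      mu <- numeric(ne)
      for (s in c("female", "male")) {
        ix <- sex == s
        if (any(ix))
          mu[ix] <- eval_curve(config$eggsize_params[[s]], e_age[ix])
      }
      sdlog <- sqrt(log(1 + config$eggsize_cv^2))
      vol_scaled <- stats::rlnorm(ne, log(mu) - sdlog^2 / 2, sdlog)
      volume_um3 <- vol_scaled * 1e6
      if (config$species == "predator") {
        ar <- config$egg_aspect_ratio
        b_um <- (volume_um3 / (4 / 3 * pi * ar))^(1 / 3)
        egg_rows <- data.frame(
          female_id = e_id, day = e_day, maternal_age = e_age,
          species = config$species, acclimated = config$acclimated,
          regime = config$regime, shape = "ellipsoid",
          a_um = ar * b_um, b_um = b_um, r_um = NA_real_,
          volume_um3 = volume_um3, sex = sex, stringsAsFactors = FALSE)
      } else {
        r_um <- (volume_um3 / (4 / 3 * pi))^(1 / 3)
        egg_rows <- data.frame(
          female_id = e_id, day = e_day, maternal_age = e_age,
          species = config$species, acclimated = config$acclimated,
          regime = config$regime, shape = "sphere",
          a_um = NA_real_, b_um = NA_real_, r_um = r_um,
          volume_um3 = volume_um3, sex = sex, stringsAsFactors = FALSE)
      }
    }
  }
  if (is.null(egg_rows))
    egg_rows <- data.frame(female_id = character(), day = integer(),
                           maternal_age = numeric(), species = character(),
                           acclimated = logical(), regime = character(),
                           shape = character(), a_um = numeric(),
                           b_um = numeric(), r_um = numeric(),
                           volume_um3 = numeric(), sex = character(),
                           stringsAsFactors = FALSE)

  structure(list(females = females, eggs = egg_rows, config = config),
            class = "cohort_tables")
}

#' @export
print.cohort_tables <- function(x, ...) {
  print(x$config)
  cat(sprintf("  %d female-day rows, %d measured eggs\n",
              nrow(x$females), nrow(x$eggs)))
  invisible(x)
}

# reported fate counts per experimental cell (escaped, died, survived of n);
# cohort sizes and fate splits reconstruct the study's printed tallies
.cell_fates <- list(
  predator = list(
    "non:mild"    = c(n = 42, esc = 23, died = 2),
    "non:extreme" = c(n = 47, esc = 36, died = 5),
    "acc:mild"    = c(n = 54, esc = 43, died = 3),
    "acc:extreme" = c(n = 45, esc = 32, died = 4)),
  prey = list(
    "non:mild"    = c(n = 48, esc = 10, died = 9),
    "non:extreme" = c(n = 39, esc = 1,  died = 15),
    "acc:mild"    = c(n = 52, esc = 8,  died = 11),
    "acc:extreme" = c(n = 42, esc = 1,  died = 18)))

# reported rate-curve estimates per species x regime
.cell_params <- function(species, regime) {
  if (species == "predator") {
    ovi <- if (regime == "extreme")
      rate_curve_params(0.8970, 1.8765, -0.3223)
    else rate_curve_params(0.1683, 2.9610, -0.4390)
    cons <- if (regime == "extreme")
      rate_curve_params(38.0805, 0, -0.0505, response_kind = "predation")
    else rate_curve_params(25.9780, 0, -0.0387, response_kind = "predation")
    eggsize <- if (regime == "extreme") list(
      female = rate_curve_params(4.0776, 0, -0.0116, 0.00095,
                                 response_kind = "egg_volume"),
      male = rate_curve_params(3.7318, 0, -0.0334, 0.00033,
                               response_kind = "egg_volume"))
    else list(
      female = rate_curve_params(3.6088, 0, 0.0436, -0.00028,
                                 response_kind = "egg_volume"),
      male = rate_curve_params(3.5284, 0, 0.0220, -0.0010,
                               response_kind = "egg_volume"))
    p_female <- if (regime == "extreme") 0.618 else 0.692
    list(ovi = ovi, cons = cons, eggsize = eggsize, p_female = p_female,
         damage_mean = NULL, damage_sd = NULL)
  } else {
    ovi <- if (regime == "extreme")
      rate_curve_params(1.4600, 2.3705, -0.3230)
    else rate_curve_params(0.5416, 2.8919, -0.3723)
    eggsize <- if (regime == "extreme") list(
      female = rate_curve_params(1.0148, 0, 0.0425, -0.0020,
                                 response_kind = "egg_volume"),
      male = rate_curve_params(0.9194, 0, 0.0633, -0.0035,
                               response_kind = "egg_volume"))
    else list(
      female = rate_curve_params(0.9490, 0, 0.0747, -0.0044,
                                 response_kind = "egg_volume"),
      male = rate_curve_params(0.9722, 0, 0.0559, -0.0028,
                               response_kind = "egg_volume"))
    p_female <- if (regime == "extreme") 0.506 else 0.631
    list(ovi = ovi, cons = NULL, eggsize = eggsize, p_female = p_female,
         damage_mean = if (regime == "extreme") 14.79 else 11.70,
         damage_sd = 4.0)
  }
}

#' Default configurations for the eight experimental cells
#'
#' Builds one [cohort_config()] per species x acclimation x regime cell,
#' with the reported curve estimates as generating parameters, the reported
#' cohort sizes (42-54 females per cell), per-level offspring sex ratios,
#' and daily hazards calibrated (via [calibrate_hazards()]) so the expected
#' 10-day escape/death/survival fractions equal the reported per-cell fate
#' tallies.  Oviposition, consumption and egg-size curves depend on the
#' adult regime only (acclimation did not alter them detectably in the
#' source experiment).
#'
#' @param seed base integer seed; cell `i` receives `seed + i`.
#' @return Named list of 8 `cohort_config` objects, names like
#'   `"predator:acc:extreme"`.
#' @export
default_cohort_configs <- function(seed = 1L) {
  out <- list()
  i <- 0L
  for (species in c("predator", "prey")) {
    for (acc in c("non", "acc")) {
      for (regime in c("mild", "extreme")) {
        i <- i + 1L
        cell <- .cell_fates[[species]][[paste(acc, regime, sep = ":")]]
        hz <- calibrate_hazards(cell[["esc"]] / cell[["n"]],
                                cell[["died"]] / cell[["n"]])
        pp <- .cell_params(species, regime)
        out[[paste(species, acc, regime, sep = ":")]] <- cohort_config(
          species = species, acclimated = acc == "acc", regime = regime,
          n_females = cell[["n"]],
          daily_escape_hazard = hz[["escape"]],
          daily_death_hazard = hz[["death"]],
          oviposition_params = pp$ovi,
          eggsize_params = pp$eggsize,
          p_female = pp$p_female,
          consumption_params = pp$cons,
          damage_mean = pp$damage_mean, damage_sd = pp$damage_sd,
          seed = seed + i)
      }
    }
  }
  out
}
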