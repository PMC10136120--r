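#' Pipeline run configuration
#'
#' Bundles everything a full analysis run needs: the stages to execute,
#' the seed (mandatory whenever simulation is among the stages), the
#' output directory, and optional paths to existing input tables (to
#' analyse real or previously simulated data instead of simulating).
#'
#' @param seed integer seed driving every random draw of the run.
#' @param out_dir output directory (created if missing).
#' @param stages character subset of
#'   `c("simulate","fates","curves","ratios","glm","report")`, in
#'   execution order.  Analysis stages require either the `simulate`
#'   stage or `females_csv`/`eggs_csv` inputs.
#' @param females_csv,eggs_csv optional input CSV paths (layout as written
#'   by the simulate stage).
#' @param summary_csv optional group-summary CSV (columns `group`,
#'   `species`, `censoring`, `regime`, `mean`, `se`, `n`) for the ratios
#'   stage; when given, ratios are computed from it (fixture mode) instead
#'   of from the female tables.
#' @param n_females optional override of the per-cell cohort sizes.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed, out_dir = "heatfec-out",
                       stages = c("simulate", "fates", "curves", "ratios",
                                  "glm", "report"),
                       females_csv = NULL, eggs_csv = NULL,
                       summary_csv = NULL, n_females = NULL) {
  valid <- c("simulate", "fates", "curves", "ratios", "glm", "report")
  if (!length(stages)) stop("empty stage list", call. = FALSE)
  bad <- setdiff(stages, valid)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stages <- valid[valid %in% stages]   # enforce dependency order
  simulating <- "simulate" %in% stages
  if (simulating && (missing(seed) || is.null(seed)))
    stop("a seed is mandatory when simulating", call. = FALSE)
  if (!simulating && is.null(females_csv) &&
      any(stages %in% c("fates", "curves", "glm")))
    stop("analysis stages need either the simulate stage or females_csv",
         call. = FALSE)
  structure(list(seed = if (missing(seed)) NA_integer_ else as.integer(seed),
                 out_dir = out_dir, stages = stages,
                 females_csv = females_csv, eggs_csv = eggs_csv,
                 summary_csv = summary_csv, n_females = n_females),
            class = "run_config")
}

#' Read a run configuration from a YAML key-value file
#'
#' Recognized keys mirror the arguments of [run_config()].
#'
#' @param path YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y),
                                  names(formals(run_config)))])
}

.req_cols <- list(
  females = c("female_id", "species", "acclimated", "regime", "day", "age",
              "status", "eggs", "consumption", "fate", "fate_day"),
  eggs = c("female_id", "day", "maternal_age", "species", "shape", "a_um",
           "b_um", "r_um", "volume_um3", "sex"))

.read_table <- function(path, kind) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.req_cols[[kind]], names(df))
  if (length(miss))
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

# per-female daily oviposition summary used by the ratios stage
.daily_rate_summary <- function(females, censoring) {
  keep <- if (censoring == "censored")
    females[females$fate == "survived", , drop = FALSE]
  else females
  rows <- list()
  for (sp in unique(keep$species)) {
    for (rg in c("extreme", "mild")) {
      d <- keep[keep$species == sp & keep$regime == rg, , drop = FALSE]
      if (!nrow(d)) next
      # per-female daily rate: eggs laid per day present on the arena
      alive <- d[d$status == "alive", , drop = FALSE]
      per <- tapply(alive$eggs, alive$female_id,
                    function(e) sum(e, na.rm = TRUE) / length(e))
      per <- per[!is.na(per)]
      rows[[paste(sp, censoring, rg)]] <- data.frame(
        group = paste(sp, censoring, rg, sep = ":"), species = sp,
        censoring = censoring, regime = rg,
        mean = mean(per), se = stats::sd(per) / sqrt(length(per)),
        n = length(per), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.ratio_stage <- function(summary_df) {
  ratios <- list(); comps <- list()
  for (cm in unique(summary_df$censoring)) {
    per_sp <- list()
    for (sp in unique(summary_df$species)) {
      a <- summary_df[summary_df$species == sp &
                        summary_df$censoring == cm &
                        summary_df$regime == "extreme", ]
      b <- summary_df[summary_df$species == sp &
                        summary_df$censoring == cm &
                        summary_df$regime == "mild", ]
      if (!nrow(a) || !nrow(b)) next
      r <- ratio_of_means(a$mean, a$se, a$n, b$mean, b$se, b$n,
                          censoring = cm)
      per_sp[[sp]] <- r
      ratios[[paste(cm, sp)]] <- data.frame(
        mode = cm, species = sp, ratio = r$m, se = r$se,
        ci_low = r$ci[1], ci_high = r$ci[2],
        pct_change = percent_change(a$mean, b$mean),
        stringsAsFactors = FALSE)
    }
    if (length(per_sp) == 2) {
      cmp <- compare_ratios(per_sp[[1]], per_sp[[2]])
      comps[[cm]] <- data.frame(
        mode = cm,
        comparison = paste(names(per_sp), collapse = " vs "),
        difference = cmp$estimate[["difference"]],
        se = cmp$estimate[["se"]], t = cmp$statistic[["t"]],
        df = cmp$parameter[["df"]], p = cmp$p.value,
        stringsAsFactors = FALSE)
    }
  }
  list(ratios = do.call(rbind, ratios), comparisons = do.call(rbind, comps))
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in dependency order
#' (simulate -> fates -> curves -> ratios -> glm -> report), writing each
#' stage's flat CSV outputs into `config$out_dir` and a plain-text log
#' (`run_log.txt`) recording the seed, stage order and elimination traces.
#' Outputs are a pure function of (inputs, config, seed): a repeated run
#' with the same seed is byte-identical.
#'
#' @param config a [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @return Invisibly, a list of in-memory stage results (`females`,
#'   `eggs`, `tallies`, `km`, `tests`, `curve_fits`, `gee`, `ratios`,
#'   `glm`, `report_path`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("stages: %s", paste(config$stages, collapse = " ")))
  res <- list()

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  females <- NULL; eggs <- NULL
  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      cfgs <- default_cohort_configs(seed = config$seed)
      if (!is.null(config$n_females))
        cfgs <- lapply(cfgs, function(cc) {
          cc$n_females <- as.integer(config$n_females); cc
        })
      sims <- lapply(cfgs, simulate_cohort)
      females <<- do.call(rbind, lapply(sims, `[[`, "females"))
      eggs <<- do.call(rbind, lapply(sims, `[[`, "eggs"))
      rownames(females) <<- NULL; rownames(eggs) <<- NULL
      utils::write.csv(females, out("females.csv"), row.names = FALSE)
      utils::write.csv(eggs, out("eggs.csv"), row.names = FALSE)
    })
  } else if (!is.null(config$females_csv)) {
    females <- .read_table(config$females_csv, "females")
    if (!is.null(config$eggs_csv))
      eggs <- .read_table(config$eggs_csv, "eggs")
  }
  res$females <- females; res$eggs <- eggs

  if ("fates" %in% config$stages) {
    run_stage("fates", function() {
      res$tallies <<- tally_fates(females,
                                  c("species", "acclimated", "regime"))
      pooled <- tally_fates(females, "species")
      utils::write.csv(rbind(pooled, res$tallies), out("fate_tallies.csv"),
                       row.names = FALSE)
      km_rows <- list(); test_rows <- list()
      for (sp in unique(females$species)) {
        d <- females[females$species == sp, ]
        for (ep in c("escape", "death")) {
          km <- km_curve(d, ep)
          km_rows[[paste(sp, ep)]] <- cbind(species = sp, endpoint = ep,
                                            as.data.frame(km))
          sd_ <- .km_data(d, ep, restrict = ep == "death")
          per <- d[!duplicated(d$female_id), ]
          grp <- per$regime[match(sd_$female_id, per$female_id)]
          bt <- breslow_test(sd_$time, sd_$event, grp)
          test_rows[[paste(sp, ep)]] <- data.frame(
            comparison = paste(sp, ep, "mild vs extreme"),
            chi_square = bt$statistic[[1]], df = bt$parameter[[1]],
            p = bt$p.value, stringsAsFactors = FALSE)
        }
      }
      res$km <<- do.call(rbind, km_rows)
      res$tests <<- do.call(rbind, test_rows)
      utils::write.csv(res$km, out("km_curves.csv"), row.names = FALSE)
      utils::write.csv(res$tests, out("tests.csv"), row.names = FALSE)
    })
  }

  if ("curves" %in% config$stages) {
    run_stage("curves", function() {
      surv <- females[females$fate == "survived" &
                        females$status == "alive", ]
      fits <- fit_rate_curve(eggs ~ age, surv, include = c("b", "c"),
                             strata = c("species", "regime"))
      rows <- lapply(names(fits), function(nm) {
        p <- fits[[nm]]$params
        data.frame(stratum = nm,
                   parameter = c("a", "b", "c"),
                   estimate = c(p$a, p$b, p$c),
                   se = unname(p$se[c("a", "b", "c")]),
                   r_squared = p$r_squared, stringsAsFactors = FALSE)
      })
      res$curve_fits <<- do.call(rbind, rows)
      utils::write.csv(res$curve_fits, out("curve_fits.csv"),
                       row.names = FALSE)
      gee_rows <- list()
      for (sp in unique(surv$species)) {
        g <- fit_rate_gee(eggs ~ age, surv[surv$species == sp, ],
                          factors = c("regime", "acclimated"),
                          interactions = c("regime:t"),
                          include = c("b", "c"))
        log_lines <<- c(log_lines,
                        sprintf("gee[%s] trace: %s", sp,
                                paste(g$trace, collapse = "; ")))
        tt <- g$terms_table
        gee_rows[[sp]] <- cbind(species = sp, tt)
      }
      res$gee <<- do.call(rbind, gee_rows)
      utils::write.csv(res$gee, out("gee_tests.csv"), row.names = FALSE)
    })
  }

  if ("ratios" %in% config$stages) {
    run_stage("ratios", function() {
      summary_df <- if (!is.null(config$summary_csv)) {
        utils::read.csv(config$summary_csv, stringsAsFactors = FALSE)
      } else {
        rbind(.daily_rate_summary(females, "uncensored"),
              .daily_rate_summary(females, "censored"))
      }
      rs <- .ratio_stage(summary_df)
      res$ratios <<- rs$ratios
      utils::write.csv(rs$ratios, out("ratios.csv"), row.names = FALSE)
      utils::write.csv(rs$comparisons, out("comparisons.csv"),
                       row.names = FALSE)
      res$comparisons <<- rs$comparisons
    })
  }

  if ("glm" %in% config$stages) {
    run_stage("glm", function() {
      glm_rows <- list()
      for (sp in unique(females$species)) {
        sr <- sex_ratio_analysis(eggs[eggs$species == sp, ],
                                 females = females[females$species == sp, ])
        if (!is.null(sr$fit)) {
          tt <- sr$fit$terms_table
          if (!is.null(tt) && nrow(tt))
            glm_rows[[paste(sp, "sex_ratio")]] <-
              cbind(analysis = paste(sp, "sex_ratio"), family =
                      sr$fit$family_label, tt)
        }
        log_lines <<- c(log_lines,
                        sprintf("sex_ratio[%s]: %.1f%% female of %d sexed",
                                sp, 100 * sr$pooled$prop_female,
                                sr$pooled$n_sexed))
      }
      # prey feeding: mean damage over alive days, dead females excluded
      prey <- females[females$species == "prey" &
                        females$fate != "died", ]
      if (nrow(prey)) {
        per <- stats::aggregate(consumption ~ female_id + regime +
                                  acclimated, data = prey, FUN = mean)
        ft <- tryCatch(
          fit_factorial(consumption ~ regime * acclimated, per,
                        family = "normal"),
          error = function(e)       # empty cell in a tiny run: drop the
            fit_factorial(consumption ~ regime + acclimated, per,
                          family = "normal"))   # interaction
        tt <- ft$terms_table
        if (!is.null(tt) && nrow(tt))
          glm_rows[["prey feeding"]] <-
            cbind(analysis = "prey feeding", family = "normal", tt)
      }
      res$glm <<- do.call(rbind, glm_rows)
      utils::write.csv(res$glm, out("glm_results.csv"), row.names = FALSE)
    })
  }

  if ("report" %in% config$stages) {
    run_stage("report", function() {
      lines <- c("heatfec pipeline report", "=======================", "")
      if (!is.null(res$tallies)) {
        lines <- c(lines, "Fate tallies (per cell):",
                   utils::capture.output(print(res$tallies)), "")
      }
      if (!is.null(res$ratios)) {
        lines <- c(lines, "Extreme:mild oviposition ratios:",
                   utils::capture.output(
                     print(res$ratios, row.names = FALSE, digits = 4)), "")
      }
      if (!is.null(res$comparisons)) {
        lines <- c(lines, "Between-species ratio comparisons:",
                   utils::capture.output(
                     print(res$comparisons, row.names = FALSE,
                           digits = 4)), "")
      }
      if (!is.null(res$curve_fits)) {
        lines <- c(lines, "Rate-curve fits:",
                   utils::capture.output(
                     print(res$curve_fits, row.names = FALSE,
                           digits = 4)), "")
      }
      res$report_path <<- out("report.txt")
      writeLines(lines, res$report_path)
    })
  }

  writeLines(log_lines, out("run_log.txt"))
  invisible(res)
}

#' Validate pipeline tables against the schema and invariants
#'
#' Checks each CSV for required columns, then for the structural
#' invariants of the data model: fates are absorbing (no rows after the
#' fate day, no `alive` status on or after it), egg and consumption
#' counts are nonnegative and missing on event days, fate labels are
#' consistent with final status, egg rows populate exactly the geometry
#' matching their species, and volumes are positive.
#'
#' @param females_csv,eggs_csv file paths (either may be `NULL`).
#' @return Data frame with one row per check: `file`, `check`, `pass`,
#'   `detail`.
#' @export
validate_tables <- function(females_csv = NULL, eggs_csv = NULL) {
  rows <- list()
  add <- function(file, check, pass, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      file = file, check = check, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }
  if (!is.null(females_csv)) {
    f <- .read_table(females_csv, "females")
    add(females_csv, "rows", TRUE, sprintf("%d rows", nrow(f)))
    post <- !is.na(f$fate_day) & f$day > f$fate_day
    add(females_csv, "absorbing fate: no rows after fate_day", !any(post),
        if (any(post)) sprintf("%d offending rows", sum(post)) else "")
    alive_after <- !is.na(f$fate_day) & f$day >= f$fate_day &
      f$status == "alive"
    add(females_csv, "no alive status on/after fate_day",
        !any(alive_after),
        if (any(alive_after)) sprintf("%d rows", sum(alive_after)) else "")
    egg_after <- !is.na(f$fate_day) & f$day >= f$fate_day &
      !is.na(f$eggs) & f$eggs > 0
    add(females_csv, "no eggs on/after fate_day", !any(egg_after),
        if (any(egg_after)) sprintf("%d rows", sum(egg_after)) else "")
    neg <- (!is.na(f$eggs) & f$eggs < 0) |
      (!is.na(f$consumption) & f$consumption < 0)
    add(females_csv, "nonnegative counts", !any(neg),
        if (any(neg)) sprintf("%d rows", sum(neg)) else "")
    last <- f[!duplicated(f$female_id, fromLast = TRUE), ]
    bad_fate <- xor(last$fate == "survived", last$status == "alive")
    add(females_csv, "fate 'survived' iff alive on final day",
        !any(bad_fate),
        if (any(bad_fate)) sprintf("%d females", sum(bad_fate)) else "")
  }
  if (!is.null(eggs_csv)) {
    e <- .read_table(eggs_csv, "eggs")
    add(eggs_csv, "rows", TRUE, sprintf("%d rows", nrow(e)))
    both <- !is.na(e$r_um) & (!is.na(e$a_um) | !is.na(e$b_um))
    add(eggs_csv, "exactly one geometry populated", !any(both),
        if (any(both)) sprintf("%d rows", sum(both)) else "")
    mism <- (e$species == "predator" & e$shape != "ellipsoid") |
      (e$species == "prey" & e$shape != "sphere")
    add(eggs_csv, "geometry matches species", !any(mism),
        if (any(mism)) sprintf("%d rows", sum(mism)) else "")
    add(eggs_csv, "positive volumes", all(e$volume_um3 > 0),
        if (!all(e$volume_um3 > 0))
          sprintf("%d rows", sum(e$volume_um3 <= 0)) else "")
  }
  do.call(rbind, rows)
}
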