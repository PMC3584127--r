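#' Build a pipeline run configuration
#'
#' Collects every knob of the design → simulate → fit → analyze pipeline
#' into one serializable object. Every stochastic stage receives a seed
#' derived deterministically from the master seed via [derive_seed()].
#'
#' @param levels signed FOV levels, degrees (default [default_levels()]).
#' @param reps repetitions per level (default 40).
#' @param block_size trials per block (default 40).
#' @param n_per_sex observers per sex group (default 11).
#' @param cohort per-group generative parameters (default
#'   [cohort_defaults()]).
#' @param n_mc Monte-Carlo goodness-of-fit simulations per observer
#'   (0 skips the test; default 500).
#' @param n_boot bootstrap draws for group slope intervals (0 skips;
#'   default 200).
#' @param lapse_bounds,guess_bounds fitting constraints (default
#'   `c(0, 0.06)`).
#' @param seed master seed.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return A `run_config` list.
#' @export
run_config <- function(levels = default_levels(), reps = 40L,
                       block_size = 40L, n_per_sex = 11L,
                       cohort = cohort_defaults(), n_mc = 500L,
                       n_boot = 200L, lapse_bounds = c(0, 0.06),
                       guess_bounds = c(0, 0.06), seed = 1L,
                       out_dir = NULL) {
  cfg <- list(levels = levels, reps = as.integer(reps),
              block_size = as.integer(block_size),
              n_per_sex = as.integer(n_per_sex), cohort = cohort,
              n_mc = as.integer(n_mc), n_boot = as.integer(n_boot),
              lapse_bounds = lapse_bounds, guess_bounds = guess_bounds,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as JSON
#' @param config a `run_config`.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a `run_config` identical to the one written.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(levels = obj$levels, reps = obj$reps,
             block_size = obj$block_size, n_per_sex = obj$n_per_sex,
             cohort = obj$cohort, n_mc = obj$n_mc, n_boot = obj$n_boot,
             lapse_bounds = obj$lapse_bounds,
             guess_bounds = obj$guess_bounds, seed = obj$seed,
             out_dir = obj$out_dir)
}

TRIAL_COLUMNS <- c("observer_id", "sex_group", "trial", "block",
                   "signed_fov", "start_phase", "response", "rt",
                   "is_practice")

#' Write / read trial records as CSV
#'
#' Comma-separated, UTF-8, header row mandatory, `.` decimal. Reading
#' validates the schema (all mandatory columns present, responses binary,
#' reaction times positive) and reports offending columns or row numbers;
#' unknown extra columns are preserved.
#'
#' @param trials data.frame of trial records.
#' @param path file path.
#' @return `write_trials` returns `path` invisibly; `read_trials` the
#'   validated data.frame.
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols) > 0) {
    stop("trial table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("trial file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!df$response %in% c("FTV", "FA"))
  if (length(bad) > 0) {
    stop(sprintf("invalid response at row %d: '%s'", bad[1],
                 df$response[bad[1]]), call. = FALSE)
  }
  bad <- which(!is.finite(df$rt) | df$rt <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-positive reaction time at row %d", bad[1]),
         call. = FALSE)
  }
  df
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes design → simulate → fit → analyze: samples a cohort, builds a
#' randomized schedule per observer, simulates all trials, fits each
#' observer's psychometric function (with optional Monte-Carlo
#' goodness-of-fit), fits the pooled and per-sex-group curves (with
#' optional bootstrap slope intervals), and runs the group statistics
#' (probit RM-ANOVA, RT RM-ANOVA, RT polynomial t-tests, RT-certainty
#' Spearman correlation). Deterministic given the master seed. If
#' `config$out_dir` is set, writes `trials.csv`, `fits.csv`,
#' `summaries.csv`, `anova_z.csv`, `anova_rt.csv`, `rt_fits.csv`,
#' `rt_ttests.csv`, `stats.json`, and `manifest.json` there.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `trials`, `fits` (per-observer table),
#'   `pooled`, `by_sex` (fits + slope CIs), `summaries`, `anova_z`,
#'   `anova_rt`, `rt_fits`, `rt_ttests`, `spearman`, and `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- "sample_cohort"
  res <- tryCatch({
    cohort <- sample_cohort(config$n_per_sex, config$cohort,
                            seed = derive_seed(config$seed, "cohort"))

    stage <- "design/simulate"
    trials <- do.call(rbind, lapply(cohort, function(m) {
      sched <- build_schedule(config$levels, config$reps,
                              config$block_size,
                              seed = derive_seed(config$seed, "design",
                                                 m$observer_id))
      simulate_trials(m, sched)
    }))
    rownames(trials) <- NULL

    stage <- "fit"
    notes <- character()
    # a stage that is under-determined for this design is flagged and
    # skipped, not fatal: degenerate configs still produce a manifest
    soft <- function(label, expr) {
      tryCatch(expr, error = function(e) {
        notes <<- c(notes, sprintf("%s: %s", label, conditionMessage(e)))
        NULL
      })
    }
    counts_by_obs <- lapply(split(trials, trials$observer_id),
                            aggregate_trials)
    fit_rows <- list()
    for (id in names(counts_by_obs)) {
      sex <- trials$sex_group[match(id, trials$observer_id)]
      f <- soft(paste0("fit[", id, "]"), {
        f <- fit_psychometric(counts_by_obs[[id]],
                              lapse_bounds = config$lapse_bounds,
                              guess_bounds = config$guess_bounds)
        if (config$n_mc >= 100L) {
          f <- mc_goodness_of_fit(f, n_sim = config$n_mc,
                                  seed = derive_seed(config$seed, "mc", id))
        }
        f
      })
      fit_rows[[id]] <- if (is.null(f)) {
        data.frame(observer_id = id, sex_group = sex, psa = NA_real_,
                   spread = NA_real_, lapse = NA_real_, guess = NA_real_,
                   slope = NA_real_, deviance = NA_real_, mc_p = NA_real_,
                   converged = FALSE, extreme_psa = NA,
                   under_determined = TRUE)
      } else {
        data.frame(observer_id = id, sex_group = sex, psa = f$psa,
                   spread = f$spread, lapse = f$lapse, guess = f$guess,
                   slope = f$slope_at_psa, deviance = f$deviance,
                   mc_p = f$mc_p_value, converged = f$converged,
                   extreme_psa = f$extreme_psa, under_determined = FALSE)
      }
    }
    fits <- do.call(rbind, fit_rows)
    rownames(fits) <- NULL

    pooled <- soft("pooled_fit",
                   pooled_fit(unname(counts_by_obs),
                              lapse_bounds = config$lapse_bounds,
                              guess_bounds = config$guess_bounds))
    by_sex <- list()
    for (g in c("female", "male")) {
      ids <- fits$observer_id[fits$sex_group == g]
      gf <- soft(paste0("pooled_fit[", g, "]"),
                 pooled_fit(unname(counts_by_obs[ids]),
                            lapse_bounds = config$lapse_bounds,
                            guess_bounds = config$guess_bounds))
      ci <- if (!is.null(gf) && config$n_boot > 0L) {
        bootstrap_slope_ci(gf, n_boot = config$n_boot,
                           seed = derive_seed(config$seed, "boot", g))
      } else NULL
      by_sex[[g]] <- list(fit = gf, slope_ci = ci)
    }

    stage <- "analyze"
    summaries <- observer_level_summary(trials)
    anova_z <- soft("anova_z", mixed_rm_anova(summaries, "z_ftv"))
    anova_rt <- soft("anova_rt", mixed_rm_anova(summaries, "mean_rt"))
    rt_fits <- soft("rt_poly", rt_poly_table(summaries))
    rt_tt <- if (is.null(rt_fits)) NULL else
      soft("rt_ttests", group_ttests(rt_fits))
    sp <- soft("spearman", spearman_rt_certainty(summaries))

    manifest <- list(
      package_version = as.character(utils::packageVersion("facingbias")),
      seed = config$seed,
      n_observers = length(cohort),
      n_levels = length(config$levels),
      reps = config$reps,
      n_trials = nrow(trials),
      n_mc = config$n_mc,
      n_boot = config$n_boot,
      skipped = notes
    )
    list(trials = trials, fits = fits, pooled = pooled, by_sex = by_sex,
         summaries = summaries, anova_z = anova_z, anova_rt = anova_rt,
         rt_fits = rt_fits, rt_ttests = rt_tt, spearman = sp,
         manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_trials(res$trials, p("trials.csv"))
    utils::write.csv(res$fits, p("fits.csv"), row.names = FALSE)
    utils::write.csv(res$summaries, p("summaries.csv"), row.names = FALSE)
    wr <- function(x, f) if (!is.null(x)) {
      utils::write.csv(as.data.frame(x), p(f), row.names = FALSE)
    }
    wr(res$anova_z, "anova_z.csv")
    wr(res$anova_rt, "anova_rt.csv")
    wr(res$rt_fits, "rt_fits.csv")
    wr(res$rt_ttests, "rt_ttests.csv")
    stats_json <- list(
      pooled = if (is.null(res$pooled)) NULL else
        res$pooled[c("psa", "spread", "lapse", "guess", "slope_at_psa",
                     "deviance")],
      by_sex = lapply(res$by_sex, function(b) {
        if (is.null(b$fit)) return(NULL)
        c(b$fit[c("psa", "spread", "slope_at_psa")],
          list(slope_ci = if (is.null(b$slope_ci)) NULL
               else b$slope_ci[c("lo", "hi", "level")]))
      }),
      spearman = res$spearman
    )
    jsonlite::write_json(stats_json, p("stats.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    jsonlite::write_json(res$manifest, p("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}
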