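# End-to-end orchestration: simulate -> classify tactics -> rates ->
# matrix demography -> hunting curves, with a reproducibility manifest.
# Machine outputs are JSON files with fixed numeric formatting so that
# re-running an identical configuration reproduces byte-identical output;
# progress logging goes to stderr.

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed; per-stage seeds are derived from it by fixed
#'   offsets unless set explicitly in `stage_seeds`.
#' @param stages Named logical vector toggling the five stages
#'   (`simulate`, `tactics`, `rates`, `demography`, `hunting`).
#' @param simulation List of overrides passed to [simulation_config()].
#' @param n_bootstrap_rates Draws for the rate table (default 10000).
#' @param n_bootstrap_repeatability Bootstrap iterations for the
#'   repeatability CI (default 1000).
#' @param pressure_grid Pressure grid for the hunting stage.
#' @param bear_years,litters Input CSV paths, used when the simulate stage
#'   is off.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "caretactics-out", seed = 42,
                            stages = c(simulate = TRUE, tactics = TRUE,
                                       rates = TRUE, demography = TRUE,
                                       hunting = TRUE),
                            simulation = list(),
                            n_bootstrap_rates = 10000,
                            n_bootstrap_repeatability = 1000,
                            pressure_grid = seq(0, 0.33, length.out = 12),
                            bear_years = NULL, litters = NULL) {
  st <- c(simulate = TRUE, tactics = TRUE, rates = TRUE, demography = TRUE,
          hunting = TRUE)
  st[names(stages)] <- stages
  cfg <- list(out_dir = out_dir, seed = seed, stages = st,
              simulation = simulation,
              n_bootstrap_rates = n_bootstrap_rates,
              n_bootstrap_repeatability = n_bootstrap_repeatability,
              pressure_grid = pressure_grid,
              bear_years = bear_years, litters = litters,
              stage_seeds = list(simulate = seed, rates = seed + 1,
                                 tactics = seed + 2, hunting = seed + 3))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' @param path File path; `.yaml`/`.yml` or `.json`.
#' @return A `pipeline_config` (unknown fields are rejected).
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown pipeline config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

log_stage <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [caretactics] ", ...)
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       na = "null", pretty = TRUE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order and writes one JSON
#' output per stage plus a manifest (package version, seeds, per-stage
#' output paths and md5 checksums). Re-running an identical configuration
#' reproduces byte-identical JSON outputs. A stage failure aborts the run
#' with that stage's error; outputs of completed stages are retained and
#' listed in the (partial) manifest written before the error propagates.
#'
#' @param config A [pipeline_config()] or a path readable by
#'   [read_pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("caretactics")),
    seed = config$seed, stages = list(), inputs = list()
  )
  finish <- function() {
    path <- file.path(config$out_dir, "manifest.json")
    write_stage_json(manifest, path)
    manifest
  }
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(e))
    finish()
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  record_stage <- function(stage, outputs) {
    manifest$stages[[stage]] <<- list(
      status = "ok", outputs = outputs,
      md5 = as.list(tools::md5sum(unlist(outputs)))
    )
  }

  # --- simulate ---
  if (config$stages[["simulate"]]) {
    log_stage("stage simulate")
    tryCatch({
      sim_cfg <- do.call(simulation_config,
                         utils::modifyList(
                           list(seed = config$stage_seeds$simulate),
                           config$simulation))
      sim <- simulate_population(sim_cfg)
      by_path <- file.path(config$out_dir, "bear_years.csv")
      li_path <- file.path(config$out_dir, "litters.csv")
      tr_path <- file.path(config$out_dir, "truth.json")
      write_bear_years(sim$bear_years, by_path)
      write_litters(sim$litters, li_path)
      write_stage_json(sim$truth, tr_path)
      record_stage("simulate", list(bear_years = by_path, litters = li_path,
                                    truth = tr_path))
      bear_years <- sim$bear_years
      litters <- sim$litters
    }, error = function(e) fail("simulate", e))
  } else {
    if (is.null(config$bear_years) || is.null(config$litters)) {
      stop("simulate stage disabled: config must name bear_years and ",
           "litters CSV inputs", call. = FALSE)
    }
    bear_years <- read_bear_years(config$bear_years)
    litters <- read_litters(config$litters)
    manifest$inputs <- list(bear_years = config$bear_years,
                            litters = config$litters)
  }

  # --- tactics ---
  if (config$stages[["tactics"]]) {
    log_stage("stage tactics")
    tryCatch({
      assignments <- assign_tactics(litters)
      trend <- weaning_trend(litters)
      rpt <- tryCatch(
        care_repeatability(litters,
                           n_bootstrap = config$n_bootstrap_repeatability,
                           seed = config$stage_seeds$tactics),
        error = function(e) list(note = conditionMessage(e)))
      primi <- primiparity_effect(litters)
      cons <- consistency_summary(assignments, bear_years)
      out <- list(
        assignments = assignments,
        trend = unclass(trend)[setdiff(names(trend), "fit")],
        repeatability = unclass(rpt),
        primiparity = primi[setdiff(names(primi), "fit")],
        consistency = cons
      )
      path <- file.path(config$out_dir, "tactics.json")
      write_stage_json(out, path)
      record_stage("tactics", list(tactics = path))
    }, error = function(e) fail("tactics", e))
  }

  # --- rates ---
  rate_table <- NULL
  fs <- NULL
  if (config$stages[["rates"]] || config$stages[["demography"]] ||
      config$stages[["hunting"]]) {
    log_stage("stage rates")
    tryCatch({
      fs <- fit_survival(bear_years)
      fr <- fit_recruitment(bear_years)
      rate_table <- bootstrap_rates(fs, fr,
                                    n_bootstrap = config$n_bootstrap_rates,
                                    seed = config$stage_seeds$rates)
      prot <- protection_effect(bear_years)
      out <- list(
        survival_model = fs$coefficients,
        recruitment_model = fr$coefficients,
        interaction_lrt = fs$interaction_lrt,
        rate_table = as.data.frame(rate_table),
        protection = list(odds_ratio = prot$odds_ratio,
                          ci = c(prot$or_ci_low, prot$or_ci_high),
                          rates = prot$rates,
                          hunting_odds_ratio = prot$hunting_odds_ratio)
      )
      path <- file.path(config$out_dir, "rates.json")
      write_stage_json(out, path)
      if (config$stages[["rates"]]) {
        record_stage("rates", list(rates = path))
      }
    }, error = function(e) fail("rates", e))
  }

  # --- demography ---
  if (config$stages[["demography"]]) {
    log_stage("stage demography")
    tryCatch({
      boot <- bootstrap_demography(rate_table)
      mats <- lapply(tactic_levels(), function(tac) {
        p <- rates_for_tactic(rate_table, tac, column = "point")
        unclass(build_leslie(p$s[1], p$s[2], p$s[3], p$s[4], p$s[5],
                             p$r59, p$r10p, tactic = tac))
      })
      names(mats) <- tactic_levels()
      out <- list(
        matrices = lapply(mats, function(m) {
          attributes(m)[c("rates", "tactic")] <- NULL; m
        }),
        point = lapply(boot$point, unclass),
        bootstrap_summary = boot$summary,
        p_T25_longer_T = boot$p_T25_longer_T,
        n_dropped = boot$n_dropped
      )
      path <- file.path(config$out_dir, "demography.json")
      write_stage_json(out, path)
      record_stage("demography", list(demography = path))
    }, error = function(e) fail("demography", e))
  }

  # --- hunting ---
  if (config$stages[["hunting"]]) {
    log_stage("stage hunting")
    tryCatch({
      pr <- pressure_index(bear_years)
      pm <- fit_pressure_models(bear_years, pr,
                                seed = config$stage_seeds$hunting)
      recr <- c(
        T15 = rate_table$point[rate_table$tactic == "T15" &
                                 rate_table$cell == "R5-9"],
        T25 = rate_table$point[rate_table$tactic == "T25" &
                                 rate_table$cell == "R5-9"]
      )
      lv <- lambda_vs_pressure(pm, recr, pressures = config$pressure_grid)
      out <- list(pressure_index = as.data.frame(pr),
                  recruitment = as.list(recr),
                  quantiles = lv$quantiles, n_invalid = lv$n_invalid)
      path <- file.path(config$out_dir, "curves.json")
      write_stage_json(out, path)
      record_stage("hunting", list(curves = path))
    }, error = function(e) fail("hunting", e))
  }

  log_stage("done: ", sum(vapply(manifest$stages, function(s)
    identical(s$status, "ok"), TRUE)), " stage(s)")
  invisible(finish())
}

#' Human-readable report from a pipeline run
#'
#' Formats the JSON outputs referenced by a manifest as markdown tables
#' (model coefficients, rate table, demographic comparison, hunting
#' curves). Values are read from the files, never recomputed; missing stage
#' outputs are noted, not fatal.
#'
#' @param manifest A manifest as returned by [run_pipeline()], or the path
#'   to a `manifest.json`, or the output directory containing it.
#' @return Character vector of report lines, invisibly; also printed.
#' @export
pipeline_report <- function(manifest) {
  if (is.character(manifest)) {
    path <- if (dir.exists(manifest)) {
      file.path(manifest, "manifest.json")
    } else {
      manifest
    }
    manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
    base <- dirname(path)
  } else {
    base <- "."
  }
  lines <- character()
  add <- function(...) lines <<- c(lines, paste0(...))
  stages <- manifest$stages
  if (length(stages) == 0) {
    add("no stages run")
    cat(lines, sep = "\n")
    return(invisible(lines))
  }
  add("# caretactics pipeline report", "")
  add("Stages: ", paste(names(stages), collapse = ", "), "")
  get_out <- function(stage, name) {
    p <- stages[[stage]]$outputs[[name]]
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) p <- file.path(base, basename(p))
    if (!file.exists(p)) return(NULL)
    jsonlite::read_json(p, simplifyVector = TRUE)
  }
  md_table <- function(df, digits = 3) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, digits)
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                      " |")))
  }
  rates <- get_out("rates", "rates")
  if (!is.null(rates)) {
    add("## Demographic-rate models", "")
    lines <- c(lines, md_table(as.data.frame(rates$survival_model)), "")
    lines <- c(lines, md_table(as.data.frame(rates$recruitment_model)), "")
    add("## Tactic- and age-class-specific rates", "")
    lines <- c(lines, md_table(as.data.frame(rates$rate_table)), "")
  } else {
    add("(rates output missing)", "")
  }
  demo <- get_out("demography", "demography")
  if (!is.null(demo)) {
    add("## Demographic comparison of tactics", "")
    for (tac in names(demo$point)) {
      p <- demo$point[[tac]]
      add("- ", tac, ": lambda = ", round(p$lambda, 3),
          ", R0 = ", round(p$R0, 3), ", T = ", round(p$T, 2),
          " y, adult fraction = ", round(100 * p$adult_fraction, 1), "%")
    }
    add("", "P(generation time T25 > T15) = ",
        round(demo$p_T25_longer_T, 3), "")
  } else {
    add("(demography output missing)", "")
  }
  curves <- get_out("hunting", "curves")
  if (!is.null(curves)) {
    add("## Growth rate vs hunting pressure (medians)", "")
    lines <- c(lines, md_table(as.data.frame(curves$quantiles)), "")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
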