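#' Run a simulate-fit-validate-report workflow from one config
#'
#' Stages (`simulate`, `fit`, `metrics`, `hte`, `report`) run in order; each
#' writes plain-text artifacts (CSV/JSON) into the output directory and the
#' run ends with a manifest recording seeds, stage status and md5 hashes of
#' every artifact. All randomness derives from the single root seed, one
#' sub-seed per stage, so identical configs give identical artifacts.
#'
#' @param config a named list or path to a YAML/JSON file with fields:
#'   `task` (`"reward_effort"` or `"attribution"`), `stages` (character
#'   vector), `seed`, `profile` (`"test"` or `"paper"`), `out_dir`,
#'   `n_subjects`, and optionally `intervention_effect` (named per-parameter
#'   shift applied at session 2 in the active arm).
#' @return the manifest (list), invisibly; written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  defaults <- list(task = "reward_effort",
                   stages = c("simulate", "fit", "metrics", "hte", "report"),
                   seed = 1L, profile = "test", out_dir = "cbtmech-run",
                   n_subjects = 30, intervention_effect = NULL)
  config <- utils::modifyList(defaults, config)
  known <- c("simulate", "fit", "metrics", "hte", "report")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!config$task %in% c("reward_effort", "attribution"))
    stop("unknown task: ", config$task, call. = FALSE)
  need_before <- c(fit = "simulate", metrics = "fit", hte = "fit", report = "fit")
  for (st in config$stages)
    if (st %in% names(need_before) &&
        match(need_before[[st]], config$stages, nomatch = 99) > match(st, config$stages))
      stop("stage '", st, "' requires stage '", need_before[[st]],
           "' earlier in the list", call. = FALSE)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  stage_seeds <- setNames(sample.int(.Machine$integer.max, length(known)), known)

  manifest <- list(package = "cbtmech",
                   version = as.character(utils::packageVersion("cbtmech")),
                   config = config[setdiff(names(config), "out_dir")],
                   stage_seeds = as.list(stage_seeds), stages = list(),
                   artifacts = list())
  env <- new.env()
  log_path <- file.path(config$out_dir, "run-log.jsonl")
  if (file.exists(log_path)) unlink(log_path)

  for (st in config$stages) {
    t0 <- Sys.time()
    status <- "complete"
    err <- tryCatch({
      .pipeline_stage(st, config, stage_seeds[[st]], env)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(err)) status <- "failed"
    rec <- list(stage = st, status = status, seed = stage_seeds[[st]],
                seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
    if (!is.null(err)) rec$error <- err
    manifest$stages[[st]] <- rec
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
    if (!is.null(err)) {
      manifest$failed <- TRUE
      break
    }
  }

  # the timing log is not a reproducible artifact; leave it out of the hashes
  files <- setdiff(list.files(config$out_dir), c("manifest.json", "run-log.jsonl"))
  manifest$artifacts <- lapply(files, function(f) {
    path <- file.path(config$out_dir, f)
    list(file = f, md5 = unname(tools::md5sum(path)))
  })
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (isTRUE(manifest$failed))
    stop("pipeline stage failed; partial outputs preserved in ", config$out_dir,
         call. = FALSE)
  invisible(manifest)
}

.pipeline_stage <- function(stage, config, seed, env) {
  out <- config$out_dir
  mcmc <- mcmc_control(profile = config$profile, seed = seed)
  if (stage == "simulate") {
    phi <- config$intervention_effect
    if (config$task == "reward_effort") {
      cc_args <- list(n_subjects = config$n_subjects, seed = seed)
      if (!is.null(phi)) cc_args$reward_effort <- list(phi_int = unlist(phi))
      cohort <- do.call(cohort_config, cc_args)
      env$data <- simulate_reward_effort_cohort(generate_task_design(seed = seed),
                                                cohort)
    } else {
      cc_args <- list(n_subjects = config$n_subjects, seed = seed)
      if (!is.null(phi)) cc_args$attribution <- list(phi_int = phi)
      cohort <- do.call(cohort_config, cc_args)
      env$data <- simulate_attribution_cohort(generate_attribution_design(seed = seed),
                                              cohort)
    }
    write.csv(env$data, file.path(out, "data.csv"), row.names = FALSE)
  } else if (stage == "fit") {
    kept <- apply_exclusion_rules(env$data, config$task)
    write.csv(kept$report, file.path(out, "exclusions.csv"), row.names = FALSE)
    env$fit <- if (config$task == "reward_effort")
      fit_reward_effort(kept$data, mcmc = mcmc)
    else fit_attribution(kept$data, mcmc = mcmc)
    env$kept_data <- kept$data
    write.csv(env$fit$summaries, file.path(out, "posterior-summary.csv"),
              row.names = FALSE)
    eff <- intervention_effect_summary(env$fit)
    jsonlite::write_json(eff, file.path(out, "intervention-effects.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else if (stage == "metrics") {
    m <- fit_metrics(env$fit, env$kept_data, seed = seed)
    jsonlite::write_json(m, file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (stage == "hte") {
    par <- if (config$task == "reward_effort") "effSens" else "theta_int_pos"
    h <- hte_from_fit(env$fit, par)
    jsonlite::write_json(list(parameter = par, sd_act = h$sd_act,
                              sd_con = h$sd_con, sd_ir = h$sd_ir,
                              sd_ir_se = h$sd_ir_se, ci95 = h$ci95,
                              effect_class = h$effect_class),
                         file.path(out, "hte.json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (stage == "report") {
    write_report(out)
  }
  invisible(NULL)
}

#' Write a human-readable report for a completed run
#'
#' Summarises the artifacts of a [run_pipeline()] output directory into
#' `report.md`: intervention-effect credible intervals with zero-exclusion
#' flags and SMD scalings, fit metrics, and the heterogeneity table.
#'
#' @param run_dir output directory of a pipeline run.
#' @return path of the written report, invisibly.
#' @export
write_report <- function(run_dir) {
  need <- c("posterior-summary.csv", "intervention-effects.json")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("missing artifacts in ", run_dir, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  summ <- read.csv(file.path(run_dir, "posterior-summary.csv"))
  eff <- jsonlite::read_json(file.path(run_dir, "intervention-effects.json"),
                             simplifyVector = TRUE)
  lines <- c("# Run report", "")
  lines <- c(lines, "## Intervention effects (90% CI)", "")
  for (i in seq_len(nrow(eff))) {
    lines <- c(lines, sprintf(
      "- %s: mean %.3f [%.3f, %.3f], zero %s, SMD-scaled %.3f",
      eff$parameter[i], eff$mean[i], eff$lower[i], eff$upper[i],
      if (isTRUE(eff$excludes_zero[i])) "excluded" else "not excluded",
      eff$smd[i]))
  }
  mfile <- file.path(run_dir, "metrics.json")
  if (file.exists(mfile)) {
    m <- jsonlite::read_json(mfile, simplifyVector = TRUE)
    lines <- c(lines, "", "## Fit metrics", "",
               sprintf("- posterior predictive accuracy: %s (SD %s)",
                       paste(round(unlist(m$ppa_mean), 3), collapse = "/"),
                       paste(round(unlist(m$ppa_sd), 3), collapse = "/")),
               sprintf("- pseudo-R2: %.3f", m$pseudo_r2),
               sprintf("- max group-level R-hat: %.3f", m$max_rhat))
  }
  hfile <- file.path(run_dir, "hte.json")
  if (file.exists(hfile)) {
    h <- jsonlite::read_json(hfile, simplifyVector = TRUE)
    lines <- c(lines, "", "## Heterogeneity of treatment effects", "",
               sprintf("- %s: SD_IR %.3f (SE %.3f), 95%% CI [%.3f, %.3f], class %s",
                       h$parameter, h$sd_ir, h$sd_ir_se, h$ci95[1], h$ci95[2],
                       h$effect_class))
  }
  lines <- c(lines, "", "## Group-level posterior summary", "")
  gp <- utils::head(summ[grepl("^(mu_|sigma_|R_|phi_|beta_)", summ$parameter), ], 40)
  for (i in seq_len(nrow(gp)))
    lines <- c(lines, sprintf("- %s: %.3f (sd %.3f, rhat %.3f)",
                              gp$parameter[i], gp$mean[i], gp$sd[i], gp$rhat[i]))
  path <- file.path(run_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

#' Read a pipeline config from YAML or JSON
#'
#' @param path file path; format chosen by extension.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
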