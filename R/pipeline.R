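#' The default model battery
#'
#' The ten (behaviour, period) models fitted by default: pant hoot,
#' piloerection, sound surround and alert focus environment in both
#' periods; swaying before only; climax scream after only (the excluded
#' combinations occurred too rarely to model).
#'
#' @return data frame with columns `behaviour`, `period`
#' @export
default_model_battery <- function() {
  rbind(
    expand.grid(behaviour = c("pant_hoot", "piloerection", "sound_surround",
                              "alert_focus_environment"),
                period = c("before", "after"), stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE),
    data.frame(behaviour = c("swaying", "climax_scream"),
               period = c("before", "after"), stringsAsFactors = FALSE)
  )
}

#' Default pipeline configuration
#'
#' @return named list of the configuration keys understood by
#'   [run_pipeline()], with their defaults
#' @export
default_pipeline_config <- function() {
  list(input = NULL,          # path to an event-table CSV; NULL simulates
       simulate = list(n_individuals = 28, mean_events = 5.5,
                       true_sigma = 1),
       outdir = "occdur_results",
       seed = 1,
       n_boot = 1000,
       nodes = 20,
       B_bounds = c(1e-4, 0.99),
       combined = FALSE,      # additionally fit period-collapsed models
       models = NULL)         # NULL = default_model_battery()
}

#' Run the full occurrence-analysis pipeline
#'
#' For every configured (behaviour, period) model: subset the event table,
#' profile the per-second rate `B`, fit the mixed model, test the
#' activity-type effect by LRT, compute parametric-bootstrap confidence
#' limits and leave-one-individual-out stability ranges, and write a
#' report block. Outputs (all under `outdir`): one
#' `<behaviour>_<period>_summary.csv` per model, a
#' `<behaviour>_<period>_replicates.csv` of bootstrap draws, a combined
#' `report.csv`, and `run_log.txt` recording seeds, tolerances, the
#' estimated `B` and its profile trace per model. A model failing hard is
#' recorded in the report and the pipeline continues. With the same
#' configuration and seed the results directory is reproduced exactly.
#'
#' @param config named list (see [default_pipeline_config()]) or path to a
#'   YAML `key: value` file with those keys
#' @return invisibly, a list with per-model results and the report data
#'   frame
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- modifyList(default_pipeline_config(), config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$input)) {
    data <- read_events(cfg$input)
    src <- cfg$input
  } else {
    data <- do.call(simulate_study,
                    c(cfg$simulate, list(seed = cfg$seed)))
    src <- "simulated"
    write_events(data, file.path(cfg$outdir, "simulated_events.csv"))
  }
  battery <- if (is.null(cfg$models)) default_model_battery()
  else as.data.frame(cfg$models, stringsAsFactors = FALSE)
  if (isTRUE(cfg$combined)) {
    extra <- unique(battery["behaviour"])
    extra$period <- "combined"
    battery <- rbind(battery, extra)
    data_combined <- collapse_periods(data)
  }

  log_lines <- c("occdur pipeline run",
                 paste0("input: ", src),
                 paste0("seed: ", cfg$seed),
                 paste0("n_boot: ", cfg$n_boot),
                 paste0("quadrature nodes: ", cfg$nodes),
                 paste0("B search interval: [", cfg$B_bounds[1], ", ",
                        cfg$B_bounds[2], "]"),
                 "")
  append_log <- function(...) log_lines <<- c(log_lines, ...)
  results <- list()
  report <- list()
  for (m in seq_len(nrow(battery))) {
    beh <- battery$behaviour[m]
    per <- battery$period[m]
    tag <- paste0(beh, "_", per)
    # per-model seed derived deterministically from the master seed
    seed_m <- (cfg$seed * 1000L + m) %% .Machine$integer.max
    res <- tryCatch({
      sub <- if (per == "combined") data_combined[data_combined$behaviour == beh, ]
      else data[data$behaviour == beh & data$period == per, ]
      fit <- occm(occurred ~ activity, sub, B_bounds = cfg$B_bounds,
                  nodes = cfg$nodes)
      lrt <- occm_lrt(fit, sub)
      boot <- occm_boot(fit, n_boot = cfg$n_boot, seed = seed_m)
      loo <- occm_loo(fit)
      tab <- occm_table(fit, lrt, boot, loo, behaviour = beh, period = per)
      write.csv(tab, file.path(cfg$outdir, paste0(tag, "_summary.csv")),
                row.names = FALSE)
      write.csv(as.data.frame(boot$estimates),
                file.path(cfg$outdir, paste0(tag, "_replicates.csv")),
                row.names = FALSE)
      append_log(paste0("model ", tag, ": n=", fit$n_obs,
                             " individuals=", fit$n_individuals,
                             " B_hat=", format(fit$B, digits = 8),
                             " sigma_hat=", format(fit$sigma, digits = 6),
                             " logLik=", format(fit$loglik, digits = 10),
                             " seed=", seed_m,
                             " boot_failed=", boot$n_failed,
                             " loo_failed=", loo$n_failed),
                 paste0("  profile B trace: ",
                             paste(sprintf("%.6g:%.6f", fit$profile$B,
                                           fit$profile$loglik),
                                   collapse = " ")))
      list(fit = fit, lrt = lrt, boot = boot, loo = loo, table = tab)
    }, error = function(e) {
      append_log(paste0("model ", tag, ": FAILED (",
                        conditionMessage(e), ")"))
      warning("model ", tag, " failed: ", conditionMessage(e), call. = FALSE)
      list(error = conditionMessage(e))
    })
    results[[tag]] <- res
    report[[tag]] <- if (is.null(res$error)) res$table
    else data.frame(behaviour = beh, period = per, term = "FAILED",
                    Est. = NA_real_, SE = NA_real_, CI_lower = NA_real_,
                    CI_upper = NA_real_, chi2 = NA_real_, df = NA_real_,
                    P = NA_real_, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  }
  report_df <- do.call(rbind, lapply(report, as.data.frame))
  rownames(report_df) <- NULL
  write.csv(report_df, file.path(cfg$outdir, "report.csv"), row.names = FALSE)
  writeLines(log_lines, file.path(cfg$outdir, "run_log.txt"))
  invisible(list(results = results, report = report_df, outdir = cfg$outdir))
}
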