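#' Export a subject trace as CSV
#'
#' Writes the per-minute trajectory of a simulated subject with columns
#' `t_min, G_mM, sensor_mM, available, insulin_Uh, dextrose_mLh, CHO_gh`.
#'
#' @param record a `trial_record`.
#' @param path output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_trace_csv <- function(record, path) {
  cmd <- record$commands
  tt <- record$plasma$t
  idx <- findInterval(tt, cmd$t_min)
  idx[idx == 0] <- 1
  df <- data.frame(
    t_min = tt,
    G_mM = record$plasma$G,
    sensor_mM = record$sensor$G,
    available = record$sensor$available,
    insulin_Uh = cmd$insulin_Uh[idx],
    dextrose_mLh = cmd$dextrose_mLh[idx],
    CHO_gh = record$nutrition$CHO_gh)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export a command log as CSV
#'
#' @param record a `trial_record`.
#' @param path output CSV path.
#' @return The command log, invisibly.
#' @export
write_command_csv <- function(record, path) {
  utils::write.csv(record$commands, path, row.names = FALSE)
  invisible(record$commands)
}

#' Default trial configuration
#'
#' Nested list mirroring the configurable pieces of a trial run; can be
#' serialized to / read from JSON for the command-line interface.
#'
#' @return Named list with components `n_per_arm`, `duration_h`,
#'   `dropout_rate_per_day`, `cohort`, `scenario`, `controller`.
#' @export
default_config <- function() {
  strip <- function(x) { x <- unclass(x); x }
  list(n_per_arm = 12, duration_h = 48, dropout_rate_per_day = 1,
       cohort = strip(cohort_config()),
       scenario = strip(scenario_config()),
       controller = strip(controller_config()))
}

#' Load a trial configuration from JSON
#'
#' Missing fields fall back to [default_config()].
#'
#' @param path JSON file path, or `NULL` for the defaults.
#' @return Configuration list as in [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        base[[nm]] <- merge_in(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  merge_in(cfg, user)
}

## rebuild the classed config objects from a plain list
config_objects <- function(cfg) {
  list(cohort = do.call(cohort_config, cfg$cohort),
       scenario = do.call(scenario_config, cfg$scenario),
       controller = do.call(controller_config, cfg$controller))
}

#' Run a configured trial and write its outputs
#'
#' Convenience wrapper used by the command-line interface: runs
#' [run_trial()] under a configuration list, writes one trace CSV and one
#' command-log CSV per subject plus a JSON endpoint summary into
#' `out_dir`.
#'
#' @param cfg configuration list from [load_config()].
#' @param seed master seed.
#' @param out_dir output directory (created if missing).
#' @return The `trial_result`, invisibly.
#' @export
run_trial_to_dir <- function(cfg, seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- config_objects(cfg)
  res <- run_trial(n_per_arm = cfg$n_per_arm, seed = seed,
                   cohort_cfg = obj$cohort, scenario_cfg = obj$scenario,
                   control_config = obj$controller,
                   duration_h = cfg$duration_h,
                   dropout_rate_per_day = cfg$dropout_rate_per_day)
  for (rec in res$records) {
    write_trace_csv(rec, file.path(out_dir,
                                   sprintf("subject_%02d_trace.csv", rec$id)))
    write_command_csv(rec, file.path(out_dir,
                                     sprintf("subject_%02d_commands.csv",
                                             rec$id)))
  }
  jsonlite::write_json(
    list(per_subject = res$summary$per_subject,
         table = res$summary$table),
    file.path(out_dir, "summary.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(res)
}
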