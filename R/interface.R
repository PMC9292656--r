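#' Run configuration
#'
#' Gathers everything needed to reproduce a simulation run: input paths,
#' the layout (or plan) selector, replication count, master seed and the
#' behaviour/deferral/cost parameters. Serializable as YAML so a run is
#' fully described by one file plus the package version.
#'
#' @param schedule Path to a day-schedule file, or `NULL` to generate a
#'   calibrated synthetic day from the seed.
#' @param catalog Path to a process-time catalogue file, or `NULL` for
#'   the defaults.
#' @param layouts Character vector of layout names, or `"all"` for the
#'   full factorial set.
#' @param replications Replications per layout.
#' @param seed Master seed.
#' @param pfill,pns,p_cons_booked,p_cons_unbooked,p_hb,clerk_cost,
#'   nurse_cost,bed_cost Scalar parameter overrides.
#' @return Object of class `run_config`.
#' @export
run_config <- function(schedule = NULL, catalog = NULL, layouts = "all",
                       replications = 30L, seed = 1L,
                       pfill = 0.9, pns = 0.05,
                       p_cons_booked = 5.03e-3, p_cons_unbooked = 4.523e-2,
                       p_hb = 5e-3,
                       clerk_cost = 5, nurse_cost = 10, bed_cost = 1) {
  for (p in c(schedule, catalog))
    if (!is.null(p) && !file.exists(p))
      stop("file not found: ", p, call. = FALSE)
  structure(list(schedule = schedule, catalog = catalog, layouts = layouts,
                 replications = as.integer(replications),
                 seed = as.integer(seed),
                 pfill = pfill, pns = pns,
                 p_cons_booked = p_cons_booked,
                 p_cons_unbooked = p_cons_unbooked, p_hb = p_hb,
                 clerk_cost = clerk_cost, nurse_cost = nurse_cost,
                 bed_cost = bed_cost),
            class = "run_config")
}

#' Read or write a run configuration as YAML
#' @param path File path.
#' @param config A [run_config()].
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown run-config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(Filter(Negate(is.null), unclass(config)), path)
  invisible(path)
}

# materialise the model objects a config describes
config_parts <- function(config) {
  day <- if (is.null(config$schedule)) {
    set.seed(config$seed)
    baseline_day(behaviour_params(config$pfill, config$pns))
  } else read_day_schedule(config$schedule)
  catalog <- if (is.null(config$catalog)) process_time_catalog()
             else read_catalog(config$catalog)
  layouts <- if (identical(config$layouts, "all")) enumerate_layouts()
             else lapply(config$layouts, parse_layout_name)
  list(day = day, catalog = catalog, layouts = layouts,
       behaviour = behaviour_params(config$pfill, config$pns),
       rates = deferral_rates(config$p_cons_booked, config$p_cons_unbooked,
                              config$p_hb),
       costs = cost_model(config$clerk_cost, config$nurse_cost,
                          config$bed_cost))
}

#' Execute a configured plan and write its artifacts
#'
#' Runs the plan described by `config`, writing to `out_dir`: the
#' per-replication KPI table (`results.tsv`), the day schedule actually
#' used (`schedule.yaml`), and a JSON run manifest (`manifest.json`:
#' seed, configuration, input file checksums, package and R versions)
#' from which the run can be regenerated.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The [run_plan()] results, invisibly.
#' @export
execute_run <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  parts <- config_parts(config)
  plan <- experiment_plan(parts$layouts, config$replications, config$seed)
  results <- run_plan(plan, parts$day, parts$behaviour, parts$catalog,
                      parts$rates, parts$costs)
  utils::write.table(results, file.path(out_dir, "results.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_day_schedule(parts$day, file.path(out_dir, "schedule.yaml"))
  write_manifest(config, out_dir)
  invisible(results)
}

write_manifest <- function(config, out_dir) {
  checksum <- function(p) if (is.null(p)) NULL else unname(tools::md5sum(p))
  manifest <- list(
    seed = config$seed,
    config = Filter(Negate(is.null), unclass(config)),
    inputs = list(schedule_md5 = checksum(config$schedule),
                  catalog_md5 = checksum(config$catalog)),
    versions = list(R = R.version.string,
                    donorflow = as.character(utils::packageVersion("donorflow"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(out_dir, "manifest.json"))
}
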