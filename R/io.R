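# File I/O: two-column time-series CSV, scenario YAML files, and run
# output bundles.

#' Read a two-column numeric time-series CSV
#'
#' Expects a header and two numeric columns (time in seconds, value); time
#' must be strictly increasing. Sampling gaps larger than twice the median
#' spacing are reported as a warning.
#'
#' @param path CSV file
#' @return list with \code{times} and \code{values}
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("expected a two-column CSV with header",
                          call. = FALSE)
  tcol <- df[[1L]]
  vcol <- df[[2L]]
  if (!is.numeric(tcol) || !is.numeric(vcol)) {
    bad <- which(!grepl("^\\s*-?[0-9.eE+-]+\\s*$", as.character(df[[1L]])) |
                   !grepl("^\\s*-?[0-9.eE+-]+\\s*$", as.character(df[[2L]])))
    stop(sprintf("non-numeric cell near line %d of '%s'",
                 if (length(bad)) bad[1L] + 1L else 2L, path), call. = FALSE)
  }
  nonmono <- which(diff(tcol) <= 0)
  if (length(nonmono)) {
    stop(sprintf("time not strictly increasing at line %d of '%s'",
                 nonmono[1L] + 2L, path), call. = FALSE)
  }
  gaps <- diff(tcol)
  med <- stats::median(gaps)
  big <- which(gaps > 2 * med)
  if (length(big)) {
    warning(sprintf("%d sampling gap(s) exceed twice the median spacing",
                    length(big)), call. = FALSE)
  }
  list(times = tcol, values = vcol)
}

#' Write a two-column time-series CSV
#' @param times,values numeric vectors of equal length
#' @param path output file
#' @param names column names
#' @export
write_timeseries_csv <- function(times, values, path,
                                 names = c("time_s", "value")) {
  df <- data.frame(times, values)
  colnames(df) <- names
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an annotation CSV (start_s, duration_s, kind, [airflow_fraction])
#' @param path CSV file
#' @return data.frame of \code{\link{resp_event}} rows
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "duration_s", "kind")
  if (!all(need %in% names(df))) {
    stop(sprintf("annotation CSV must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    resp_event(df$kind[i], df$start_s[i], df$duration_s[i],
               airflow_fraction = if ("airflow_fraction" %in% names(df))
                 df$airflow_fraction[i] else NULL,
               V_T = if ("V_T" %in% names(df)) df$V_T[i] else NA_real_,
               b_r = if ("b_r" %in% names(df)) df$b_r[i] else NA_real_)
  }))
}

#' List the bundled breathing scenarios
#'
#' Scenario files reproduce the validation patterns (normal subject, severe
#' OSA) and the nine OSA study simulations.
#'
#' @return character vector of scenario names
#' @export
list_scenarios <- function() {
  dir_ <- system.file("extdata", "scenarios", package = "apneaox")
  sub("\\.yaml$", "", list.files(dir_, pattern = "\\.yaml$"))
}

#' Load a breathing scenario
#'
#' @param name a bundled scenario name (see \code{\link{list_scenarios}})
#'   or a path to a scenario YAML file. A scenario file holds the
#'   \code{\link{breathing_spec}} fields plus an \code{events} list of
#'   \code{\link{resp_event}} fields.
#' @return a \code{\link{breathing_spec}}
#' @export
load_scenario <- function(name) {
  path <- if (file.exists(name)) name else {
    system.file("extdata", "scenarios", paste0(name, ".yaml"),
                package = "apneaox")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop(sprintf("scenario '%s' not found; bundled: %s", name,
                 paste(list_scenarios(), collapse = ", ")), call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  events <- NULL
  if (!is.null(y$events)) {
    events <- do.call(rbind, lapply(y$events, function(e) {
      resp_event(e$kind, e$start, e$duration,
                 airflow_fraction = e$airflow_fraction,
                 V_T = if (is.null(e$V_T)) NA_real_ else e$V_T,
                 b_r = if (is.null(e$b_r)) NA_real_ else e$b_r)
    }))
  }
  breathing_spec(V_T = y$V_T, V_D = y$V_D, V_End = y$V_End, b_r = y$b_r,
                 events = events, total_duration = y$total_duration,
                 stabilization_time = if (is.null(y$stabilization_time)) 360
                 else y$stabilization_time)
}

#' Write a simulation output bundle
#'
#' Emits \code{timeseries.csv} (all compartment traces),
#' \code{events.csv}, \code{metrics.json} and \code{manifest.json} (run
#' configuration: parameters, solver settings, seed, package version) into
#' a directory.
#'
#' @param sim an \code{oxy_sim}
#' @param dir output directory (created if missing)
#' @param seed seed recorded in the manifest
#' @return the directory, invisibly
#' @export
write_sim_outputs <- function(sim, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- sim$series
  out <- data.frame(time_s = s$time, V_A_L = s$V_A, P_A_mmHg = s$P_A,
                    S_sa = s$S_sa, S_sv = s$S_sv,
                    C_sa_d_uM = s$C_sa_d * 1e6, C_sv_d_uM = s$C_sv_d * 1e6,
                    C_pa_T = s$C_pa_T, C_pv_T = s$C_pv_T)
  utils::write.csv(out, file.path(dir, "timeseries.csv"), row.names = FALSE)
  ev <- sim$events
  if (nrow(ev)) {
    utils::write.csv(
      data.frame(start_s = ev$start, duration_s = ev$duration,
                 kind = ev$kind, airflow_fraction = ev$airflow_fraction),
      file.path(dir, "events.csv"), row.names = FALSE)
  }
  m <- oxygen_metrics(sim)
  jsonlite::write_json(
    list(pct_decrease = m$pct_decrease,
         pct_reduction_mass_transfer = m$pct_reduction_mass_transfer,
         per_event = m$per_event),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  cfg <- write_params(sim$params)
  jsonlite::write_json(
    list(package = "apneaox",
         version = as.character(utils::packageVersion("apneaox")),
         seed = seed, dt = sim$dt, n_slices = sim$n_slices,
         params = cfg),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
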