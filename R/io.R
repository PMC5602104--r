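#' Read and write session event logs
#'
#' The on-disk event log is JSON-lines: one event per line with fields
#' `t_s` (seconds since experiment start), `animal_id`, `kind` and a
#' free-form string `payload` (semicolon-separated `key=value` pairs).
#' Reading validates per-animal time ordering; writing and re-reading is an
#' identity. A flat CSV export with the same columns is also provided.
#'
#' @param path File path.
#' @param events Data frame with columns `t_s`, `animal_id`, `kind`,
#'   `payload`.
#' @return `read_event_log()` returns the events data frame;
#'   writers return `path` invisibly.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(t_s = numeric(0), animal_id = character(0),
                      kind = character(0), payload = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop(sprintf("parse error at line %d of %s: %s",
                                   i, path, conditionMessage(e))))
    for (f in c("t_s", "animal_id", "kind"))
      if (is.null(rec[[f]]))
        stop(sprintf("parse error at line %d of %s: missing field '%s'",
                     i, path, f))
    data.frame(t_s = as.numeric(rec$t_s),
               animal_id = as.character(rec$animal_id),
               kind = as.character(rec$kind),
               payload = if (is.null(rec$payload)) "" else
                 as.character(rec$payload),
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  validate_event_order(ev, path)
  ev
}

#' @rdname read_event_log
#' @export
write_event_log <- function(events, path) {
  stopifnot(all(c("t_s", "animal_id", "kind") %in% names(events)))
  payload <- if ("payload" %in% names(events)) events$payload else
    rep("", nrow(events))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(list(t_s = events$t_s[i],
                                     animal_id = events$animal_id[i],
                                     kind = events$kind[i],
                                     payload = payload[i]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname read_event_log
#' @export
write_event_csv <- function(events, path) {
  payload <- if ("payload" %in% names(events)) events$payload else ""
  utils::write.csv(data.frame(t_s = events$t_s,
                              animal_id = events$animal_id,
                              kind = events$kind, payload = payload),
                   path, row.names = FALSE)
  invisible(path)
}

validate_event_order <- function(events, path = "<events>") {
  for (id in unique(events$animal_id)) {
    tt <- events$t_s[events$animal_id == id]
    if (is.unsorted(tt))
      stop("validation error: out-of-order events for animal ", id,
           " in ", path)
  }
  invisible(events)
}

#' Write and load a simulation output directory
#'
#' Persists a [simulate_cage()] result as the package's plain-text formats:
#' `events.jsonl`, one trace CSV per trial under `traces/`, a
#' `trials.csv` manifest mapping trial records to trace files, the
#' configuration as YAML, and a run manifest (JSON) recording the config
#' snapshot, seed, tool version, input checksums and timestamp.
#'
#' @param sim A `sim_output` from [simulate_cage()].
#' @param dir Output directory (created if needed).
#' @return `write_sim_output()` returns `dir` invisibly;
#'   `read_sim_output()` returns a list with `events`, `trials`, `traces`
#'   and `config`.
#' @export
write_sim_output <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_output"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  write_event_log(sim$events, file.path(dir, "events.jsonl"))
  trials <- sim$trials
  trials$trace_file <- ifelse(is.na(trials$trace_id), NA_character_,
                              file.path("traces",
                                        paste0(trials$trace_id, ".csv")))
  utils::write.csv(trials, file.path(dir, "trials.csv"), row.names = FALSE)
  for (tid in names(sim$traces)) {
    write_trace_csv(sim$traces[[tid]],
                    file.path(dir, "traces", paste0(tid, ".csv")))
  }
  # t0 of each trace lives in the manifest via trials.csv (t_init is the
  # initiation sample; trace files are relative to their own first sample)
  t0 <- vapply(sim$traces, function(tr) tr$t0, numeric(1))
  utils::write.csv(data.frame(trace_id = names(sim$traces), t0_s = t0),
                   file.path(dir, "trace_index.csv"), row.names = FALSE)
  write_task_config(sim$config, file.path(dir, "config.yaml"))
  write_run_manifest(dir, seed = sim$seed, config = sim$config)
  invisible(dir)
}

#' @rdname write_sim_output
#' @export
read_sim_output <- function(dir) {
  events <- read_event_log(file.path(dir, "events.jsonl"))
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  config <- read_task_config(file.path(dir, "config.yaml"))
  idx <- utils::read.csv(file.path(dir, "trace_index.csv"),
                         stringsAsFactors = FALSE)
  traces <- stats::setNames(
    lapply(seq_len(nrow(idx)), function(i)
      read_trace_csv(file.path(dir, "traces", paste0(idx$trace_id[i], ".csv")),
                     t0 = idx$t0_s[i])),
    idx$trace_id)
  list(events = events, trials = trials, traces = traces, config = config)
}

#' Run manifest
#'
#' Records what produced a run directory: tool version, seed, configuration
#' snapshot, MD5 checksums of the files present, and a timestamp.
#'
#' @param dir Run directory.
#' @param seed Seed used, if any.
#' @param config A [task_config()] or `NULL`.
#' @return Path of the manifest, invisibly.
#' @export
write_run_manifest <- function(dir, seed = NULL, config = NULL) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  sums <- as.list(tools::md5sum(file.path(dir, files)))
  names(sums) <- files
  man <- list(tool = "levercage",
              version = as.character(utils::packageVersion("levercage")),
              seed = seed,
              config = if (!is.null(config)) unclass(config),
              files = sums,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(file.path(dir, "manifest.json"))
}

#' Read and write agent profile files
#'
#' Profiles are stored as YAML: a list of records, each holding the
#' [agent_profile()] fields (at minimum `animal_id`; `preset` and any
#' overrides optional).
#'
#' @param path YAML file path.
#' @param profiles List of [agent_profile()] objects.
#' @return `read_profiles()` returns a list of `agent_profile` objects.
#' @export
read_profiles <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    if (!is.null(r$circadian_weights))
      r$circadian_weights <- as.numeric(r$circadian_weights)
    do.call(agent_profile, r)
  })
}

#' @rdname read_profiles
#' @export
write_profiles <- function(profiles, path) {
  yaml::write_yaml(lapply(profiles, unclass), path)
  invisible(path)
}
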