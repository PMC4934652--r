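#' @section File formats:
#' All tables are comma-separated UTF-8 with a header row and `.` decimals.
#' Tilt traces: one CSV per session with columns `trial_index`,
#' `sample_index` (0-based, 0 at fish onset), `tilt_deg`. Event logs and
#' ground-truth sidecars are JSON-lines, one record per trial. A run
#' manifest (JSON) lists the seed, configuration, and every file written.
#' @name tiltchron-io
NULL

#' Write / read a session's tilt traces
#'
#' @param traces Trace matrix (samples x trials, see [render_tilt_traces()])
#'   or long tibble with columns `trial_index`, `sample_index`, `tilt_deg`.
#' @param path CSV file path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns the long tibble.
#' @export
write_trace_csv <- function(traces, path) {
  if (is.matrix(traces)) traces <- traces_as_tibble(traces)
  readr::write_csv(traces[, c("trial_index", "sample_index", "tilt_deg")],
                   path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    trial_index = readr::col_integer(),
    sample_index = readr::col_integer(),
    tilt_deg = readr::col_double()
  ))
}

#' Write / read a session event log (JSON-lines)
#'
#' One record per trial with the trial specification and, when supplied, the
#' spawn time.
#'
#' @param plan A `session_plan`.
#' @param path Output path (`.jsonl`).
#' @param spawn_times Optional numeric vector of spawn times (seconds), one
#'   per trial (see [spawn_timeline()]).
#' @return `write_event_log()` returns `path` invisibly; `read_event_log()`
#'   returns a tibble.
#' @export
write_event_log <- function(plan, path, spawn_times = NULL) {
  df <- plan$trials
  if (!is.null(spawn_times)) {
    stopifnot(length(spawn_times) == nrow(df))
    df$spawn_time <- spawn_times
  }
  lines <- vapply(seq_len(nrow(df)), function(i) {
    jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, na = "null",
                     digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  purrr::map_dfr(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    rec[vapply(rec, is.null, logical(1))] <- NA
    tibble::as_tibble(rec)
  })
}

#' Write / read a ground-truth sidecar (JSON-lines)
#'
#' Latent per-trial ground truth from the simulator, stored separately from
#' the observable traces.
#'
#' @param latent Tibble from [sample_latent_trials()] (optionally with
#'   `subject_id`).
#' @param path Output path (`.jsonl`).
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns a tibble.
#' @export
write_ground_truth <- function(latent, path) {
  keep <- intersect(c("subject_id", "trial_index", "phase", "correct",
                      "decision_time", "movement_duration",
                      "response_direction", "missed"), names(latent))
  df <- latent[, keep]
  lines <- vapply(seq_len(nrow(df)), function(i) {
    jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, na = "null",
                     digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  read_event_log(path)
}

#' Read a session configuration file
#'
#' Accepts YAML (or its flat `key: value` subset); unknown keys are
#' rejected. Any field not present keeps its [session_config()] default.
#'
#' @param path Path to a YAML config file.
#' @return A [session_config()].
#' @export
read_session_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(session_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(paste0("Unknown config field(s): ", paste(bad, collapse = ", ")),
          class = "tiltchron_config_error")
  }
  do.call(session_config, vals)
}

#' Write a simulated cohort to disk
#'
#' Per subject: an event log (`subject_<id>_events.jsonl`) and a trace CSV
#' (`subject_<id>_traces.csv`, main phase). Cohort-wide: a subjects table
#' (`subjects.csv`), a ground-truth sidecar (`ground_truth.jsonl`), and a
#' run manifest (`manifest.json`).
#'
#' @param cohort A `cohort_sim`.
#' @param dir Output directory (created if missing).
#' @return The manifest, invisibly (a list).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (id in cohort$subjects$subject_id) {
    key <- as.character(id)
    ef <- file.path(dir, sprintf("subject_%03d_events.jsonl", id))
    tf <- file.path(dir, sprintf("subject_%03d_traces.csv", id))
    write_event_log(cohort$plans[[key]], ef)
    write_trace_csv(cohort$traces[[key]], tf)
    files <- c(files, ef, tf)
  }
  sf <- file.path(dir, "subjects.csv")
  readr::write_csv(cohort$subjects, sf)
  gf <- file.path(dir, "ground_truth.jsonl")
  write_ground_truth(cohort$latent, gf)
  files <- c(files, sf, gf)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tiltchron")),
    master_seed = cohort$master_seed,
    n_subjects = nrow(cohort$subjects),
    config = unclass(cohort$config),
    files = basename(files),
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort back from disk
#'
#' Reconstructs a `cohort_sim`-compatible object from a [write_cohort()]
#' directory (traces and plans; latent ground truth when present).
#'
#' @param dir Directory written by [write_cohort()].
#' @param config A [session_config()] matching the simulation (defaults
#'   to the manifest's, when available).
#' @return A list with `subjects`, `plans`, `traces`, `latent`, `config`.
#' @export
read_cohort <- function(dir, config = NULL) {
  man_path <- file.path(dir, "manifest.json")
  if (is.null(config) && file.exists(man_path)) {
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    config <- do.call(session_config, man$config)
  }
  config <- config %||% session_config()
  subjects <- readr::read_csv(file.path(dir, "subjects.csv"),
                              show_col_types = FALSE)
  plans <- list()
  traces <- list()
  for (id in subjects$subject_id) {
    key <- as.character(id)
    ev <- read_event_log(file.path(dir, sprintf("subject_%03d_events.jsonl",
                                                id)))
    plans[[key]] <- structure(list(config = config, trials = ev,
                                   seed = NA_integer_),
                              class = "session_plan")
    tr <- read_trace_csv(file.path(dir, sprintf("subject_%03d_traces.csv",
                                                id)))
    traces[[key]] <- traces_as_matrix(tr)
  }
  gt_path <- file.path(dir, "ground_truth.jsonl")
  latent <- if (file.exists(gt_path)) read_ground_truth(gt_path) else NULL
  list(subjects = subjects, plans = plans, traces = traces,
       latent = latent, config = config)
}

#' Validate cohort files
#'
#' Schema checks on the file dialects used by the package: trace CSVs must
#' have the three trace columns with equal-length, 0-based sample runs per
#' trial; JSON-lines files must parse per line; `subjects.csv` must contain
#' `subject_id` and `age`. Problems are reported, not raised.
#'
#' @param paths Character vector of file paths, or a directory.
#' @return A tibble with columns `file`, `ok`, `message`.
#' @export
validate_files <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, full.names = TRUE)
  }
  purrr::map_dfr(paths, function(p) {
    msg <- tryCatch({
      if (!file.exists(p)) return(tibble::tibble(file = p, ok = FALSE,
                                                 message = "file missing"))
      if (file.size(p) == 0) return(tibble::tibble(file = p, ok = FALSE,
                                                   message = "empty file"))
      if (grepl("traces\\.csv$", p)) {
        df <- readr::read_csv(p, show_col_types = FALSE,
                              progress = FALSE)
        need <- c("trial_index", "sample_index", "tilt_deg")
        if (!all(need %in% names(df))) {
          return(tibble::tibble(file = p, ok = FALSE,
                                message = "missing trace columns"))
        }
        if (!is.numeric(df$tilt_deg) || anyNA(df$tilt_deg)) {
          return(tibble::tibble(file = p, ok = FALSE,
                                message = "malformed tilt values"))
        }
        runs <- table(df$trial_index)
        if (length(unique(runs)) != 1L) {
          return(tibble::tibble(file = p, ok = FALSE,
                                message = "unequal samples per trial"))
        }
        if (min(df$sample_index) != 0L) {
          return(tibble::tibble(file = p, ok = FALSE,
                                message = "sample_index must start at 0"))
        }
      } else if (grepl("\\.jsonl$", p)) {
        lines <- readLines(p, warn = FALSE)
        bad <- which(!vapply(lines, function(l) {
          tryCatch({jsonlite::fromJSON(l); TRUE}, error = function(e) FALSE)
        }, logical(1)))
        if (length(bad)) {
          return(tibble::tibble(file = p, ok = FALSE,
                                message = paste("unparseable line(s):",
                                                paste(head(bad, 5),
                                                      collapse = ", "))))
        }
      } else if (grepl("subjects\\.csv$", p)) {
        df <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
        if (!all(c("subject_id", "age") %in% names(df))) {
          return(tibble::tibble(file = p, ok = FALSE,
                                message = "missing subject columns"))
        }
      }
      "ok"
    }, error = function(e) paste("read error:", conditionMessage(e)))
    if (is.data.frame(msg)) msg else tibble::tibble(file = p, ok = msg == "ok",
                                                    message = msg)
  })
}

#' Write a cohort report
#'
#' Serializes cohort statistics as JSON and, optionally, a human-readable
#' text table.
#'
#' @param stats A [cohort_stats()] object.
#' @param json_path Output JSON path.
#' @param text_path Optional text-summary path.
#' @return `json_path`, invisibly.
#' @export
write_cohort_report <- function(stats, json_path, text_path = NULL) {
  payload <- list(
    n_subjects = stats$n_subjects,
    n_missed_total = stats$n_missed_total,
    estimates = tidy(stats),
    mt_means_ms = stats$mt_means_ms,
    within_subject_sem = list(accuracy = stats$sem_accuracy,
                              rt_ms = stats$sem_rt_ms),
    quadrants = stats$quadrants
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "rows")
  if (!is.null(text_path)) {
    writeLines(utils::capture.output(print(stats)), text_path)
  }
  invisible(json_path)
}
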