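#' Write an entry-event log
#'
#' Serializes the `events` table of a participant log. JSON-lines (one
#' event object per line) is the canonical dialect; CSV carries the same
#' columns. Timestamps are float seconds since experiment start.
#'
#' @param log A `participant_log` (or a plain events data frame).
#' @param path Output file; the extension (`.jsonl`/`.csv`) picks the
#'   dialect unless `format` is given.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path)) "csv" else "jsonl"
  }
  events <- if (inherits(log, "participant_log")) log$events else log
  if (format == "csv") {
    utils::write.csv(events, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(events))) {
      writeLines(jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    }
  }
  invisible(path)
}

#' Read an entry-event log
#'
#' @param path A `.jsonl` or `.csv` event log written by
#'   [write_event_log()].
#' @return The events data frame.
#' @export
read_event_log <- function(path) {
  if (grepl("\\.csv$", path)) {
    ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    rows <- lapply(lines, function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
    ev <- do.call(rbind, rows)
  }
  required <- c("participant_id", "timestamp", "day_index", "daily_ordinal",
                "outcome", "phase")
  missing <- setdiff(required, names(ev))
  if (length(missing)) {
    stop(sprintf("event log %s lacks columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ev
}

#' Read a task configuration file
#'
#' YAML or JSON with the [task_config()] field names; unknown fields are
#' rejected with their paths, and defaults fill the rest.
#'
#' @param path Config file (`.yaml`/`.yml`/`.json`).
#' @return A validated `task_config`.
#' @export
read_task_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  legal <- names(formals(task_config))
  # day boundary may be given as day_boundary (clock hours) for convenience
  if ("day_boundary" %in% names(raw)) {
    raw$day_boundary_hour <- raw$day_boundary
    raw$day_boundary <- NULL
  }
  bad <- setdiff(names(raw), legal)
  if (length(bad)) {
    stop(sprintf("unknown config field(s): %s",
                 paste0("$", bad, collapse = ", ")), call. = FALSE)
  }
  do.call(task_config, raw)
}

#' Write a task configuration file
#'
#' @param config A [task_config()].
#' @param path Destination (`.yaml`/`.yml`/`.json`).
#' @return `path`, invisibly.
#' @export
write_task_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' Read a cohort specification file
#'
#' YAML/JSON with fields `n_per_group` (named list of group sizes), `seed`,
#' and optional `params` overrides forwarded to
#' [default_params_distribution()].
#'
#' @param path Spec file.
#' @return List with `n_per_group`, `seed` and `params_distribution`.
#' @export
read_cohort_spec <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
         else yaml::read_yaml(path)
  n_per_group <- unlist(raw$n_per_group)
  if (is.null(n_per_group)) {
    stop("cohort spec lacks $n_per_group", call. = FALSE)
  }
  dist_args <- raw$params %||% list()
  legal <- c(setdiff(names(formals(default_params_distribution)), "..."),
             names(formals(agent_params)))
  bad <- setdiff(names(dist_args), legal)
  if (length(bad)) {
    stop(sprintf("unknown cohort params field(s): %s",
                 paste0("$params$", bad, collapse = ", ")), call. = FALSE)
  }
  list(n_per_group = n_per_group,
       seed = raw$seed %||% 1L,
       params_distribution = do.call(default_params_distribution, dist_args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run manifest for a pipeline stage
#'
#' Records the configuration hash, master seed and input/output files of a
#' stage, so that identical manifests imply identical outputs.
#'
#' @param out_dir Directory whose files are hashed into the manifest.
#' @param config The configuration object used.
#' @param seed Master seed.
#' @param stage Stage label.
#' @return The manifest list (also written to `manifest.json` in
#'   `out_dir`).
#' @export
run_manifest <- function(out_dir, config, seed, stage = "simulate") {
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("freeoperant")),
    seed = seed,
    config_hash = unname(tools::md5sum(
      structure(write_config_tmp(config), names = NULL))),
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

write_config_tmp <- function(config) {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  tmp
}
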