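## File formats and session management: frame PNGs, data.txt traces,
## series CSVs, YAML run configs, and ISO-8601 session directories.

#' Write a process trace to data.txt
#'
#' Tab-separated columns `time_min  raw_percent  smoothed_percent` with a
#' header line, one row per frame, matching the monitoring program's
#' on-disk artifact.  If a stop was triggered, a final comment line
#' `# stop_time_min=<value>` records it.  Values are written with 17
#' significant digits so [read_data_txt()] round-trips them exactly.
#'
#' @param trace A [process_trace()].
#' @param path Output file path.
#' @param stop_time_min Stop time in minutes, or `NA`/`NULL` for none.
#' @return `path`, invisibly.
#' @export
write_data_txt <- function(trace, path, stop_time_min = NA) {
  stopifnot(inherits(trace, "process_trace"))
  num <- function(x) sprintf("%.17g", x)
  lines <- c("time_min\traw_percent\tsmoothed_percent",
             paste(num(trace$time_min), num(trace$raw_percent),
                   num(trace$smoothed_percent), sep = "\t"))
  if (!is.null(stop_time_min) && !is.na(stop_time_min))
    lines <- c(lines, sprintf("# stop_time_min=%.17g", stop_time_min))
  writeLines(lines, path)
  invisible(path)
}

#' Read a data.txt process trace
#'
#' Inverse of [write_data_txt()]; returns the trace plus any recorded
#' stop time.
#'
#' @param path File written by [write_data_txt()].
#' @return List with `trace` (a [process_trace()]) and `stop_time_min`
#'   (`NA` if no stop was recorded).
#' @export
read_data_txt <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1 || lines[1] != "time_min\traw_percent\tsmoothed_percent")
    stop("not a data.txt file: bad header in ", path)
  stop_time <- NA_real_
  is_comment <- startsWith(lines, "#")
  stop_lines <- lines[is_comment]
  if (length(stop_lines) > 0) {
    m <- regmatches(stop_lines[1], regexec("stop_time_min=([-0-9.eE+]+)", stop_lines[1]))[[1]]
    if (length(m) == 2) stop_time <- as.numeric(m[2])
  }
  body <- lines[-1][!is_comment[-1]]
  if (length(body) == 0) stop("data.txt has no data rows: ", path)
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  trace <- process_trace(as.numeric(parts[, 1]), as.numeric(parts[, 2]),
                         as.numeric(parts[, 3]))
  list(trace = trace, stop_time_min = stop_time)
}

#' Write a concentration series to CSV
#'
#' Columns `time_min,value,analyte,units` with header; the strict format
#' [read_series_csv()] validates.
#'
#' @param series A [concentration_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "concentration_series"))
  df <- data.frame(time_min = sprintf("%.17g", series$time_min),
                   value = sprintf("%.17g", series$value),
                   analyte = attr(series, "analyte"),
                   units = attr(series, "units"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a concentration series CSV
#'
#' Requires the exact header `time_min,value,analyte,units`; the analyte
#' column must be constant over the file.
#'
#' @param path File written by [write_series_csv()] (or hand-authored in
#'   the same format).
#' @return A [concentration_series()].
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_min", "value", "analyte", "units")
  if (!identical(names(df), required))
    stop("bad series CSV header in ", path, ": expected ",
         paste(required, collapse = ","))
  if (length(unique(df$analyte)) != 1)
    stop("series CSV mixes analytes: ", path)
  concentration_series(as.numeric(df$time_min), as.numeric(df$value),
                       analyte = df$analyte[1],
                       units = as.character(df$units[1]))
}

#' Write frames of a run as 8-bit grayscale PNGs
#'
#' Files are named `frame_<index>_<t_min>.png` inside `dir` (created if
#' needed), index starting at 0 in time order.
#'
#' @param series A `frame_series` from [simulate_discoloration_run()],
#'   or a list of `decell_frame`s.
#' @param dir Output directory.
#' @return Character vector of file paths, invisibly.
#' @export
write_frames <- function(series, dir) {
  frames <- if (inherits(series, "frame_series")) series$frames else series
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    path <- file.path(dir, sprintf("frame_%04d_%g.png", i - 1L, f$timestamp_min))
    png::writePNG(f$pixels / 255, path)
    path
  }, character(1))
  invisible(paths)
}

#' Read a directory of frame PNGs
#'
#' Reads `frame_<index>_<t_min>.png` files back into a time-ordered list
#' of `decell_frame`s, timestamps parsed from the file names.
#'
#' @param dir Directory written by [write_frames()].
#' @return List of `decell_frame`s in time order.
#' @export
read_frames <- function(dir) {
  files <- list.files(dir, pattern = "^frame_[0-9]+_.*\\.png$", full.names = TRUE)
  if (length(files) == 0) stop("no frame PNGs found in ", dir)
  t_min <- as.numeric(sub("^frame_[0-9]+_(.*)\\.png$", "\\1", basename(files)))
  ord <- order(t_min)
  lapply(ord, function(i) {
    arr <- png::readPNG(files[i])
    if (length(dim(arr)) == 3L) arr <- arr[, , 2L]  # green channel
    px <- round(arr * 255)
    storage.mode(px) <- "integer"
    new_frame(px, t_min[i])
  })
}

run_config_defaults <- function() {
  list(time_get_photo = list(value = 5, unit = "min"),
       stop_time_n = 10L,
       k_percent = 3.0,
       smoothing_sigma = 2.0,
       flow_rate_mL_per_h = 50,
       seed = 1L,
       output_dir = ".")
}

#' Assemble and validate a run configuration
#'
#' Central knobs of a monitored run.  The frame interval carries an
#' explicit unit tag (`"s"` or `"min"`) because both 10-second and
#' 5-minute acquisition schedules are in routine use; it is converted to
#' minutes internally (`interval_min` in the result).
#'
#' @param time_get_photo List `list(value =, unit = "s"|"min")`, or a
#'   string like `"10 s"` / `"5 min"`.
#' @param stop_time_n Stopping-rule window (default 10).
#' @param k_percent Stopping-rule tolerance in percent (default 3).
#' @param smoothing_sigma Gaussian sigma in samples (default 2).
#' @param flow_rate_mL_per_h Pump flow (default 50).
#' @param seed Master seed; every random stage derives from it.
#' @param output_dir Where sessions are created.
#' @return An object of class `run_config` (list incl. derived
#'   `interval_min`).
#' @export
run_config <- function(time_get_photo = list(value = 5, unit = "min"),
                       stop_time_n = 10L, k_percent = 3.0,
                       smoothing_sigma = 2.0, flow_rate_mL_per_h = 50,
                       seed = 1L, output_dir = ".") {
  if (is.character(time_get_photo)) {
    parts <- strsplit(trimws(time_get_photo), "\\s+")[[1]]
    if (length(parts) != 2)
      stop("time_get_photo string must look like '10 s' or '5 min'")
    time_get_photo <- list(value = as.numeric(parts[1]), unit = parts[2])
  }
  if (!is.list(time_get_photo) ||
      !all(c("value", "unit") %in% names(time_get_photo)))
    stop("time_get_photo needs 'value' and an explicit 'unit' tag")
  if (!time_get_photo$unit %in% c("s", "min"))
    stop("time_get_photo unit must be 's' or 'min'")
  problems <- character(0)
  if (!is.numeric(time_get_photo$value) || time_get_photo$value <= 0)
    problems <- c(problems, "time_get_photo$value must be > 0")
  if (stop_time_n < 2) problems <- c(problems, "stop_time_n must be >= 2")
  if (k_percent <= 0) problems <- c(problems, "k_percent must be > 0")
  if (smoothing_sigma <= 0) problems <- c(problems, "smoothing_sigma must be > 0")
  if (flow_rate_mL_per_h <= 0) problems <- c(problems, "flow_rate_mL_per_h must be > 0")
  if (length(problems) > 0)
    stop("invalid run configuration: ", paste(problems, collapse = "; "))
  interval_min <- if (time_get_photo$unit == "s")
    time_get_photo$value / 60 else time_get_photo$value
  structure(list(time_get_photo = time_get_photo,
                 stop_time_n = as.integer(stop_time_n),
                 k_percent = k_percent,
                 smoothing_sigma = smoothing_sigma,
                 flow_rate_mL_per_h = flow_rate_mL_per_h,
                 seed = as.integer(seed),
                 output_dir = output_dir,
                 interval_min = interval_min),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Missing keys take the defaults (window 10, k 3%, flow 50 mL/h, 5-min
#' frames); unknown keys are rejected so a typo never silently falls
#' back to a default.
#'
#' @param path YAML file; an empty file yields the full default config.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(run_config_defaults())
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  args <- utils::modifyList(run_config_defaults(), raw)
  do.call(run_config, args)
}

#' Save a run configuration as YAML
#'
#' Inverse of [load_config()]; loading the saved file reproduces the
#' configuration exactly.
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  keep <- setdiff(names(unclass(config)), "interval_min")
  yaml::write_yaml(unclass(config)[keep], path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "Run config: frames every %g %s, window %d, k %g%%, sigma %g, flow %g mL/h, seed %d\n",
    x$time_get_photo$value, x$time_get_photo$unit, x$stop_time_n,
    x$k_percent, x$smoothing_sigma, x$flow_rate_mL_per_h, x$seed))
  invisible(x)
}

#' Create a session directory with manifest and log
#'
#' Makes an ISO-8601-UTC-named directory under the config's
#' `output_dir`, with `frames/`, `traces/` and `plots/` subdirectories,
#' a `manifest.json` (creation time, config snapshot, empty file
#' inventory, tool version) written before any result file, and a
#' `session.log` opened with the full config snapshot.  An existing
#' directory is never reused: collisions get `-1`, `-2`, ... suffixes.
#'
#' @param config A [run_config()].
#' @param name Optional directory name; default the current UTC time.
#' @return An object of class `decell_session`: list with `dir`,
#'   `manifest_path`, `log_path` and the `config`.
#' @export
create_session <- function(config, name = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(name))
    name <- format(Sys.time(), "%Y-%m-%dT%H%M%SZ", tz = "UTC")
  base <- file.path(config$output_dir, name)
  dir <- base
  i <- 0L
  while (dir.exists(dir)) {
    i <- i + 1L
    dir <- paste0(base, "-", i)
  }
  dir.create(dir, recursive = TRUE)
  for (sub in c("frames", "traces", "plots"))
    dir.create(file.path(dir, sub))
  manifest <- list(created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   config = unclass(config),
                   files = list(),
                   tool_version = as.character(utils::packageVersion("decellmon")))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  log_path <- file.path(dir, "session.log")
  session <- structure(list(dir = dir, manifest_path = manifest_path,
                            log_path = log_path, config = config),
                       class = "decell_session")
  session_log(session, paste0("session created: ", dir))
  session_log(session, paste0("tool version: ", manifest$tool_version))
  session_log(session, paste0("config: ",
                              jsonlite::toJSON(unclass(config), auto_unbox = TRUE)))
  session_log(session, paste0("seed: ", config$seed))
  session
}

#' Append a line to the session log
#'
#' @param session A `decell_session`.
#' @param message Log line.
#' @return The session, invisibly.
#' @export
session_log <- function(session, message) {
  stopifnot(inherits(session, "decell_session"))
  stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  cat(sprintf("[%s] %s\n", stamp, message), file = session$log_path,
      append = TRUE)
  invisible(session)
}

#' Register a result file in the session manifest
#'
#' @param session A `decell_session`.
#' @param path File path (inside the session directory).
#' @param role Short description of the file's role.
#' @return The session, invisibly.
#' @export
add_session_file <- function(session, path, role = "") {
  stopifnot(inherits(session, "decell_session"))
  manifest <- jsonlite::read_json(session$manifest_path)
  rel <- sub(paste0("^", session$dir, "/?"), "", path)
  manifest$files[[length(manifest$files) + 1L]] <-
    list(path = rel, role = role)
  jsonlite::write_json(manifest, session$manifest_path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(session)
}

#' @export
print.decell_session <- function(x, ...) {
  cat("Session:", x$dir, "\n")
  invisible(x)
}
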