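# File-format plumbing: the CSV/JSON dialects shared by the interfaces,
# the simulator and the scorer. All CSVs are comma-separated with a header
# row and '.' decimal point; JSON numbers keep full precision.

check_columns <- function(df, cols, what) {
  if (!all(cols %in% names(df))) {
    hf_stop(sprintf("%s needs columns %s", what, paste(cols, collapse = ", ")),
            "hf_shape_error")
  }
  df
}

#' Read / write accelerometer traces (`t,ax,ay,az`; seconds, g)
#'
#' @param path file path.
#' @return `read_accel_csv`: a data frame with columns `t`, `ax`, `ay`,
#'   `az`.
#' @export
read_accel_csv <- function(path) {
  check_columns(utils::read.csv(path), c("t", "ax", "ay", "az"),
                "accelerometer CSV")
}

#' @rdname read_accel_csv
#' @param trace data frame with columns `t`, `ax`, `ay`, `az`.
#' @export
write_accel_csv <- function(trace, path) {
  check_columns(trace, c("t", "ax", "ay", "az"), "accelerometer trace")
  utils::write.csv(trace[, c("t", "ax", "ay", "az")], path, row.names = FALSE)
  invisible(path)
}

#' Read / write control-voltage traces (`t,vx,vy`; seconds, volts)
#'
#' @param path file path.
#' @return `read_voltage_csv`: a data frame with columns `t`, `vx`, `vy`.
#' @export
read_voltage_csv <- function(path) {
  check_columns(utils::read.csv(path), c("t", "vx", "vy"), "voltage CSV")
}

#' @rdname read_voltage_csv
#' @param trace data frame with columns `t`, `vx`, `vy`.
#' @export
write_voltage_csv <- function(trace, path) {
  check_columns(trace, c("t", "vx", "vy"), "voltage trace")
  utils::write.csv(trace[, c("t", "vx", "vy")], path, row.names = FALSE)
  invisible(path)
}

#' Read / write two-channel IR-oculography traces
#' (`t,ch_left,ch_right`; seconds, volts)
#'
#' @param path file path.
#' @return `read_ir_trace_csv`: a data frame with columns `t`, `ch_left`,
#'   `ch_right`.
#' @export
read_ir_trace_csv <- function(path) {
  check_columns(utils::read.csv(path), c("t", "ch_left", "ch_right"),
                "IR trace CSV")
}

#' @rdname read_ir_trace_csv
#' @param trace data frame with columns `t`, `ch_left`, `ch_right`.
#' @export
write_ir_trace_csv <- function(trace, path) {
  check_columns(trace, c("t", "ch_left", "ch_right"), "IR trace")
  utils::write.csv(trace[, c("t", "ch_left", "ch_right")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a gesture window as an IR trace CSV
#'
#' @param window a [gesture_window()].
#' @param path output path.
#' @param fs sampling rate used for the time column, Hz.
#' @return `path`, invisibly.
#' @export
write_gesture_window_csv <- function(window, path, fs = 50) {
  stopifnot(inherits(window, "gesture_window"))
  write_ir_trace_csv(data.frame(
    t = (seq_len(window$window_len) - 1) / fs,
    ch_left = window$left_channel,
    ch_right = window$right_channel), path)
}

#' Write / read a labelled gesture dataset as a directory of CSVs
#'
#' The directory holds one IR-trace CSV per window plus a `manifest.csv`
#' mapping `file` to `label`.
#'
#' @param windows list of labelled [gesture_window()] objects.
#' @param dir dataset directory (created if needed).
#' @param fs sampling rate, Hz.
#' @return the directory (write) or the list of windows (read), invisibly /
#'   directly.
#' @export
write_gesture_dataset <- function(windows, dir, fs = 50) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("window_%04d.csv", seq_along(windows))
  labels <- vapply(windows, function(w) w$label %||% NA_character_,
                   character(1))
  for (i in seq_along(windows)) {
    write_gesture_window_csv(windows[[i]], file.path(dir, files[i]), fs = fs)
  }
  utils::write.csv(data.frame(file = files, label = labels),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_gesture_dataset
#' @export
read_gesture_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    hf_stop(sprintf("no manifest.csv in '%s'", dir), "hf_shape_error")
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  check_columns(manifest, c("file", "label"), "dataset manifest")
  lapply(seq_len(nrow(manifest)), function(i) {
    tr <- read_ir_trace_csv(file.path(dir, manifest$file[i]))
    gesture_window(tr$ch_left, tr$ch_right, label = manifest$label[i],
                   window_len = nrow(tr))
  })
}

#' Read / write voice token streams
#'
#' JSON-lines (`{"t": <seconds>, "word": "<token>"}` per line, files ending
#' in `.jsonl` or `.json`) or plain text with one token per line (tokens
#' then get unit-spaced timestamps).
#'
#' @param path file path.
#' @return `read_tokens`: a data frame with columns `t`, `word`.
#' @export
read_tokens <- function(path) {
  if (grepl("\\.jsonl?$", path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      return(data.frame(t = numeric(0), word = character(0)))
    }
    recs <- lapply(lines, jsonlite::fromJSON)
    data.frame(t = vapply(recs, function(r) as.numeric(r$t), numeric(1)),
               word = vapply(recs, function(r) as.character(r$word),
                             character(1)))
  } else {
    words <- trimws(readLines(path, warn = FALSE))
    words <- words[nzchar(words)]
    data.frame(t = seq_along(words) - 1, word = words)
  }
}

#' @rdname read_tokens
#' @param tokens data frame with columns `t`, `word`.
#' @export
write_tokens <- function(tokens, path) {
  check_columns(tokens, c("t", "word"), "token stream")
  lines <- vapply(seq_len(nrow(tokens)), function(i) {
    jsonlite::toJSON(list(t = tokens$t[i], word = tokens$word[i]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write simulation courses as JSON
#'
#' A course is a start pose, an integration step, and a set of circular
#' obstacles.
#'
#' @param path file path.
#' @return `read_course_json`: a list with `start` (x, y, heading), `dt`
#'   and `obstacles` (data frame `x`, `y`, `radius`).
#' @export
read_course_json <- function(path) {
  course <- jsonlite::read_json(path, simplifyVector = TRUE)
  obstacles <- course$obstacles
  if (is.null(obstacles) || length(obstacles) == 0) {
    obstacles <- data.frame(x = numeric(0), y = numeric(0),
                            radius = numeric(0))
  }
  obstacles <- as.data.frame(obstacles)
  if (nrow(obstacles) > 0) {
    check_columns(obstacles, c("x", "y", "radius"), "course obstacles")
    if (any(obstacles$radius <= 0)) {
      hf_stop("obstacle radii must be positive", "hf_validation_error")
    }
  }
  list(start = as.list(course$start %||% list(x = 0, y = 0, heading = 0)),
       dt = course$dt %||% 0.1,
       obstacles = obstacles)
}

#' @rdname read_course_json
#' @param course a course list (`start`, `dt`, `obstacles`).
#' @export
write_course_json <- function(course, path) {
  jsonlite::write_json(
    list(start = course$start %||% list(x = 0, y = 0, heading = 0),
         dt = course$dt %||% 0.1,
         obstacles = course$obstacles %||%
           data.frame(x = numeric(0), y = numeric(0), radius = numeric(0))),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read / write trajectory traces (`t,x,y,heading,v,omega`)
#'
#' @param path file path.
#' @return `read_trajectory_csv`: a data frame.
#' @export
read_trajectory_csv <- function(path) {
  check_columns(utils::read.csv(path),
                c("t", "x", "y", "heading", "v", "omega"), "trajectory CSV")
}

#' @rdname read_trajectory_csv
#' @param trace trajectory data frame.
#' @export
write_trajectory_csv <- function(trace, path) {
  check_columns(trace, c("t", "x", "y", "heading", "v", "omega"),
                "trajectory trace")
  utils::write.csv(trace[, c("t", "x", "y", "heading", "v", "omega")],
                   path, row.names = FALSE)
  invisible(path)
}
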