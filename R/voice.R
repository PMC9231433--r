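# Voice-command grammar: eight words split into "attention" commands that
# arm a motion mode (stop / move / go / run) and "orientation" commands that
# pick the direction (forward / backward / left / right). An attention word
# must precede its orientation word; "move" drives for 1 s, "go" for 2 s,
# "run" continuously until another command arrives, and "stop" halts
# everything.

ATTENTION_WORDS <- c("stop", "move", "go", "run")
ORIENTATION_WORDS <- c("forward", "backward", "left", "right")

#' The eight-word voice vocabulary
#'
#' @return a list with elements `attention` and `orientation`.
#' @export
voice_vocabulary <- function() {
  list(attention = ATTENTION_WORDS, orientation = ORIENTATION_WORDS)
}

# Motion mode armed by each (non-stop) attention word.
attention_mode <- function(word) {
  switch(word,
         move = list(mode = "timed", duration_s = 1),
         go   = list(mode = "timed", duration_s = 2),
         run  = list(mode = "continuous", duration_s = NA_real_))
}

#' Parse a raw voice token
#'
#' Case-insensitive, whitespace-trimmed match against the eight-word
#' vocabulary. Out-of-vocabulary words raise an error, modelling the
#' recognizer rejecting an utterance.
#'
#' @param text raw recognizer output.
#' @return a list with `word` (normalized) and `category`
#'   (`"attention"` or `"orientation"`).
#' @export
#' @examples
#' parse_voice_token("RUN ")
#' parse_voice_token("left")
parse_voice_token <- function(text) {
  word <- tolower(trimws(text))
  if (word %in% ATTENTION_WORDS) {
    list(word = word, category = "attention")
  } else if (word %in% ORIENTATION_WORDS) {
    list(word = word, category = "orientation")
  } else {
    hf_stop(sprintf("unrecognized voice token '%s'", text),
            "hf_vocabulary_error")
  }
}

#' A semantic drive command
#'
#' @param direction one of forward/backward/left/right, or `"stop"` for the
#'   halt command.
#' @param mode `"timed"`, `"continuous"`, or `"halt"` (stop only).
#' @param duration_s 1 or 2 seconds when timed; `NA` otherwise.
#' @return a `drive_command` object.
#' @export
drive_command <- function(direction,
                          mode = c("timed", "continuous", "halt"),
                          duration_s = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "halt") {
    if (direction != "stop") {
      hf_stop("halt mode is reserved for the stop command",
              "hf_validation_error")
    }
  } else if (!(direction %in% ORIENTATION_WORDS)) {
    hf_stop(sprintf("unknown drive direction '%s'", direction),
            "hf_vocabulary_error")
  }
  if (mode == "timed" && !(isTRUE(duration_s == 1) || isTRUE(duration_s == 2))) {
    hf_stop("timed commands last 1 or 2 seconds", "hf_validation_error")
  }
  if (mode != "timed") duration_s <- NA_real_
  structure(list(direction = direction, mode = mode,
                 duration_s = duration_s),
            class = "drive_command")
}

#' @export
print.drive_command <- function(x, ...) {
  cat(switch(x$mode,
             halt = "Drive command: stop\n",
             timed = sprintf("Drive command: %s for %g s\n",
                             x$direction, x$duration_s),
             continuous = sprintf("Drive command: %s, continuous\n",
                                  x$direction)))
  invisible(x)
}

#' Initial grammar state
#'
#' @return a `grammar_state` object with no pending attention word, no
#'   active command, and the halted flag set (the chair waits for an
#'   attention command).
#' @export
grammar_state <- function() {
  structure(list(pending_attention = NULL, active_command = NULL,
                 halted = TRUE),
            class = "grammar_state")
}

#' Advance the voice grammar by one token
#'
#' Semantics: `stop` clears the pending attention word and any active
#' command and emits the halt command; another attention word replaces any
#' pending one (letting the user correct themselves); an orientation word
#' with a pending attention emits a [drive_command()] carrying the
#' attention's mode and duration; an orientation word with nothing pending
#' is silently ignored, so spurious recognizer output cannot move the chair.
#'
#' @param state a [grammar_state()].
#' @param token a parsed token from [parse_voice_token()], or raw text.
#' @return a list with the new `state` and `command` (a [drive_command()]
#'   or `NULL`).
#' @export
#' @examples
#' st <- grammar_step(grammar_state(), "go")$state
#' grammar_step(st, "right")$command   # right, timed, 2 s
grammar_step <- function(state, token) {
  stopifnot(inherits(state, "grammar_state"))
  if (is.character(token)) token <- parse_voice_token(token)
  command <- NULL
  if (token$word == "stop") {
    state$pending_attention <- NULL
    state$active_command <- NULL
    state$halted <- TRUE
    command <- drive_command("stop", "halt")
  } else if (token$category == "attention") {
    state$pending_attention <- token$word
  } else if (!is.null(state$pending_attention)) {
    armed <- attention_mode(state$pending_attention)
    command <- drive_command(token$word, armed$mode, armed$duration_s)
    state$pending_attention <- NULL
    state$active_command <- command   # supersedes any previous command
    state$halted <- FALSE
  }
  list(state = state, command = command)
}

#' Run a timed voice session over a token stream
#'
#' Folds [grammar_step()] over a time-ordered token stream and produces the
#' activation timeline: timed commands deactivate after their duration,
#' continuous commands run until superseded or stopped, and any newly
#' emitted command supersedes the one currently active.
#'
#' @param tokens data frame with columns `t` (seconds, nondecreasing) and
#'   `word`.
#' @return a data frame with columns `direction`, `mode`, `duration_s`,
#'   `t_on`, `t_off`. `t_off` is `NA` for a command still active when the
#'   stream ends.
#' @export
#' @examples
#' run_voice_session(data.frame(t = c(0, 1), word = c("move", "right")))
run_voice_session <- function(tokens) {
  if (!all(c("t", "word") %in% names(tokens))) {
    hf_stop("token stream needs columns t, word", "hf_shape_error")
  }
  if (nrow(tokens) > 1 && any(diff(tokens$t) < 0)) {
    hf_stop("token timestamps must be nondecreasing", "hf_order_error")
  }
  state <- grammar_state()
  rows <- list()
  active <- NULL    # list(i = row index, end = scheduled end time or Inf)

  close_active <- function(at) {
    if (!is.null(active)) {
      rows[[active$i]]$t_off <<- at
      active <<- NULL
    }
  }

  for (k in seq_len(nrow(tokens))) {
    t_k <- tokens$t[k]
    if (!is.null(active) && active$end <= t_k) close_active(active$end)
    step <- grammar_step(state, as.character(tokens$word[k]))
    state <- step$state
    cmd <- step$command
    if (is.null(cmd)) next
    if (cmd$mode == "halt") {
      close_active(t_k)
    } else {
      close_active(t_k)
      rows[[length(rows) + 1]] <- data.frame(
        direction = cmd$direction, mode = cmd$mode,
        duration_s = cmd$duration_s, t_on = t_k, t_off = NA_real_)
      active <- list(i = length(rows),
                     end = if (cmd$mode == "timed") t_k + cmd$duration_s
                           else Inf)
    }
  }
  if (!is.null(active)) {
    close_active(if (is.finite(active$end)) active$end else NA_real_)
  }
  if (length(rows) == 0) {
    return(data.frame(direction = character(0), mode = character(0),
                      duration_s = numeric(0), t_on = numeric(0),
                      t_off = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
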