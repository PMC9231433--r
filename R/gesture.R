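# Eye-gesture windows: the fixed-length two-channel classification unit
# (1.5 s at 50 Hz = 75 samples per channel), conditioning, feature
# extraction, and the gesture-pair command decoder.

GESTURE_LABELS <- c("open", "close", "left", "right")

#' The fixed gesture label order
#'
#' Order used for classifier outputs, tie-breaking and model serialization.
#'
#' @return `c("open", "close", "left", "right")`.
#' @export
gesture_labels <- function() GESTURE_LABELS

#' Construct a two-channel gesture window
#'
#' A `gesture_window` holds one classification unit: `window_len` samples
#' from each infrared sensor channel (left and right eye), optionally with
#' a known gesture label.
#'
#' @param left_channel,right_channel numeric vectors of exactly `window_len`
#'   samples (volts).
#' @param label optional gesture label in [gesture_labels()].
#' @param window_len expected samples per channel; the default 75 is 1.5 s
#'   at the 50 Hz sampling rate.
#' @return a `gesture_window` object.
#' @export
gesture_window <- function(left_channel, right_channel, label = NULL,
                           window_len = 75) {
  if (length(left_channel) != window_len ||
      length(right_channel) != window_len) {
    hf_stop(sprintf("both channels must hold exactly %d samples (got %d, %d)",
                    window_len, length(left_channel), length(right_channel)),
            "hf_shape_error")
  }
  if (!is.null(label) && !(label %in% GESTURE_LABELS)) {
    hf_stop(sprintf("unknown gesture label '%s'", label),
            "hf_vocabulary_error")
  }
  structure(
    list(left_channel = as.numeric(left_channel),
         right_channel = as.numeric(right_channel),
         label = label, window_len = window_len),
    class = "gesture_window"
  )
}

#' @export
print.gesture_window <- function(x, ...) {
  cat(sprintf("Gesture window: %d samples/channel%s\n", x$window_len,
              if (is.null(x$label)) "" else sprintf(", label '%s'", x$label)))
  invisible(x)
}

#' Condition raw IR traces and assemble a gesture window
#'
#' Each channel is passed through the exponential moving average and then
#' the DC blocker (smoothing first, baseline removal second), keeping the
#' two channels separate.
#'
#' @param left,right raw channel samples, exactly `window_len` each.
#' @param ema an [ema_params()] object.
#' @param dcb a [dc_blocker_params()] object.
#' @param label optional gesture label to carry through.
#' @param window_len samples per channel (default 75).
#' @return a filtered [gesture_window()].
#' @export
condition_and_window <- function(left, right,
                                 ema = ema_params(),
                                 dcb = dc_blocker_params(),
                                 label = NULL, window_len = 75) {
  if (length(left) != length(right)) {
    hf_stop("channel length mismatch", "hf_shape_error")
  }
  if (length(left) != window_len) {
    hf_stop(sprintf("expected %d samples per channel, got %d",
                    window_len, length(left)), "hf_shape_error")
  }
  gesture_window(
    dc_blocker(ema_filter(left, ema), dcb),
    dc_blocker(ema_filter(right, ema), dcb),
    label = label, window_len = window_len
  )
}

#' Flatten a gesture window into the classifier feature vector
#'
#' Concatenates the filtered samples, left channel first, giving a vector of
#' length `2 * window_len` (150 by default).
#'
#' @param window a [gesture_window()].
#' @return numeric feature vector.
#' @export
window_to_features <- function(window) {
  stopifnot(inherits(window, "gesture_window"))
  c(window$left_channel, window$right_channel)
}

#' Map an ordered gesture pair to a drive action
#'
#' Exactly four pairs command the chair: (left, left) turns left,
#' (right, right) turns right, (right, close) drives forward and
#' (left, close) drives backward. Every other ordered pair is a deliberate
#' no-op, so stray classifications cannot move the chair.
#'
#' @param first,second gesture labels from [gesture_labels()].
#' @return one of `"left"`, `"right"`, `"forward"`, `"backward"`, or
#'   `NA_character_` for a non-command pair.
#' @export
#' @examples
#' gesture_pair_action("left", "left")    # "left"
#' gesture_pair_action("right", "close")  # "forward"
#' gesture_pair_action("open", "open")    # NA: not a command
gesture_pair_action <- function(first, second) {
  for (lab in c(first, second)) {
    if (!(lab %in% GESTURE_LABELS)) {
      hf_stop(sprintf("unknown gesture label '%s'", lab),
              "hf_vocabulary_error")
    }
  }
  switch(paste(first, second),
         "left left"   = "left",
         "right right" = "right",
         "right close" = "forward",
         "left close"  = "backward",
         NA_character_)
}

#' Decode a stream of classified gestures into drive actions
#'
#' Consecutive classified windows form ordered pairs; the four command pairs
#' of [gesture_pair_action()] emit actions, any other pair resets without
#' acting. Idle windows (`NA` entries, windows in which no gesture was
#' classified) are tolerated between the two gestures of a pair up to
#' `timeout_windows`; beyond that the pending gesture expires.
#'
#' @param labels character vector of gesture labels, with `NA` marking idle
#'   windows.
#' @param timeout_windows maximum number of idle windows allowed between the
#'   two gestures of a pair.
#' @return a data frame with columns `window` (index of the completing
#'   gesture) and `action`.
#' @export
#' @examples
#' decode_gesture_sequence(c("left", "left", "right", "close"))
decode_gesture_sequence <- function(labels, timeout_windows = 3) {
  stopifnot(is_scalar_number(timeout_windows), timeout_windows >= 0)
  known <- is.na(labels) | labels %in% GESTURE_LABELS
  if (!all(known)) {
    hf_stop(sprintf("unknown gesture label '%s'", labels[!known][1]),
            "hf_vocabulary_error")
  }
  pending <- NA_character_
  idle <- 0L
  out_window <- integer(0)
  out_action <- character(0)
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (is.na(lab)) {
      idle <- idle + 1L
      if (idle > timeout_windows) pending <- NA_character_
      next
    }
    if (is.na(pending)) {
      pending <- lab
      idle <- 0L
    } else {
      act <- gesture_pair_action(pending, lab)
      if (!is.na(act)) {
        out_window <- c(out_window, i)
        out_action <- c(out_action, act)
      }
      pending <- NA_character_
      idle <- 0L
    }
  }
  data.frame(window = out_window, action = out_action)
}

#' Segment a long two-channel trace into gesture windows
#'
#' Splits a trace into consecutive non-overlapping windows of `window_len`
#' samples; a trailing partial window is dropped.
#'
#' @param left,right full-length channel samples.
#' @param window_len samples per window (default 75).
#' @return a list of unlabelled sample pairs
#'   (`list(left = ..., right = ...)`), one per window.
#' @export
segment_trace <- function(left, right, window_len = 75) {
  if (length(left) != length(right)) {
    hf_stop("channel length mismatch", "hf_shape_error")
  }
  n_win <- length(left) %/% window_len
  lapply(seq_len(n_win), function(k) {
    idx <- ((k - 1) * window_len + 1):(k * window_len)
    list(left = left[idx], right = right[idx])
  })
}
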