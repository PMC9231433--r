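# Seed-reproducible synthetic signal generators for all three input
# channels: static-gravity accelerometer traces for scripted head motions,
# two-channel infrared-oculography gesture waveforms, and noisy voice token
# streams. These stand in for the hardware so the whole pipeline can be
# exercised and tested without sensors.

#' Script a sequence of head poses
#'
#' @param segments data frame with columns `duration_s`, `theta_x`,
#'   `theta_y` (target inclination angles in degrees, each in
#'   \[-90, +90\]). Each segment holds its target pose for its duration,
#'   with a 0.2 s linear ramp from the previous pose.
#' @param noise_sigma per-axis Gaussian accelerometer noise, g.
#' @param fs sampling rate, Hz.
#' @param seed integer RNG seed.
#' @return a `head_motion_script` object.
#' @export
head_motion_script <- function(segments, noise_sigma = 0.02, fs = 50,
                               seed = 0) {
  if (!all(c("duration_s", "theta_x", "theta_y") %in% names(segments))) {
    hf_stop("segments need columns duration_s, theta_x, theta_y",
            "hf_shape_error")
  }
  if (any(segments$duration_s <= 0)) {
    hf_stop("segment durations must be positive", "hf_range_error")
  }
  if (any(abs(segments$theta_x) > 90) || any(abs(segments$theta_y) > 90)) {
    hf_stop("target angles must lie in [-90, +90] degrees", "hf_range_error")
  }
  stopifnot(fs > 0, noise_sigma >= 0)
  structure(list(segments = segments, noise_sigma = noise_sigma,
                 fs = fs, seed = seed),
            class = "head_motion_script")
}

# Unit gravity vector whose tilt_from_accel equals (theta_x, theta_y):
# ax = sin(theta_x), ay = sin(theta_y), az = sqrt(1 - ax^2 - ay^2).
# Requires sin^2(theta_x) + sin^2(theta_y) <= 1, i.e. both axes cannot be
# near +-90 simultaneously (a physical head cannot do that either).
angles_to_gravity <- function(theta_x, theta_y) {
  ax <- sin(theta_x * pi / 180)
  ay <- sin(theta_y * pi / 180)
  rem <- 1 - ax^2 - ay^2
  if (any(rem < -1e-9)) {
    hf_stop("incompatible angle pair: sin^2(theta_x) + sin^2(theta_y) > 1",
            "hf_range_error")
  }
  data.frame(ax = ax, ay = ay, az = sqrt(pmax(rem, 0)))
}

#' Generate a static-gravity accelerometer trace for a head-motion script
#'
#' For each segment the noiseless acceleration is the unit gravity vector
#' that [tilt_from_accel()] maps back to the segment's target angles; the
#' pose ramps linearly from the previous segment's target over the first
#' 0.2 s of each segment. Independent Gaussian noise of `noise_sigma` is
#' added per axis. The generator emulates a head-worn IMU at rest in each
#' pose — it models gravity only, no linear acceleration.
#'
#' @param script a [head_motion_script()].
#' @return a data frame with columns `t`, `ax`, `ay`, `az` (seconds, g).
#' @export
#' @examples
#' sc <- head_motion_script(
#'   data.frame(duration_s = 1, theta_x = 30, theta_y = 0),
#'   noise_sigma = 0)
#' head(gen_accel_trace(sc))
gen_accel_trace <- function(script) {
  stopifnot(inherits(script, "head_motion_script"))
  fs <- script$fs
  seg <- script$segments
  ramp_s <- 0.2
  tx <- numeric(0)
  ty <- numeric(0)
  prev <- c(seg$theta_x[1], seg$theta_y[1])   # first segment starts on target
  for (i in seq_len(nrow(seg))) {
    n_i <- max(1L, round(seg$duration_s[i] * fs))
    tt <- (seq_len(n_i) - 1) / fs
    frac <- pmin(tt / ramp_s, 1)
    tx <- c(tx, prev[1] + frac * (seg$theta_x[i] - prev[1]))
    ty <- c(ty, prev[2] + frac * (seg$theta_y[i] - prev[2]))
    prev <- c(seg$theta_x[i], seg$theta_y[i])
  }
  g <- angles_to_gravity(tx, ty)
  n <- nrow(g)
  if (script$noise_sigma > 0) {
    g <- with_preserved_seed(script$seed, {
      g + matrix(stats::rnorm(3 * n, sd = script$noise_sigma), n, 3)
    })
  }
  cbind(data.frame(t = (seq_len(n) - 1) / fs), g)
}

#' Waveform template parameters for synthetic eye-gesture windows
#'
#' Each synthetic window is `baseline_dc` plus a linear drift, a
#' gesture-specific pulse per channel, and Gaussian noise. The four classes
#' are distinguished by the pulse signs: a left gaze deflects the left
#' channel up and the right channel down, a right gaze the mirror image,
#' a blink ("close") deflects both channels up, and "open" is baseline
#' only. (Which physical sensor responds positively to which gaze is a
#' convention; flip `pulse_amp`'s sign to reverse it.)
#'
#' @param baseline_dc sensor DC offset, volts.
#' @param pulse_amp pulse amplitude, volts.
#' @param pulse_center pulse centre, samples.
#' @param pulse_width pulse full width, samples.
#' @param drift_slope baseline drift, volts/sample.
#' @param noise_sigma Gaussian noise, volts.
#' @param fs sampling rate, Hz.
#' @param window_len samples per channel; must equal `round(fs * 1.5)`.
#' @param seed master RNG seed.
#' @return a `gesture_template_params` object.
#' @export
gesture_template_params <- function(baseline_dc = 2.0, pulse_amp = 0.8,
                                    pulse_center = 37, pulse_width = 15,
                                    drift_slope = 0.001, noise_sigma = 0.05,
                                    fs = 50, window_len = round(fs * 1.5),
                                    seed = 0) {
  if (window_len != round(fs * 1.5)) {
    hf_stop("window_len must equal round(fs * 1.5)", "hf_validation_error")
  }
  stopifnot(noise_sigma >= 0, pulse_width > 0)
  structure(list(baseline_dc = baseline_dc, pulse_amp = pulse_amp,
                 pulse_center = pulse_center, pulse_width = pulse_width,
                 drift_slope = drift_slope, noise_sigma = noise_sigma,
                 fs = fs, window_len = window_len, seed = seed),
            class = "gesture_template_params")
}

# Per-channel pulse signs for each gesture class.
gesture_pulse_signs <- function(label) {
  switch(label,
         open  = c(left = 0, right = 0),
         close = c(left = 1, right = 1),
         left  = c(left = 1, right = -1),
         right = c(left = -1, right = 1),
         hf_stop(sprintf("unknown gesture label '%s'", label),
                 "hf_vocabulary_error"))
}

#' Generate one raw synthetic gesture window
#'
#' @param label gesture class, one of [gesture_labels()].
#' @param params a [gesture_template_params()].
#' @param seed RNG seed for this window; defaults to the seed stored in
#'   `params`.
#' @return a labelled raw (unfiltered) [gesture_window()].
#' @export
#' @examples
#' w <- gen_gesture_window("left", gesture_template_params(noise_sigma = 0))
#' plot(w$left_channel, type = "l")
gen_gesture_window <- function(label, params = gesture_template_params(),
                               seed = params$seed) {
  signs <- gesture_pulse_signs(label)
  n <- params$window_len
  idx <- seq_len(n)
  # Gaussian bump with full width ~ pulse_width samples
  bump <- exp(-0.5 * ((idx - params$pulse_center) / (params$pulse_width / 2))^2)
  base <- params$baseline_dc + params$drift_slope * (idx - 1)
  left <- base + signs["left"] * params$pulse_amp * bump
  right <- base + signs["right"] * params$pulse_amp * bump
  if (params$noise_sigma > 0) {
    noise <- with_preserved_seed(seed, {
      matrix(stats::rnorm(2 * n, sd = params$noise_sigma), n, 2)
    })
    left <- left + noise[, 1]
    right <- right + noise[, 2]
  }
  gesture_window(left, right, label = label, window_len = n)
}

#' Generate a balanced labelled gesture dataset
#'
#' Produces `n_per_class` raw windows for each of the four gesture classes
#' (the default 50 per class gives the 200-window acquisition protocol).
#' Each window draws its noise from a distinct sub-seed derived from the
#' master seed in `params`, so the whole dataset is reproducible from one
#' number.
#'
#' @param n_per_class windows per gesture class (default 50).
#' @param params a [gesture_template_params()].
#' @return a list of labelled [gesture_window()] objects, length
#'   `4 * n_per_class`, grouped by class in [gesture_labels()] order.
#' @export
gen_gesture_dataset <- function(n_per_class = 50,
                                params = gesture_template_params()) {
  stopifnot(n_per_class >= 1)
  windows <- vector("list", 4 * n_per_class)
  k <- 0L
  for (lab in GESTURE_LABELS) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      windows[[k]] <- gen_gesture_window(
        lab, params, seed = derive_subseed(params$seed, k))
    }
  }
  windows
}

#' Generate a noisy voice token stream from a script
#'
#' Emits the scripted tokens at their scripted times; each token is
#' independently dropped with probability `drop_prob` or replaced with a
#' uniformly random in-vocabulary word with probability `confusion_prob`,
#' modelling a recognizer that misses or confuses commands.
#'
#' @param script data frame with columns `t`, `word` (all words must be in
#'   the eight-word vocabulary).
#' @param drop_prob per-token drop probability in \[0, 1\].
#' @param confusion_prob per-token confusion probability in \[0, 1\].
#' @param seed RNG seed.
#' @return a data frame with columns `t`, `word` (the surviving tokens).
#' @export
gen_voice_stream <- function(script, drop_prob = 0, confusion_prob = 0,
                             seed = 0) {
  if (!all(c("t", "word") %in% names(script))) {
    hf_stop("script needs columns t, word", "hf_shape_error")
  }
  stopifnot(drop_prob >= 0, drop_prob <= 1,
            confusion_prob >= 0, confusion_prob <= 1)
  vocab <- c(ATTENTION_WORDS, ORIENTATION_WORDS)
  words <- tolower(trimws(as.character(script$word)))
  if (!all(words %in% vocab)) {
    hf_stop(sprintf("scripted word '%s' is out of vocabulary",
                    words[!(words %in% vocab)][1]),
            "hf_vocabulary_error")
  }
  n <- length(words)
  if (n == 0) return(data.frame(t = numeric(0), word = character(0)))
  with_preserved_seed(seed, {
    dropped <- stats::runif(n) < drop_prob
    confused <- stats::runif(n) < confusion_prob
    words[confused] <- sample(vocab, sum(confused), replace = TRUE)
    data.frame(t = script$t[!dropped], word = words[!dropped])
  })
}
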