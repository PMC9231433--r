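# Platform configuration: one YAML (or JSON) file selects the active input
# interface and supplies every module's tunable parameters; a single master
# seed fans out to all randomised components.

#' Default platform configuration
#'
#' @return a nested list with blocks `interface`, `master_seed`, `head`,
#'   `eye`, `voice`, `drive` and `gesture_template`.
#' @export
default_config <- function() {
  list(
    interface = "head",
    master_seed = 0L,
    head = list(m = 2.5, n = 2.5, r = 0, s = 27000, v_ref = 2.5,
                v_min = 0, v_max = 5, dead_zone_deg = 10,
                invert_x = FALSE, invert_y = FALSE),
    eye = list(w = 0.2, alpha = 0.95, fs = 50, window_len = 75,
               timeout_windows = 3, holdout_fraction = 0.2),
    voice = list(drop_prob = 0, confusion_prob = 0),
    drive = list(v_max = 1, omega_max = 1, v_ref = 2.5, volts_span = 2.5,
                 dt = 0.1, swap_axes = FALSE),
    gesture_template = list(baseline_dc = 2.0, pulse_amp = 0.8,
                            pulse_center = 37, pulse_width = 15,
                            drift_slope = 0.001, noise_sigma = 0.05)
  )
}

# Recursive merge of user values over defaults; unknown keys are rejected
# with their full key path so typos surface immediately.
merge_config <- function(defaults, user, path = character(0)) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    hf_stop(sprintf("config key '%s' must be a block",
                    paste(path, collapse = ".")), "hf_config_error")
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    hf_stop(sprintf("unknown config key '%s'",
                    paste(c(path, unknown[1]), collapse = ".")),
            "hf_config_error")
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a platform configuration file
#'
#' Reads YAML (or JSON, by `.json` extension), fills unspecified keys with
#' defaults, rejects unknown keys with their key path, and enforces that
#' exactly one interface is selected.
#'
#' @param path configuration file; `NULL` or an empty file gives all
#'   defaults.
#' @return a validated configuration list (see [default_config()]).
#' @export
load_config <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) {
      hf_stop(sprintf("config file '%s' not found", path), "hf_config_error")
    }
    user <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
    } else {
      yaml::read_yaml(path)
    }
  }
  cfg <- merge_config(default_config(), user)
  if (length(cfg$interface) != 1 ||
      !(cfg$interface %in% c("head", "voice", "eye"))) {
    hf_stop("exactly one interface must be selected: head, voice or eye",
            "hf_config_error")
  }
  if (!is_scalar_number(cfg$master_seed)) {
    hf_stop("master_seed must be a single number", "hf_config_error")
  }
  cfg
}

#' Build module parameter objects from a configuration
#'
#' @param cfg a [load_config()] result.
#' @return a list with ready-to-use parameter objects: `cubic_map`
#'   ([cubic_map_params()]), `ema` ([ema_params()]), `dc_blocker`
#'   ([dc_blocker_params()]), `drive` ([drive_params()]) and
#'   `gesture_template` ([gesture_template_params()]).
#' @export
config_params <- function(cfg = default_config()) {
  h <- cfg$head
  e <- cfg$eye
  d <- cfg$drive
  g <- cfg$gesture_template
  list(
    cubic_map = cubic_map_params(m = h$m, n = h$n, r = h$r, s = h$s,
                                 v_ref = h$v_ref, v_min = h$v_min,
                                 v_max = h$v_max,
                                 dead_zone_deg = h$dead_zone_deg,
                                 invert_x = isTRUE(h$invert_x),
                                 invert_y = isTRUE(h$invert_y)),
    ema = ema_params(w = e$w),
    dc_blocker = dc_blocker_params(alpha = e$alpha),
    drive = drive_params(v_max = d$v_max, omega_max = d$omega_max,
                         v_ref = d$v_ref, volts_span = d$volts_span,
                         dt = d$dt, swap_axes = isTRUE(d$swap_axes)),
    gesture_template = gesture_template_params(
      baseline_dc = g$baseline_dc, pulse_amp = g$pulse_amp,
      pulse_center = g$pulse_center, pulse_width = g$pulse_width,
      drift_slope = g$drift_slope, noise_sigma = g$noise_sigma,
      fs = cfg$eye$fs, window_len = cfg$eye$window_len,
      seed = derive_subseed(cfg$master_seed, 1))
  )
}
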