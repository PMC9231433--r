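# Wheelchair simulator: the two joystick-replacement voltages map linearly
# to linear and angular speed about the 2.5 V rest point, pose integrates
# under unicycle kinematics, and an ultrasonic anti-collision gate inhibits
# forward motion when an obstacle is inside the 1.2 m forward detection
# cone.

#' Simulator drive parameters
#'
#' @param v_max linear speed at full-scale voltage, m/s.
#' @param omega_max angular speed at full-scale voltage, rad/s.
#' @param v_ref rest voltage, volts.
#' @param volts_span voltage swing from rest to full scale, volts.
#' @param dt integration step, seconds.
#' @param swap_axes if `TRUE`, `vy` drives linear speed and `vx` angular
#'   speed (the channel assignment is a wiring convention).
#' @return a `drive_params` object.
#' @export
drive_params <- function(v_max = 1, omega_max = 1, v_ref = 2.5,
                         volts_span = 2.5, dt = 0.1, swap_axes = FALSE) {
  stopifnot(v_max > 0, omega_max > 0, v_ref > 0, volts_span > 0, dt > 0)
  stop_if_not_flag(swap_axes, "swap_axes")
  structure(list(v_max = v_max, omega_max = omega_max, v_ref = v_ref,
                 volts_span = volts_span, dt = dt, swap_axes = swap_axes),
            class = "drive_params")
}

#' Initial wheelchair state
#'
#' @param x,y position, metres.
#' @param heading radians, normalized to (-pi, pi].
#' @param t time, seconds.
#' @return a `wheelchair_state` object (also carries the last applied `v`
#'   and `omega`).
#' @export
wheelchair_state <- function(x = 0, y = 0, heading = 0, t = 0) {
  structure(list(x = x, y = y, heading = normalize_heading(heading),
                 v = 0, omega = 0, t = t),
            class = "wheelchair_state")
}

normalize_heading <- function(h) {
  h <- (h + pi) %% (2 * pi) - pi
  ifelse(h == -pi, pi, h)   # keep the convention (-pi, pi]
}

#' Convert control voltages to body velocities
#'
#' Linear map, odd about the rest voltage: 2.5 V on both channels is rest,
#' 5 V on the speed channel is `v_max` forward, 0 V is `v_max` reverse, and
#' likewise for the turn channel.
#'
#' @param vx,vy control voltages in \[0, 5\] V.
#' @param params a [drive_params()].
#' @return a list with `v` (m/s) and `omega` (rad/s).
#' @export
#' @examples
#' voltages_to_velocities(2.5, 2.5)  # rest
#' voltages_to_velocities(5, 2.5)    # full-speed forward
voltages_to_velocities <- function(vx, vy, params = drive_params()) {
  stopifnot(inherits(params, "drive_params"))
  lo <- params$v_ref - params$volts_span
  hi <- params$v_ref + params$volts_span
  if (any(vx < lo | vx > hi | vy < lo | vy > hi)) {
    hf_stop(sprintf("control voltages must lie in [%g, %g] V", lo, hi),
            "hf_range_error")
  }
  if (params$swap_axes) { tmp <- vx; vx <- vy; vy <- tmp }
  list(v = params$v_max * (vx - params$v_ref) / params$volts_span,
       omega = params$omega_max * (vy - params$v_ref) / params$volts_span)
}

#' Advance the wheelchair pose by one step
#'
#' Unicycle kinematics: the heading is updated first, then the position
#' advances along the new heading.
#'
#' @param state a [wheelchair_state()].
#' @param v linear speed, m/s.
#' @param omega angular speed, rad/s.
#' @param params a [drive_params()] (supplies `dt`).
#' @return the updated `wheelchair_state`.
#' @export
step_kinematics <- function(state, v, omega, params = drive_params()) {
  stopifnot(inherits(state, "wheelchair_state"),
            is.finite(v), is.finite(omega))
  dt <- params$dt
  state$heading <- normalize_heading(state$heading + omega * dt)
  state$x <- state$x + v * cos(state$heading) * dt
  state$y <- state$y + v * sin(state$heading) * dt
  state$v <- v
  state$omega <- omega
  state$t <- state$t + dt
  state
}

#' Ultrasonic anti-collision gate
#'
#' Two front-mounted ultrasonic sensors are modelled as a forward detection
#' cone of half-angle `cone_half_deg`. If any obstacle's boundary lies
#' within `range_m` inside that cone, forward velocity (`v > 0`) is forced
#' to zero; turning in place and reversing away remain possible.
#'
#' @param v,omega commanded velocities.
#' @param state a [wheelchair_state()].
#' @param obstacles data frame with columns `x`, `y`, `radius` (metres); may
#'   have zero rows.
#' @param range_m detection range, metres (default 1.2).
#' @param cone_half_deg half-angle of the forward cone, degrees.
#' @return a list with the gated `v` and (unchanged) `omega`, plus
#'   `blocked` (`TRUE` if the gate fired).
#' @export
ultrasonic_gate <- function(v, omega, state, obstacles, range_m = 1.2,
                            cone_half_deg = 30) {
  stopifnot(inherits(state, "wheelchair_state"), range_m > 0)
  blocked <- FALSE
  if (v > 0 && !is.null(obstacles) && nrow(obstacles) > 0) {
    dx <- obstacles$x - state$x
    dy <- obstacles$y - state$y
    dist_boundary <- sqrt(dx^2 + dy^2) - obstacles$radius
    bearing <- atan2(dy, dx) - state$heading
    bearing <- abs((bearing + pi) %% (2 * pi) - pi)
    blocked <- any(dist_boundary <= range_m &
                     bearing <= cone_half_deg * pi / 180)
    if (blocked) v <- 0
  }
  list(v = v, omega = omega, blocked = blocked)
}

#' Run the closed loop: voltages -> gate -> kinematics
#'
#' Steps an interface's control-voltage stream through the velocity map,
#' the anti-collision gate and the kinematics integrator, one voltage row
#' per `dt`. Deterministic for deterministic inputs.
#'
#' @param voltages data frame with columns `vx`, `vy` (volts), one row per
#'   time step; a `t` column, if present, is ignored in favour of `dt`
#'   spacing.
#' @param course a list with elements `obstacles` (data frame `x`, `y`,
#'   `radius`; may be empty) and `start` (named list/vector with `x`, `y`,
#'   `heading`).
#' @param params a [drive_params()].
#' @param range_m anti-collision range, metres.
#' @return a data frame trace with columns `t`, `x`, `y`, `heading`, `v`,
#'   `omega`, `blocked`; the first row is the initial pose.
#' @export
run_closed_loop <- function(voltages, course = list(), params = drive_params(),
                            range_m = 1.2) {
  if (nrow(as.data.frame(voltages)) > 0 &&
      !all(c("vx", "vy") %in% names(voltages))) {
    hf_stop("voltage stream needs columns vx, vy", "hf_shape_error")
  }
  obstacles <- course$obstacles %||%
    data.frame(x = numeric(0), y = numeric(0), radius = numeric(0))
  start <- course$start %||% list(x = 0, y = 0, heading = 0)
  state <- wheelchair_state(start$x %||% start[["x"]],
                            start$y %||% start[["y"]],
                            start$heading %||% start[["heading"]])
  n <- nrow(as.data.frame(voltages))
  trace <- data.frame(t = numeric(n + 1), x = numeric(n + 1),
                      y = numeric(n + 1), heading = numeric(n + 1),
                      v = numeric(n + 1), omega = numeric(n + 1),
                      blocked = logical(n + 1))
  trace[1, ] <- list(state$t, state$x, state$y, state$heading, 0, 0, FALSE)
  for (k in seq_len(n)) {
    vel <- voltages_to_velocities(voltages$vx[k], voltages$vy[k], params)
    gated <- ultrasonic_gate(vel$v, vel$omega, state, obstacles, range_m)
    state <- step_kinematics(state, gated$v, gated$omega, params)
    trace[k + 1, ] <- list(state$t, state$x, state$y, state$heading,
                           gated$v, gated$omega, gated$blocked)
  }
  trace
}
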