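# Head-movement interface: inclination angles from a 3-axis accelerometer,
# the cubic dead-zone map to joystick voltages, and Table-style direction
# classification (up -> forward, down -> backward, right -> right,
# left -> left).

#' Head inclination angles from static 3-axis acceleration
#'
#' Recovers the two head inclination angles from the projection of gravity
#' onto a head-mounted 3-axis accelerometer:
#' \deqn{\theta_x = \arctan\!\left(a_x / \sqrt{a_y^2 + a_z^2}\right), \qquad
#'       \theta_y = \arctan\!\left(a_y / \sqrt{a_x^2 + a_z^2}\right)}
#' both reported in degrees in \[-90, +90\]. The formulas use only the
#' direction of the measured vector, so the result is invariant under
#' positive scaling of `(ax, ay, az)` — the accelerometer's gain does not
#' matter. A zero denominator yields ±90° by the sign of the numerator.
#'
#' @param ax,ay,az acceleration components (any common unit; typically g).
#'   `ax` may instead be a data frame with columns `ax`, `ay`, `az`.
#' @return a data frame with columns `theta_x`, `theta_y` (degrees).
#' @export
#' @examples
#' tilt_from_accel(0, 0, 1)           # level head
#' tilt_from_accel(0.5, 0, sqrt(3)/2) # 30 degree forward tilt
tilt_from_accel <- function(ax, ay = NULL, az = NULL) {
  if (is.data.frame(ax)) {
    df <- ax
    if (!all(c("ax", "ay", "az") %in% names(df))) {
      hf_stop("data frame input needs columns ax, ay, az", "hf_shape_error")
    }
    ax <- df$ax; ay <- df$ay; az <- df$az
  }
  stopifnot(length(ax) == length(ay), length(ay) == length(az))
  if (any(!is.finite(ax) | !is.finite(ay) | !is.finite(az))) {
    hf_stop("acceleration values must be finite", "hf_degenerate_input_error")
  }
  if (any(ax == 0 & ay == 0 & az == 0)) {
    hf_stop("all-zero acceleration vector: inclination undefined",
            "hf_degenerate_input_error")
  }
  rad2deg <- 180 / pi
  theta_x <- atan(ax / sqrt(ay^2 + az^2)) * rad2deg
  theta_y <- atan(ay / sqrt(ax^2 + az^2)) * rad2deg
  # atan(+-Inf) handles the zero-denominator limits (+-90 by numerator sign)
  data.frame(theta_x = theta_x, theta_y = theta_y)
}

#' Parameters of the cubic dead-zone voltage map
#'
#' The head interface maps each inclination angle to a joystick-replacement
#' voltage through a cubic curve centred on the rest point:
#' \deqn{v = \mathrm{clamp}\!\left(m \,(\theta - r)^3 / s + v_{ref}\right)}
#' The cube's flat centre is the "dead zone": small involuntary head
#' movements stay near the 2.5 V rest voltage, and the chair starts moving
#' softly once the tilt reaches the rising part of the curve. All parameters
#' are user-adjustable.
#'
#' Defaults (`m = n = 2.5`, `r = 0`, `s = 30^3`) make a 30° tilt saturate
#' the 0–5 V output, a comfortable head excursion.
#'
#' @param m,n slope factors for the x- and y-axis curves (dimensionless).
#' @param r centre offset of the quasi-linear zone, degrees.
#' @param s scale factor, degrees^3; larger values flatten the curve.
#' @param v_ref reference (rest) voltage, volts.
#' @param v_min,v_max output clamp, volts.
#' @param dead_zone_deg threshold angle for direction classification, degrees.
#' @param invert_x,invert_y flip the sense of an axis (some users prefer
#'   tilting down for forward).
#' @return an object of class `cubic_map_params`.
#' @export
cubic_map_params <- function(m = 2.5, n = 2.5, r = 0, s = 27000,
                             v_ref = 2.5, v_min = 0, v_max = 5,
                             dead_zone_deg = 10,
                             invert_x = FALSE, invert_y = FALSE) {
  stopifnot(is_scalar_number(m), is_scalar_number(n), is_scalar_number(r),
            is_scalar_number(s), is_scalar_number(v_ref),
            is_scalar_number(v_min), is_scalar_number(v_max),
            is_scalar_number(dead_zone_deg))
  stop_if_not_flag(invert_x, "invert_x")
  stop_if_not_flag(invert_y, "invert_y")
  if (s <= 0) hf_stop("scale factor s must be > 0", "hf_validation_error")
  if (!(v_min < v_ref && v_ref < v_max)) {
    hf_stop("need v_min < v_ref < v_max", "hf_validation_error")
  }
  if (dead_zone_deg < 0) {
    hf_stop("dead_zone_deg must be >= 0", "hf_validation_error")
  }
  structure(
    list(m = m, n = n, r = r, s = s, v_ref = v_ref,
         v_min = v_min, v_max = v_max, dead_zone_deg = dead_zone_deg,
         invert_x = invert_x, invert_y = invert_y),
    class = "cubic_map_params"
  )
}

#' @export
print.cubic_map_params <- function(x, ...) {
  cat("Cubic dead-zone map: v = clamp(m*(theta - r)^3/s + v_ref)\n")
  cat(sprintf("  m = %g, n = %g, r = %g deg, s = %g deg^3\n",
              x$m, x$n, x$r, x$s))
  cat(sprintf("  v_ref = %g V, clamp [%g, %g] V, dead zone %g deg\n",
              x$v_ref, x$v_min, x$v_max, x$dead_zone_deg))
  if (x$invert_x || x$invert_y) {
    cat(sprintf("  inverted axes:%s%s\n",
                if (x$invert_x) " x" else "", if (x$invert_y) " y" else ""))
  }
  invisible(x)
}

# Apply the per-user axis inversion before centring on r.
effective_angles <- function(theta_x, theta_y, params) {
  list(x = if (params$invert_x) -theta_x else theta_x,
       y = if (params$invert_y) -theta_y else theta_y)
}

#' Map inclination angles to control voltages through the cubic curve
#'
#' @param theta_x,theta_y inclination angles, degrees. `theta_x` may be a
#'   data frame with columns `theta_x`, `theta_y`.
#' @param params a [cubic_map_params()] object.
#' @return a data frame with columns `vx`, `vy` (volts, clamped to
#'   `[v_min, v_max]`).
#' @export
#' @examples
#' cubic_map(0, 0)    # rest point: 2.5 V on both axes
#' cubic_map(30, -30) # saturated forward, full left
cubic_map <- function(theta_x, theta_y = NULL, params = cubic_map_params()) {
  if (is.data.frame(theta_x)) {
    df <- theta_x
    theta_x <- df$theta_x; theta_y <- df$theta_y
  }
  stopifnot(inherits(params, "cubic_map_params"),
            length(theta_x) == length(theta_y))
  ang <- effective_angles(theta_x, theta_y, params)
  vx <- params$m * (ang$x - params$r)^3 / params$s + params$v_ref
  vy <- params$n * (ang$y - params$r)^3 / params$s + params$v_ref
  data.frame(
    vx = pmin(pmax(vx, params$v_min), params$v_max),
    vy = pmin(pmax(vy, params$v_min), params$v_max)
  )
}

#' Classify head tilt into a discrete drive action
#'
#' Inside the dead zone (both centred angles within `dead_zone_deg`) the
#' action is `"neutral"`. Otherwise the dominant axis — the larger absolute
#' centred angle, ties going to the x-axis — selects the action: up-tilt
#' (positive x) drives forward, down backward, positive y right, negative y
#' left.
#'
#' @inheritParams cubic_map
#' @return a character vector with values in
#'   `c("forward", "backward", "left", "right", "neutral")`.
#' @export
#' @examples
#' classify_head_direction(20, 0)  # "forward"
#' classify_head_direction(0, -20) # "left"
classify_head_direction <- function(theta_x, theta_y = NULL,
                                    params = cubic_map_params()) {
  if (is.data.frame(theta_x)) {
    df <- theta_x
    theta_x <- df$theta_x; theta_y <- df$theta_y
  }
  stopifnot(inherits(params, "cubic_map_params"),
            length(theta_x) == length(theta_y))
  ang <- effective_angles(theta_x, theta_y, params)
  cx <- ang$x - params$r
  cy <- ang$y - params$r
  out <- rep("neutral", length(cx))
  active <- abs(cx) > params$dead_zone_deg | abs(cy) > params$dead_zone_deg
  x_dominant <- abs(cx) >= abs(cy)   # tie resolves to the x-axis
  out[active & x_dominant & cx > 0] <- "forward"
  out[active & x_dominant & cx <= 0] <- "backward"
  out[active & !x_dominant & cy > 0] <- "right"
  out[active & !x_dominant & cy <= 0] <- "left"
  out
}

#' Run the full head-interface pipeline on an accelerometer trace
#'
#' Converts each sample of a timestamped acceleration trace to inclination
#' angles, maps them through the cubic dead-zone curve, and attaches the
#' discrete direction classification.
#'
#' @param accel data frame with columns `t`, `ax`, `ay`, `az`.
#' @param params a [cubic_map_params()] object.
#' @return a data frame with columns `t`, `theta_x`, `theta_y`, `vx`, `vy`,
#'   `action`.
#' @export
head_run <- function(accel, params = cubic_map_params()) {
  if (!all(c("t", "ax", "ay", "az") %in% names(accel))) {
    hf_stop("accel trace needs columns t, ax, ay, az", "hf_shape_error")
  }
  ang <- tilt_from_accel(accel$ax, accel$ay, accel$az)
  volts <- cubic_map(ang$theta_x, ang$theta_y, params)
  cbind(data.frame(t = accel$t), ang, volts,
        data.frame(action = classify_head_direction(ang$theta_x, ang$theta_y,
                                                    params)))
}
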