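# Signal conditioning for the infrared-oculography channels: an exponential
# moving average (first-order IIR low-pass) to smooth sensor noise, followed
# by a DC blocker (first-order IIR high-pass) to remove the reflectance
# baseline.

#' Exponential-moving-average parameters
#'
#' @param w weighting factor in (0, 1]; smaller values smooth more. `w = 1`
#'   is the identity filter.
#' @param y_init initial previous-output value `y(-1)`.
#' @return an `ema_params` object.
#' @export
ema_params <- function(w = 0.2, y_init = 0) {
  stopifnot(is_scalar_number(w), is_scalar_number(y_init))
  if (w <= 0 || w > 1) {
    hf_stop("EMA weighting factor w must lie in (0, 1]", "hf_validation_error")
  }
  structure(list(w = w, y_init = y_init), class = "ema_params")
}

#' DC-blocker parameters
#'
#' @param alpha pole coefficient in (0, 1); values near 1 give a lower
#'   corner frequency (narrower notch at DC).
#' @param x_init initial previous-input value `x(-1)`; `NULL` means "use the
#'   first sample", which starts the filter transient-free.
#' @param y_init initial previous-output value `y(-1)`.
#' @return a `dc_blocker_params` object.
#' @export
dc_blocker_params <- function(alpha = 0.95, x_init = NULL, y_init = 0) {
  stopifnot(is_scalar_number(alpha), is_scalar_number(y_init))
  if (!is.null(x_init)) stopifnot(is_scalar_number(x_init))
  if (alpha <= 0 || alpha >= 1) {
    hf_stop("DC blocker pole alpha must lie in (0, 1) for stability",
            "hf_validation_error")
  }
  structure(list(alpha = alpha, x_init = x_init, y_init = y_init),
            class = "dc_blocker_params")
}

#' Exponential moving average filter
#'
#' First-order recursive low-pass smoother
#' \deqn{y(n) = w\,x(n) + (1 - w)\,y(n-1)}
#' with `y(-1) = y_init`. Output length equals input length; an empty input
#' returns an empty output.
#'
#' @param x numeric input samples.
#' @param params an [ema_params()] object.
#' @return numeric vector of filtered samples.
#' @export
#' @examples
#' ema_filter(c(1, 0, 0, 0), ema_params(w = 0.5, y_init = 0))
ema_filter <- function(x, params = ema_params()) {
  stopifnot(inherits(params, "ema_params"), is.numeric(x))
  n <- length(x)
  if (n == 0) return(numeric(0))
  y <- numeric(n)
  prev <- params$y_init
  w <- params$w
  for (i in seq_len(n)) {
    prev <- w * x[i] + (1 - w) * prev
    y[i] <- prev
  }
  y
}

#' DC-blocker filter
#'
#' First-order IIR high-pass
#' \deqn{y(n) = x(n) - x(n-1) + \alpha\,y(n-1)}
#' with `x(-1) = x_init` and `y(-1) = y_init`. A constant input with matched
#' initial state (`x_init` equal to the constant, `y_init = 0`) is rejected
#' exactly. Output length equals input length.
#'
#' @param x numeric input samples.
#' @param params a [dc_blocker_params()] object.
#' @return numeric vector of filtered samples.
#' @export
#' @examples
#' dc_blocker(rep(2, 5), dc_blocker_params())        # matched start: zeros
#' dc_blocker(c(1, 1, 1), dc_blocker_params(x_init = 0))
dc_blocker <- function(x, params = dc_blocker_params()) {
  stopifnot(inherits(params, "dc_blocker_params"), is.numeric(x))
  n <- length(x)
  if (n == 0) return(numeric(0))
  y <- numeric(n)
  x_prev <- params$x_init %||% x[1]
  y_prev <- params$y_init
  a <- params$alpha
  for (i in seq_len(n)) {
    y_prev <- (x[i] - x_prev) + a * y_prev
    x_prev <- x[i]
    y[i] <- y_prev
  }
  y
}
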