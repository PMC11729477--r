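#' Filter specification for zero-lag Butterworth smoothing
#'
#' `order` is the effective order after the forward-backward (zero-lag)
#' doubling convention common in gait analysis: a 4th-order zero-lag filter
#' is realised as two passes of a 2nd-order Butterworth design. Marker
#' trajectories conventionally use `order = 4`, IMU accelerations
#' `order = 2`, both with a 12 Hz cutoff.
#'
#' @param order Effective even filter order (>= 2).
#' @param cutoff Low-pass cutoff frequency in Hz; must lie below Nyquist.
#' @param rate Sampling rate of the series to be filtered, Hz.
#' @param convention `"halved"` (default): the digital design order is
#'   `order / 2` and the two passes double it; `"direct"`: the stated order
#'   is designed and applied twice.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(order, cutoff, rate,
                        convention = c("halved", "direct")) {
  convention <- match.arg(convention)
  if (order < 2 || order %% 2 != 0) stop("`order` must be even and >= 2", call. = FALSE)
  if (cutoff <= 0 || cutoff >= rate / 2) {
    stop(sprintf("cutoff %g Hz must lie in (0, Nyquist = %g Hz)", cutoff, rate / 2),
         call. = FALSE)
  }
  structure(list(order = order, cutoff = cutoff, rate = rate,
                 convention = convention, zero_lag = TRUE),
            class = "filter_spec")
}

design_order <- function(spec) {
  if (spec$convention == "halved") spec$order / 2 else spec$order
}

# Butterworth coefficients for the single-pass design.
butter_coefs <- function(spec) {
  signal::butter(design_order(spec), spec$cutoff / (spec$rate / 2), type = "low")
}

#' Zero-lag (forward-backward) Butterworth low-pass filter
#'
#' Applies the Butterworth design forward and backward so the net phase is
#' zero and event timing is preserved. Endpoint transients are suppressed by
#' odd (mirror) reflection padding of length three times the filter's
#' characteristic length (`rate / cutoff` samples), capped at the series
#' length.
#'
#' @param x Numeric vector, or matrix filtered column-wise.
#' @param spec A [filter_spec()].
#' @return Filtered series, same dimensions as `x`.
#' @examples
#' t <- seq(0, 2, by = 1 / 240)
#' x <- sin(2 * pi * t)                      # 1 Hz: deep in the passband
#' spec <- filter_spec(4, 12, 240)
#' max(abs(butterworth_zero_lag(x, spec) - x)) < 1e-3
#' @export
butterworth_zero_lag <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (is.matrix(x)) {
    return(apply(x, 2L, butterworth_zero_lag, spec = spec))
  }
  n <- length(x)
  pad <- min(ceiling(3 * spec$rate / spec$cutoff), n - 1L)
  if (n <= 3L || pad < 3L) {
    stop("series too short for zero-lag filtering at this cutoff", call. = FALSE)
  }
  bf <- butter_coefs(spec)
  # odd reflection about the end samples keeps value and slope continuous
  head_pad <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(head_pad, x, tail_pad)
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[seq(pad + 1L, pad + n)]
}

# Squared-magnitude (two-pass) frequency response of the design at
# frequencies f (Hz); the analytic oracle used by the tests.
filter_gain_two_pass <- function(spec, f) {
  bf <- butter_coefs(spec)
  w <- 2 * pi * f / spec$rate
  H <- vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(bf$b) - 1))
    num <- sum(bf$b * z)
    den <- sum(bf$a * exp(-1i * wi * (seq_along(bf$a) - 1)))
    abs(num / den)
  }, numeric(1))
  H^2
}

#' Finite-difference differentiation
#'
#' Central differences at interior samples --- \eqn{(x_{t+1} - x_{t-1}) /
#' (2\Delta t)} for velocity and \eqn{(x_{t+1} - 2x_t + x_{t-1}) /
#' \Delta t^2} for acceleration --- with second-order one-sided stencils at
#' the first and last samples, so the output has the same length as the
#' input.
#'
#' @param x Numeric vector, or matrix differentiated column-wise.
#' @param rate Sampling rate in Hz.
#' @param deriv_order 1 (velocity) or 2 (acceleration).
#' @return Derivative series, same dimensions as `x`.
#' @export
finite_difference <- function(x, rate, deriv_order = 1L) {
  if (is.matrix(x)) {
    return(apply(x, 2L, finite_difference, rate = rate, deriv_order = deriv_order))
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to differentiate", call. = FALSE)
  if (!deriv_order %in% c(1L, 2L)) stop("deriv_order must be 1 or 2", call. = FALSE)
  dt <- 1 / rate
  i <- 2:(n - 1L)
  if (deriv_order == 1L) {
    d <- numeric(n)
    d[i] <- (x[i + 1L] - x[i - 1L]) / (2 * dt)
    d[1L] <- (-3 * x[1L] + 4 * x[2L] - x[3L]) / (2 * dt)
    d[n] <- (3 * x[n] - 4 * x[n - 1L] + x[n - 2L]) / (2 * dt)
  } else {
    if (n < 4L) stop("need at least 4 samples for second derivatives", call. = FALSE)
    d <- numeric(n)
    d[i] <- (x[i + 1L] - 2 * x[i] + x[i - 1L]) / dt^2
    d[1L] <- (2 * x[1L] - 5 * x[2L] + 4 * x[3L] - x[4L]) / dt^2
    d[n] <- (2 * x[n] - 5 * x[n - 1L] + 4 * x[n - 2L] - x[n - 3L]) / dt^2
  }
  d
}

#' Remove the gravitational offset from IMU accelerations
#'
#' Subtracts `g` from the vertical channel only; an accelerometer at rest
#' with its z-axis up reads +g on that axis, so a stationary reading of
#' (0, 0, 9.81) becomes (0, 0, 0).
#'
#' @param acc `n x 3` acceleration matrix in m/s^2, columns (X, Y, Z) with
#'   Z vertical, or a plain vertical-axis vector.
#' @param g Gravitational acceleration, default 9.81 m/s^2.
#' @param vertical Column index of the vertical axis (default 3).
#' @return Same shape as `acc` with the vertical channel reduced by `g`.
#' @export
gravity_correct <- function(acc, g = 9.81, vertical = 3L) {
  if (is.matrix(acc)) {
    acc[, vertical] <- acc[, vertical] - g
    acc
  } else {
    acc - g
  }
}
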