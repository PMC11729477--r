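#' Event series container
#'
#' @param times Event times in seconds, strictly increasing.
#' @param source `"camera"` or `"imu"`.
#' @param foot `"left"`, `"right"` or `"unspecified"`.
#' @return An `event_series` object.
#' @export
event_series <- function(times, source = c("camera", "imu"),
                         foot = c("unspecified", "left", "right")) {
  source <- match.arg(source)
  foot <- match.arg(foot)
  times <- as.numeric(times)
  if (length(times) && any(diff(times) <= 0)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = times, source = source, foot = foot),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d %s events (%s foot)\n",
              length(x$times), x$source, x$foot))
  if (length(x$times)) {
    cat("  ", paste(sprintf("%.3f", utils::head(x$times, 10L)), collapse = " "),
        if (length(x$times) > 10L) "..." else "", "\n")
  }
  invisible(x)
}

# Parabolic sub-sample refinement of an extremum at index i.
refine_extremum <- function(y, i, rate, t0 = 0) {
  n <- length(y)
  if (i <= 1L || i >= n) return(t0 + (i - 1) / rate)
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  delta <- if (abs(denom) < .Machine$double.eps) 0 else
    0.5 * (y[i - 1L] - y[i + 1L]) / denom
  t0 + (i - 1 + max(-0.5, min(0.5, delta))) / rate
}

# Indices of strict local minima.
local_minima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1L)] < y[1:(n - 2L)] & y[2:(n - 1L)] <= y[3:n]) + 1L
}

# Dominant stride period (s) from the autocorrelation of a detrended
# signal, searched over the physiological stride band.
dominant_stride_period <- function(x, rate, band = c(0.5, 2)) {
  x <- x - mean(x)
  n <- length(x)
  lag_min <- max(2L, floor(band[1L] * rate))
  lag_max <- min(n - 2L, ceiling(band[2L] * rate))
  if (lag_max <= lag_min) {
    stop("series too short to estimate a stride period", call. = FALSE)
  }
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = FALSE)$acf[, 1L, 1L]
  lags <- lag_min:lag_max
  best <- lags[which.max(ac[lags + 1L])]
  # aperiodic signals have band autocorrelations of order 1/sqrt(n)
  if (ac[best + 1L] <= 0.2) {
    stop("no periodicity detectable in the stride band", call. = FALSE)
  }
  best / rate
}

#' Camera-side heel-strike detection
#'
#' With a vertical ground-reaction-force series present, heel strike is the
#' first sample of each contiguous region where the force rises through the
#' threshold (20 N by default). Without force data, the kinematic fallback
#' detects local minima of the heel-marker height separated by at least
#' half the dominant stride period, with parabolic sub-sample refinement.
#'
#' @param heel_height Heel-marker height series, metres.
#' @param rate Sampling rate, Hz.
#' @param grf Optional vertical ground-reaction-force series, N, same rate.
#' @param grf_threshold Contact threshold, N.
#' @param t0 Time of first sample, seconds.
#' @param foot Which foot the series belongs to.
#' @return An [event_series()] with `source = "camera"`.
#' @export
detect_hs_camera <- function(heel_height, rate, grf = NULL,
                             grf_threshold = 20, t0 = 0,
                             foot = "unspecified") {
  if (!is.null(grf)) {
    above <- grf >= grf_threshold
    rises <- which(above & !c(TRUE, above[-length(above)]))
    if (!length(rises)) {
      stop(sprintf("no ground-contact onsets found (force never rises through %g N)",
                   grf_threshold), call. = FALSE)
    }
    return(event_series(t0 + (rises - 1) / rate, "camera", foot))
  }
  period <- dominant_stride_period(heel_height, rate)
  cand <- local_minima(heel_height)
  if (!length(cand)) stop("no heel-height minima found", call. = FALSE)
  keep <- select_separated(cand, heel_height[cand], min_gap = 0.5 * period * rate)
  times <- vapply(keep, refine_extremum, numeric(1), y = heel_height,
                  rate = rate, t0 = t0)
  event_series(sort(times), "camera", foot)
}

# Greedy depth-first selection: deepest candidates first, rejecting any
# candidate closer than min_gap samples to an accepted one.
select_separated <- function(idx, depth, min_gap) {
  ord <- idx[order(depth)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  sort(kept)
}

#' IMU-side initial-contact detection (Gaussian CWT)
#'
#' Implements the wavelet pipeline for trunk-accelerometer gait events:
#' the gravity-corrected vertical acceleration is detrended, numerically
#' integrated, then differentiated with a Gaussian-derivative smoothing
#' kernel (a continuous wavelet transform at a single scale, one tenth of
#' the stride period by default). Local minima of the transformed signal
#' are initial contacts; one IC per step is detected and, when
#' `per = "stride"` (the default), the deeper of the two alternating step
#' streams is kept so events index the same foot once per stride.
#'
#' @param vertical_acc Gravity-corrected vertical acceleration, m/s^2.
#' @param rate Sampling rate, Hz.
#' @param scale Wavelet scale in seconds; default `stride period / 10`.
#' @param per `"stride"` (one event per stride, same foot) or `"step"`
#'   (every initial contact).
#' @param t0 Time of first sample, seconds.
#' @return An [event_series()] with `source = "imu"`; the estimated stride
#'   period (s) is attached as attribute `stride_period`.
#' @export
detect_hs_imu <- function(vertical_acc, rate, scale = NULL,
                          per = c("stride", "step"), t0 = 0) {
  per <- match.arg(per)
  x <- as.numeric(vertical_acc)
  if (length(x) < rate) stop("series too short for IC detection", call. = FALSE)
  period <- dominant_stride_period(x, rate)
  if (period < 0.5 || period > 2) {
    stop(sprintf("dominant stride period %.2f s outside the 0.5-2 s gait band",
                 period), call. = FALSE)
  }
  if (is.null(scale)) scale <- period / 10
  x <- x - mean(x)
  dt <- 1 / rate
  # cumulative trapezoid integration
  v <- c(0, cumsum((x[-1L] + x[-length(x)]) / 2 * dt))
  w <- gauss_deriv_filter(v, scale * rate)
  cand <- local_minima(w)
  if (!length(cand)) stop("no initial-contact minima found", call. = FALSE)
  # one IC per step: refractory of roughly a third of the stride keeps
  # both feet while rejecting wavelet ripple
  cand <- select_separated(cand, w[cand], min_gap = 0.3 * period * rate)
  if (per == "stride") {
    cand <- pick_stride_parity(cand, w, period * rate)
  }
  times <- vapply(cand, refine_extremum, numeric(1), y = w, rate = rate, t0 = t0)
  ev <- event_series(sort(times), "imu")
  attr(ev, "stride_period") <- period
  ev
}

# Smoothed derivative: convolution with the first derivative of a
# Gaussian of SD `scale_samples`, sign chosen so the output approximates
# d/dt of the input (per sample spacing accounted for).
gauss_deriv_filter <- function(x, scale_samples) {
  half <- max(3L, ceiling(4 * scale_samples))
  k <- seq(-half, half)
  g <- exp(-k^2 / (2 * scale_samples^2))
  dg <- -k * g / scale_samples^2      # d/dk of the Gaussian
  dg <- dg - mean(dg)                 # exact zero DC response
  n <- length(x)
  xp <- c(2 * x[1L] - x[seq(min(half + 1L, n), 2L)], x,
          2 * x[n] - x[seq(n - 1L, max(n - half, 1L))])
  y <- stats::filter(xp, rev(dg), sides = 2L)
  as.numeric(y[seq(half + 1L, half + n)]) * -1
}

# Split alternating step events into two same-foot streams and keep the
# one with the deeper mean transform value.
pick_stride_parity <- function(idx, w, period_samples) {
  if (length(idx) < 3L) return(idx)
  even <- idx[seq(1L, length(idx), by = 2L)]
  odd <- idx[seq(2L, length(idx), by = 2L)]
  gaps <- diff(idx)
  if (stats::median(gaps) > 0.75 * period_samples) return(idx)  # already stride-level
  if (mean(w[even]) <= mean(w[odd])) even else odd
}

#' Pair heel-strike events across systems
#'
#' Estimates the constant clock offset between the two series as the median
#' of nearest-event time differences, then greedily pairs nearest
#' neighbours within `tolerance` after removing that offset. Unpaired
#' events are reported, not dropped.
#'
#' @param camera,imu [event_series()] objects.
#' @param tolerance Maximum |camera - (imu - offset)| for a pair, seconds.
#' @return List with `pairs` (data.frame `camera`, `imu`, `delta`),
#'   `offset` (estimated imu-minus-camera clock offset, s), and
#'   `unpaired` (list of leftover camera / imu times).
#' @export
match_events <- function(camera, imu, tolerance = 0.05) {
  tc <- camera$times; ti <- imu$times
  if (!length(tc) || !length(ti)) {
    stop("both event series must be non-empty", call. = FALSE)
  }
  nearest <- vapply(tc, function(t) ti[which.min(abs(ti - t))], numeric(1))
  offset <- stats::median(nearest - tc)
  ti_adj <- ti - offset
  pairs <- data.frame(camera = numeric(0), imu = numeric(0), delta = numeric(0))
  used_i <- logical(length(ti))
  for (j in order(tc)) {
    d <- abs(ti_adj - tc[j])
    d[used_i] <- Inf
    k <- which.min(d)
    if (is.finite(d[k]) && d[k] <= tolerance) {
      used_i[k] <- TRUE
      pairs <- rbind(pairs, data.frame(camera = tc[j], imu = ti[k],
                                       delta = ti_adj[k] - tc[j]))
    }
  }
  if (!nrow(pairs)) stop("no event pairs within tolerance", call. = FALSE)
  list(pairs = pairs[order(pairs$camera), ],
       offset = offset,
       unpaired = list(camera = setdiff(tc, pairs$camera),
                       imu = ti[!used_i]))
}
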