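#' Segment a series into gait cycles
#'
#' A gait cycle spans two consecutive same-foot heel strikes. The first and
#' last cycles of a trial are discarded (they carry filter-edge and
#' detection-boundary transients) whenever at least three interior cycles
#' would remain; otherwise nothing is trimmed and a warning is emitted.
#'
#' @param values Numeric vector or `n x d` matrix of samples.
#' @param rate Sampling rate, Hz.
#' @param events An [event_series()] (or numeric vector of event times, s).
#' @param t0 Time of the first sample, seconds.
#' @param trim Drop the first and last cycle (default TRUE).
#' @return List of `gait_cycle` objects: each has `values` (matrix of the
#'   samples spanning the cycle plus one guard sample each side when
#'   available), `time` (their timestamps), `t_start`, `t_end`.
#' @export
segment_cycles <- function(values, rate, events, t0 = 0, trim = TRUE) {
  times <- if (inherits(events, "event_series")) events$times else as.numeric(events)
  if (length(times) < 2L) stop("need at least 2 events to segment cycles", call. = FALSE)
  values <- as.matrix(values)
  n <- nrow(values)
  bounds <- data.frame(start = times[-length(times)], end = times[-1L])
  if (trim) {
    if (nrow(bounds) >= 3L) {
      bounds <- bounds[-c(1L, nrow(bounds)), ]
    } else {
      warning("too few cycles to trim; first/last cycles kept", call. = FALSE)
    }
  }
  sample_time <- t0 + (seq_len(n) - 1) / rate
  lapply(seq_len(nrow(bounds)), function(i) {
    i0 <- max(1L, findInterval(bounds$start[i], sample_time) - 1L)
    i1 <- min(n, findInterval(bounds$end[i], sample_time) + 2L)
    if (i1 - i0 < 3L) stop("cycle spans too few samples", call. = FALSE)
    structure(list(values = values[i0:i1, , drop = FALSE],
                   time = sample_time[i0:i1],
                   t_start = bounds$start[i], t_end = bounds$end[i]),
              class = "gait_cycle")
  })
}

#' Time-normalize a gait cycle to a fixed node grid
#'
#' Resamples each direction of the cycle by cubic-spline interpolation onto
#' nodes at 0%, 1%, ..., 100% of the cycle interval. Nodes at the
#' boundaries are interpolated within the sampled support (the cycle
#' carries guard samples), never extrapolated.
#'
#' @param cycle A `gait_cycle` from [segment_cycles()].
#' @param n_nodes Number of nodes (default 101).
#' @return `n_nodes x d` matrix of resampled values.
#' @export
time_normalize <- function(cycle, n_nodes = 101L) {
  stopifnot(inherits(cycle, "gait_cycle"), n_nodes >= 2L)
  if (nrow(cycle$values) < 4L) {
    stop("cycle has too few samples for spline resampling", call. = FALSE)
  }
  nodes <- seq(cycle$t_start, cycle$t_end, length.out = n_nodes)
  apply(cycle$values, 2L, function(col) {
    stats::spline(cycle$time, col, xout = nodes, method = "fmm")$y
  })
}

#' Amplitude-normalize a cycle curve to [-1, 1]
#'
#' Divides by the largest absolute extreme, so the curve fits within
#' `[-1, 1]` with at least one node at +1 or -1.
#'
#' @param curve Numeric vector (or matrix normalized column-wise).
#' @return Normalized curve, same shape.
#' @export
amplitude_normalize <- function(curve) {
  if (is.matrix(curve)) return(apply(curve, 2L, amplitude_normalize))
  m <- max(abs(range(curve)))
  if (m == 0) {
    warning("all-zero curve left unnormalized", call. = FALSE)
    return(curve)
  }
  curve / m
}

#' Pointwise ensemble average of normalized cycles
#'
#' @param cycles List of equal-length numeric vectors (or equal-dim
#'   matrices).
#' @return List with `mean` and `sd` (sample SD; zero-filled with a warning
#'   when only one cycle is supplied).
#' @export
ensemble_average <- function(cycles) {
  if (!length(cycles)) stop("no cycles to average", call. = FALSE)
  arr <- simplify2array(cycles)
  nd <- length(dim(arr))
  if (length(cycles) == 1L) {
    warning("single cycle: SD set to zero", call. = FALSE)
    m <- cycles[[1L]]
    return(list(mean = m, sd = m * 0))
  }
  list(mean = apply(arr, seq_len(nd - 1L), mean),
       sd = apply(arr, seq_len(nd - 1L), stats::sd))
}

#' Assemble a subject x condition x node x direction cycle set
#'
#' The statistical substrate of the comparison: per subject and condition
#' one 101-node, 3-direction curve (the ensemble average over that
#' subject's interior cycles). `normalized = TRUE` applies per-subject,
#' per-direction amplitude normalization (used by the SPM magnitude
#' comparison); agreement statistics use the physical-unit curves.
#'
#' @param curves Nested list: `curves[[subject]][[condition]]` is a
#'   `n_nodes x 3` matrix.
#' @param conditions Character vector of condition names.
#' @param directions Direction labels (default AP, ML, SI).
#' @param normalized Whether values were amplitude-normalized to [-1, 1].
#' @return A `cycle_set`: 4-d array with dimnames
#'   (subject, condition, node, direction).
#' @export
cycle_set <- function(curves, conditions, directions = c("AP", "ML", "SI"),
                      normalized = FALSE) {
  subjects <- names(curves)
  if (is.null(subjects)) subjects <- sprintf("S%02d", seq_along(curves))
  n_nodes <- nrow(curves[[1L]][[1L]])
  arr <- array(NA_real_,
               dim = c(length(subjects), length(conditions), n_nodes,
                       length(directions)),
               dimnames = list(subject = subjects, condition = conditions,
                               node = 0:(n_nodes - 1L), direction = directions))
  for (s in seq_along(subjects)) {
    for (cnd in seq_along(conditions)) {
      m <- curves[[s]][[conditions[cnd]]]
      if (is.null(m)) stop(sprintf("subject %s lacks condition %s",
                                   subjects[s], conditions[cnd]), call. = FALSE)
      if (normalized && any(abs(m) > 1 + 1e-12)) {
        stop("normalized cycle values must lie in [-1, 1]", call. = FALSE)
      }
      arr[s, cnd, , ] <- m
    }
  }
  structure(arr, normalized = normalized, class = c("cycle_set", "array"))
}

#' @export
print.cycle_set <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<cycle_set> %d subjects x %d conditions x %d nodes x %d directions%s\n",
              d[1L], d[2L], d[3L], d[4L],
              if (isTRUE(attr(x, "normalized"))) " (amplitude-normalized)" else ""))
  invisible(x)
}

#' Long-format view of a cycle set
#'
#' @param x A `cycle_set`.
#' @param ... Unused.
#' @return data.frame with columns subject, condition, direction, node,
#'   value --- the exchange format between pipeline stages.
#' @export
as.data.frame.cycle_set <- function(x, ...) {
  dn <- dimnames(x)
  g <- expand.grid(subject = dn$subject, condition = dn$condition,
                   node = as.integer(dn$node), direction = dn$direction,
                   stringsAsFactors = FALSE)
  g$value <- mapply(function(s, cnd, nd, dir) x[s, cnd, as.character(nd), dir],
                    g$subject, g$condition, g$node, g$direction)
  g[order(g$subject, g$condition, g$direction, g$node), ]
}
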