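#' Configuration for the synthetic gait generator
#'
#' Defines a cohort of walking trials with closed-form marker trajectories,
#' a virtual L5 accelerometer and analytically known ground truth (CoM
#' trajectory and right-foot heel-strike times). Defaults emulate a healthy
#' adult cohort walking at self-selected speed: 16 subjects, ~1.1 s strides
#' with 0.05 s between-subject SD, 1.3 m/s progression, markers at 240 Hz
#' and the IMU at 128 Hz.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param n_strides Strides per trial (>= 3 so interior cycles survive edge
#'   trimming).
#' @param stride_duration Mean stride time, seconds.
#' @param stride_sd Between-subject SD of stride time, seconds (draws are
#'   clamped to +/- 3 SD).
#' @param walking_speed Forward progression speed, m/s.
#' @param marker_rate,imu_rate Sampling rates, Hz.
#' @param marker_noise_sd Marker noise SD, metres (per axis and frame).
#' @param imu_noise_sd IMU noise SD, m/s^2 (per axis and sample).
#' @param sensor_offset Length-3 placement offset of the IMU relative to the
#'   pelvis-segment CoM, metres (X anteroposterior, Y mediolateral,
#'   Z vertical).
#' @param axis_misalignment Sensor-axis misalignment angle about the
#'   walking axis, degrees.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @param osc Oscillation amplitudes, see [default_oscillations()].
#' @return A `gait_sim_config` object.
#' @export
gait_sim_config <- function(n_subjects = 16L, n_strides = 12L,
                            stride_duration = 1.1, stride_sd = 0.05,
                            walking_speed = 1.3,
                            marker_rate = 240, imu_rate = 128,
                            marker_noise_sd = 5e-4, imu_noise_sd = 0.03,
                            sensor_offset = c(-0.10, 0, 0.05),
                            axis_misalignment = 0, gravity = 9.81,
                            seed = 1L, osc = default_oscillations()) {
  if (marker_rate <= 0 || imu_rate <= 0) {
    stop("sampling rates must be positive", call. = FALSE)
  }
  if (stride_duration <= 0) stop("stride_duration must be positive", call. = FALSE)
  if (n_strides < 3L) stop("n_strides must be >= 3", call. = FALSE)
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (length(sensor_offset) != 3L) stop("sensor_offset must have length 3", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), n_strides = as.integer(n_strides),
         stride_duration = stride_duration, stride_sd = stride_sd,
         walking_speed = walking_speed,
         marker_rate = marker_rate, imu_rate = imu_rate,
         marker_noise_sd = marker_noise_sd, imu_noise_sd = imu_noise_sd,
         sensor_offset = as.numeric(sensor_offset),
         axis_misalignment = axis_misalignment, gravity = gravity,
         seed = as.integer(seed), osc = osc),
    class = "gait_sim_config"
  )
}

#' Oscillation amplitudes of the synthetic walker
#'
#' All amplitudes in metres. The whole body shares a common CoM-like
#' translation: vertical and anteroposterior fluctuation at twice the
#' stride frequency (one bounce per step) with a smaller stride-frequency
#' vertical component expressing left/right step asymmetry, and mediolateral
#' sway at stride frequency. The pelvis adds local motion the rest of the
#' body does not share (this is what makes the L5 sensor differ from the
#' whole-body CoM). Limb markers swing anteroposteriorly at stride
#' frequency in left/right antiphase (so their contribution cancels in the
#' whole-body CoM), and heel/toe/ankle markers lift once per stride with
#' the heel-height minimum defining the heel-strike ground truth.
#'
#' @param scale Common multiplier; `scale = 0` yields a rigid walker whose
#'   CoM moves on a straight line.
#' @return Named list of amplitudes.
#' @export
default_oscillations <- function(scale = 1) {
  lapply(list(
    com_vert2 = 0.010, com_vert1 = 0.012, com_ap2 = 0.005, com_ml1 = 0.020,
    pelvis_ml1 = 0.010, pelvis_ap2 = 0.004, pelvis_vert2 = 0.003,
    swing_hip = 0.02, swing_knee = 0.08, swing_ankle = 0.15,
    swing_foot = 0.18, swing_elbow = 0.03, swing_wrist = 0.06,
    lift_heel = 0.06, lift_toe = 0.05, lift_ankle = 0.03,
    limb_ml = 0.005
  ), function(a) a * scale)
}

# Fixed phases (radians) of the harmonic components, relative to the
# right heel strike. Vertical phases are 0 so the vertical-acceleration
# minimum coincides with heel strike.
.phase <- list(ap2 = -0.8, ml1 = 1.2, pelvis_ml1 = 1.9, pelvis_ap2 = 0.9,
               swing = -pi / 2, limb_ml = 0.4)

# Standing-posture marker positions (metres); X anteroposterior,
# Y mediolateral (left positive), Z vertical.
.marker_bases <- list(
  VERTEX = c(0, 0, 1.70), C7 = c(0, 0, 1.45),
  L_SHOULDER = c(0, 0.18, 1.40), R_SHOULDER = c(0, -0.18, 1.40),
  L_ELBOW = c(0, 0.20, 1.10), R_ELBOW = c(0, -0.20, 1.10),
  L_WRIST = c(0, 0.21, 0.85), R_WRIST = c(0, -0.21, 0.85),
  L_ASIS = c(0.05, 0.12, 1.00), R_ASIS = c(0.05, -0.12, 1.00),
  L_HIP = c(0, 0.09, 0.92), R_HIP = c(0, -0.09, 0.92),
  L_KNEE = c(0, 0.10, 0.50), R_KNEE = c(0, -0.10, 0.50),
  L_ANKLE = c(0, 0.11, 0.08), R_ANKLE = c(0, -0.11, 0.08),
  L_HEEL = c(-0.06, 0.11, 0.05), R_HEEL = c(-0.06, -0.11, 0.05),
  L_TOE = c(0.12, 0.11, 0.03), R_TOE = c(0.12, -0.11, 0.03)
)

# A motion is base + drift*t + sum of harmonics c*cos(w*tau) + s*sin(w*tau),
# tau = t - hs_phase, w = 2*pi*mult*f. Harmonics are stored as a matrix
# with columns axis, mult, c, s so linear combinations stay closed-form.
new_motion <- function(base, drift = c(0, 0, 0)) {
  list(base = base, drift = drift,
       harm = matrix(numeric(0), 0L, 4L,
                     dimnames = list(NULL, c("axis", "mult", "c", "s"))))
}

add_harm <- function(motion, axis, mult, amp, phase = 0, const = 0) {
  motion$base[axis] <- motion$base[axis] + const
  if (amp != 0) {
    motion$harm <- rbind(motion$harm,
                         c(axis, mult, amp * cos(phase), -amp * sin(phase)))
  }
  motion
}

eval_motion <- function(motion, t, f, hs_phase, deriv = 0L) {
  t <- as.numeric(t)
  out <- matrix(0, length(t), 3L, dimnames = list(NULL, c("X", "Y", "Z")))
  if (deriv == 0L) {
    out <- out + rep(motion$base, each = length(t)) +
      outer(t, motion$drift)
  } else if (deriv == 1L) {
    out <- out + rep(motion$drift, each = length(t))
  }
  h <- motion$harm
  tau <- t - hs_phase
  for (i in seq_len(nrow(h))) {
    w <- 2 * pi * h[i, "mult"] * f
    th <- w * tau
    v <- switch(as.character(deriv),
                "0" = h[i, "c"] * cos(th) + h[i, "s"] * sin(th),
                "1" = w * (-h[i, "c"] * sin(th) + h[i, "s"] * cos(th)),
                "2" = -w^2 * (h[i, "c"] * cos(th) + h[i, "s"] * sin(th)))
    out[, h[i, "axis"]] <- out[, h[i, "axis"]] + v
  }
  out
}

# Weighted linear combination of motions (same f / hs_phase assumed).
combine_motions <- function(motions, weights) {
  base <- Reduce(`+`, Map(function(m, w) w * m$base, motions, weights))
  drift <- Reduce(`+`, Map(function(m, w) w * m$drift, motions, weights))
  harm <- do.call(rbind, Map(function(m, w) {
    h <- m$harm
    h[, c("c", "s")] <- h[, c("c", "s"), drop = FALSE] * w
    h
  }, motions, weights))
  out <- new_motion(base, drift)
  if (!is.null(harm) && nrow(harm)) {
    key <- paste(harm[, "axis"], harm[, "mult"])
    cc <- rowsum(harm[, "c"], key)
    ss <- rowsum(harm[, "s"], key)
    ax <- as.numeric(vapply(strsplit(rownames(cc), " "), `[`, "", 1L))
    mu <- as.numeric(vapply(strsplit(rownames(cc), " "), `[`, "", 2L))
    out$harm <- cbind(axis = ax, mult = mu, c = as.numeric(cc), s = as.numeric(ss))
    colnames(out$harm) <- c("axis", "mult", "c", "s")
  }
  out
}

# Build the closed-form motion of every marker for one trial.
marker_motions <- function(config) {
  osc <- config$osc
  ph <- .phase
  motions <- list()
  for (nm in names(.marker_bases)) {
    m <- new_motion(.marker_bases[[nm]], drift = c(config$walking_speed, 0, 0))
    # whole-body common translation
    m <- add_harm(m, 3L, 2, osc$com_vert2, 0)
    m <- add_harm(m, 3L, 1, osc$com_vert1, 0)
    m <- add_harm(m, 1L, 2, osc$com_ap2, ph$ap2)
    m <- add_harm(m, 2L, 1, osc$com_ml1, ph$ml1)
    side <- if (startsWith(nm, "L_")) "L" else if (startsWith(nm, "R_")) "R" else ""
    # left limbs swing in antiphase to right ones; arms counter-swing legs
    leg_phase <- ph$swing + if (side == "L") pi else 0
    arm_phase <- leg_phase + pi
    if (nm %in% c("L_ASIS", "R_ASIS", "L_HIP", "R_HIP")) {
      m <- add_harm(m, 2L, 1, osc$pelvis_ml1, ph$pelvis_ml1)
      m <- add_harm(m, 1L, 2, osc$pelvis_ap2, ph$pelvis_ap2)
      m <- add_harm(m, 3L, 2, osc$pelvis_vert2, 0)
    }
    if (side != "") {
      ml_phase <- ph$limb_ml + if (side == "L") pi else 0
      swing <- switch(sub("^[LR]_", "", nm),
                      HIP = osc$swing_hip, KNEE = osc$swing_knee,
                      ANKLE = osc$swing_ankle, HEEL = osc$swing_foot,
                      TOE = osc$swing_foot, ELBOW = osc$swing_elbow,
                      WRIST = osc$swing_wrist, 0)
      if (swing != 0) {
        phase <- if (grepl("ELBOW|WRIST", nm)) arm_phase else leg_phase
        m <- add_harm(m, 1L, 1, swing, phase)
        m <- add_harm(m, 2L, 1, osc$limb_ml, ml_phase)
      }
      lift <- switch(sub("^[LR]_", "", nm),
                     HEEL = osc$lift_heel, TOE = osc$lift_toe,
                     ANKLE = osc$lift_ankle, 0)
      if (lift != 0) {
        # lift * (1 - cos) for the right foot: minimum height exactly at
        # the right heel strike; left foot shifted by half a stride
        lift_phase <- if (side == "L") 0 else pi
        m <- add_harm(m, 3L, 1, lift, lift_phase, const = lift)
      }
    }
    motions[[nm]] <- m
  }
  motions
}

# Pelvis-segment CoM motion = centroid of the four pelvis markers (the
# pelvis endpoints are mid-ASIS and mid-hip with com_ratio 0.5).
pelvis_com_motion <- function(motions) {
  combine_motions(motions[c("L_ASIS", "R_ASIS", "L_HIP", "R_HIP")],
                  rep(0.25, 4L))
}

# Per-marker weights of the whole-body CoM under a body model: segment i
# contributes (1 - r_i) * w_i to its proximal centroid markers and
# r_i * w_i to its distal ones.
com_marker_weights <- function(model) {
  w <- numeric(0)
  addw <- function(w, names, amount) {
    for (nm in names) w[nm] <- (if (nm %in% names(w)) w[[nm]] else 0) + amount
    w
  }
  for (i in seq_len(nrow(model$segments))) {
    s <- model$segments[i, ]
    p <- split_markers(s$proximal); d <- split_markers(s$distal)
    w <- addw(w, p, (1 - s$com_ratio) * s$mass_fraction / length(p))
    w <- addw(w, d, s$com_ratio * s$mass_fraction / length(d))
  }
  w
}

hs_phase_of <- function(config) 0.3 * config$stride_duration

# Realized stride duration for a subject: mean + clamped normal deviate.
subject_stride <- function(config, subject_index) {
  if (config$stride_sd <= 0) return(config$stride_duration)
  set.seed(subject_seed(config, subject_index))
  z <- stats::rnorm(1L)
  config$stride_duration + config$stride_sd * max(-3, min(3, z))
}

subject_seed <- function(config, subject_index) {
  (config$seed %% 100000L) * 10007L + as.integer(subject_index)
}

#' Closed-form whole-body CoM of the synthetic walker
#'
#' Evaluates the exact mass-weighted CoM of the noise-free generator at
#' arbitrary times, independent of any sampling. The marker motions are
#' closed-form harmonic sums, so the CoM (a fixed linear combination of
#' them under the default body model) is too.
#'
#' @param config A [gait_sim_config()].
#' @param t Times in seconds, within `[0, n_strides * stride_duration]`.
#' @param deriv Derivative order: 0 (position), 1 (velocity) or
#'   2 (acceleration).
#' @return `length(t) x 3` matrix (X, Y, Z).
#' @export
analytic_com <- function(config, t, deriv = 0L) {
  stopifnot(inherits(config, "gait_sim_config"))
  span <- config$n_strides * config$stride_duration
  if (any(t < 0 | t > span)) {
    stop(sprintf("t outside trial span [0, %g]", span), call. = FALSE)
  }
  motions <- marker_motions(config)
  w <- com_marker_weights(default_body_model())
  com_motion <- combine_motions(motions[names(w)], as.numeric(w))
  eval_motion(com_motion, t, 1 / config$stride_duration,
              hs_phase_of(config), deriv = deriv)
}

#' Tri-axial IMU series container
#'
#' @param acc `n x 3` acceleration matrix, m/s^2, columns (X, Y, Z); the
#'   vertical (Z) axis includes gravity unless corrected.
#' @param rate Sampling rate, Hz.
#' @param t0 Time of first sample, seconds.
#' @return An `imu_series` object.
#' @export
imu_series <- function(acc, rate, t0 = 0) {
  acc <- as.matrix(acc)
  stopifnot(ncol(acc) == 3L, rate > 0)
  colnames(acc) <- c("X", "Y", "Z")
  structure(list(acc = acc, rate = as.numeric(rate),
                 time = t0 + (seq_len(nrow(acc)) - 1) / rate),
            class = "imu_series")
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series> %d samples @ %g Hz (%.2f s)\n",
              nrow(x$acc), x$rate, nrow(x$acc) / x$rate))
  invisible(x)
}

#' Generate one synthetic walking trial
#'
#' Produces marker trajectories (including an `ML5` marker riding on the
#' virtual sensor), a virtual L5 IMU stream, and ground truth: the exact
#' noise-free whole-body CoM at the marker rate and the analytic right-foot
#' heel-strike times (minima of the right-heel height). The IMU channel is
#' the analytic second derivative of the pelvis-segment CoM displaced by
#' `sensor_offset`, rotated by `axis_misalignment` about the walking axis,
#' with gravity added on the sensor's vertical axis, sampled at `imu_rate`,
#' plus Gaussian noise.
#'
#' @param config A [gait_sim_config()].
#' @param subject_index Subject number; seeds noise and the subject's
#'   stride-time draw deterministically from `config$seed`.
#' @return A `gait_trial`: list with `markers`, `imu`, `truth_com`,
#'   `truth_hs`, `subject_id` and the realized `config`.
#' @export
generate_trial <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "gait_sim_config"))
  config$stride_duration <- subject_stride(config, subject_index)
  config$stride_sd <- 0
  f <- 1 / config$stride_duration
  hs0 <- hs_phase_of(config)
  span <- config$n_strides * config$stride_duration
  set.seed(subject_seed(config, subject_index) + 1L)

  motions <- marker_motions(config)
  t_mark <- seq(0, span, by = 1 / config$marker_rate)
  pelvis <- pelvis_com_motion(motions)
  ml5 <- pelvis
  ml5$base <- ml5$base + config$sensor_offset

  positions <- lapply(motions, eval_motion, t = t_mark, f = f, hs_phase = hs0)
  positions$ML5 <- eval_motion(ml5, t_mark, f, hs0)
  clean <- positions
  if (config$marker_noise_sd > 0) {
    positions <- lapply(positions, function(p) {
      p + matrix(stats::rnorm(length(p), sd = config$marker_noise_sd), nrow(p))
    })
  }
  markers <- marker_series(positions, config$marker_rate)

  w <- com_marker_weights(default_body_model())
  truth_com <- Reduce(`+`, Map(function(nm, wt) wt * clean[[nm]],
                               names(w), as.numeric(w)))

  t_imu <- seq(0, span, by = 1 / config$imu_rate)
  acc <- eval_motion(ml5, t_imu, f, hs0, deriv = 2L)
  acc[, 3L] <- acc[, 3L] + config$gravity
  ang <- config$axis_misalignment * pi / 180
  if (ang != 0) {
    # sensor frame rotated about the walking (X) axis: measured components
    # are the world vector expressed in the sensor frame
    R <- matrix(c(1, 0, 0,
                  0, cos(ang), -sin(ang),
                  0, sin(ang), cos(ang)), 3L, 3L, byrow = TRUE)
    acc <- acc %*% R  # acc %*% R == t(R^T %*% t(acc))
  }
  if (config$imu_noise_sd > 0) {
    acc <- acc + matrix(stats::rnorm(length(acc), sd = config$imu_noise_sd),
                        nrow(acc))
  }

  truth_hs <- hs0 + (seq_len(config$n_strides) - 1) * config$stride_duration

  structure(list(markers = markers,
                 imu = imu_series(acc, config$imu_rate),
                 truth_com = truth_com,
                 truth_hs = truth_hs,
                 subject_id = sprintf("S%02d", subject_index),
                 config = config),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %s: %d strides @ %.3f s, %d markers, %d IMU samples\n",
              x$subject_id, x$config$n_strides, x$config$stride_duration,
              length(x$markers$positions), nrow(x$imu$acc)))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' One trial per subject, each with a per-subject stride duration drawn
#' from `N(stride_duration, stride_sd^2)` (clamped at three SD) and a
#' subject-specific noise seed derived deterministically from the config
#' seed.
#'
#' @param config A [gait_sim_config()].
#' @return List of `gait_trial` objects, length `n_subjects`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "gait_sim_config"))
  lapply(seq_len(config$n_subjects), function(i) generate_trial(config, i))
}
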