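# Shared fixture builders; everything is generated in code at test time.

# Smooth Gaussian random curves: white noise convolved with a unit-energy
# Gaussian kernel of the requested FWHM (nodes), unit marginal variance.
smooth_gauss_curves <- function(n, q, fwhm) {
  sig <- fwhm / sqrt(8 * log(2))
  k <- dnorm(seq(-ceiling(4 * sig), ceiling(4 * sig)), sd = sig)
  k <- k / sqrt(sum(k^2))
  pad <- length(k)
  t(apply(matrix(rnorm(n * (q + 2 * pad)), n), 1, function(x) {
    y <- stats::filter(x, k, sides = 2)
    y[!is.na(y)][seq_len(q)]
  }))
}

# Null repeated-measures design: n subjects x k conditions x q nodes of
# independent smooth Gaussian curves.
null_design <- function(n = 16, k = 3, q = 101, fwhm = 10) {
  Y <- array(0, c(n, k, q))
  for (i in seq_len(n)) for (j in seq_len(k)) {
    Y[i, j, ] <- smooth_gauss_curves(1, q, fwhm)
  }
  Y
}

# Noise-free, deterministic synthetic trial shared across tests.
clean_trial_config <- function(...) {
  gait_sim_config(n_subjects = 1, marker_noise_sd = 0, imu_noise_sd = 0,
                  stride_sd = 0, seed = 1, ...)
}

# Closure simulation: the IMU stream and the whole-body CoM coincide by
# construction (no pelvis-local motion, no noise, no sensor offset); high
# sampling rates keep discretization error below the closure bounds.
closure_sim_config <- function(n_subjects = 4, seed = 5) {
  osc <- default_oscillations()
  osc$pelvis_ml1 <- 0
  osc$pelvis_ap2 <- 0
  osc$pelvis_vert2 <- 0
  gait_sim_config(n_subjects = n_subjects, marker_noise_sd = 0,
                  imu_noise_sd = 0, stride_sd = 0,
                  sensor_offset = c(0, 0, 0), marker_rate = 960,
                  imu_rate = 256, osc = osc, seed = seed)
}

# Simple rotation matrix about the axis (1 = X, 2 = Y, 3 = Z).
rot3 <- function(axis, angle) {
  c1 <- cos(angle); s1 <- sin(angle)
  R <- diag(3)
  ix <- setdiff(1:3, axis)
  R[ix[1], ix[1]] <- c1; R[ix[2], ix[2]] <- c1
  R[ix[1], ix[2]] <- -s1; R[ix[2], ix[1]] <- s1
  R
}
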