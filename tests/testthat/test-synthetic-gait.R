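test_that("identical config and seed give bit-identical trials", {
  cfg <- gait_sim_config(n_subjects = 2, seed = 7)
  expect_identical(generate_trial(cfg, 1), generate_trial(cfg, 1))
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("config invariants are enforced", {
  expect_error(gait_sim_config(marker_rate = 0), "rates")
  expect_error(gait_sim_config(stride_duration = -1), "stride_duration")
  expect_error(gait_sim_config(n_strides = 2), "n_strides")
})

test_that("noise-free IMU vertical equals analytic acceleration plus gravity", {
  # with pelvis-local and limb oscillations removed, the pelvis CoM is the
  # whole-body CoM, whose acceleration analytic_com() supplies independently
  osc <- default_oscillations()
  for (nm in c("pelvis_ml1", "pelvis_ap2", "pelvis_vert2", "swing_hip",
               "swing_knee", "swing_ankle", "swing_foot", "swing_elbow",
               "swing_wrist", "lift_heel", "lift_toe", "lift_ankle",
               "limb_ml")) osc[[nm]] <- 0
  cfg <- clean_trial_config(sensor_offset = c(0, 0, 0), osc = osc)
  tr <- generate_trial(cfg, 1)
  want <- analytic_com(tr$config, tr$imu$time, deriv = 2L)
  got <- tr$imu$acc
  got[, 3] <- got[, 3] - 9.81
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("noise-free vertical IMU mean over whole strides equals gravity", {
  cfg <- clean_trial_config(stride_duration = 1.0, n_strides = 10)
  tr <- generate_trial(cfg, 1)
  k <- 10 * 128  # commensurate sampling: integer samples per stride
  expect_lt(abs(mean(tr$imu$acc[seq_len(k), 3]) - 9.81), 1e-6)
})

test_that("heel-strike truth is evenly spaced and matches heel-height minima", {
  cfg <- clean_trial_config(n_strides = 10, stride_duration = 1.1)
  tr <- generate_trial(cfg, 1)
  expect_length(tr$truth_hs, 10)
  expect_equal(unique(round(diff(tr$truth_hs), 9)), 1.1)
  # heel height has its minima at the truth times
  hz <- tr$markers$positions$R_HEEL[, 3]
  tt <- tr$markers$time
  for (hs in tr$truth_hs[2:9]) {
    i <- which.min(abs(tt - hs))
    win <- hz[max(1, i - 60):min(length(hz), i + 60)]
    expect_lte(hz[i], min(win) + 1e-10)
  }
})

test_that("marker set covers every endpoint the default model references", {
  tr <- generate_trial(clean_trial_config(n_strides = 3), 1)
  need <- gaitcom:::model_marker_names(default_body_model())
  expect_true(all(need %in% names(tr$markers$positions)))
  expect_true("ML5" %in% names(tr$markers$positions))
})

test_that("analytic_com degenerates to uniform progression without oscillation", {
  cfg <- clean_trial_config(osc = default_oscillations(scale = 0))
  ts <- c(0, 0.7, 1.9, 3.2)
  com <- analytic_com(cfg, ts)
  expect_equal(com[, 1] - com[1, 1], cfg$walking_speed * ts, tolerance = 1e-12)
  expect_equal(diff(range(com[, 2])), 0)
  expect_equal(diff(range(com[, 3])), 0)
})

test_that("analytic_com is stride-periodic up to the forward progression", {
  cfg <- clean_trial_config()
  T <- cfg$stride_duration
  a <- analytic_com(cfg, 0.4)
  b <- analytic_com(cfg, 0.4 + T)
  expect_equal(b[1] - a[1], cfg$walking_speed * T, tolerance = 1e-10)
  expect_equal(a[2:3], b[2:3], tolerance = 1e-10)
  expect_error(analytic_com(cfg, -0.5), "span")
})

test_that("analytic_com equals a brute-force sum over the 13 segment CoMs", {
  cfg <- clean_trial_config()
  tr <- generate_trial(cfg, 1)
  t_probe <- c(0.37, 2.11, 5.55)
  frames <- round(t_probe * cfg$marker_rate) + 1
  bm <- default_body_model()
  for (j in seq_along(t_probe)) {
    t_exact <- tr$markers$time[frames[j]]
    brute <- c(0, 0, 0)
    for (i in seq_len(nrow(bm$segments))) {
      s <- bm$segments[i, ]
      brute <- brute + s$mass_fraction *
        segment_com(s, tr$markers, frames[j])
    }
    expect_equal(unname(analytic_com(tr$config, t_exact)[1, ]), unname(brute),
                 tolerance = 1e-9)
  }
})

test_that("cohort generation respects the stride-time distribution", {
  cfg <- gait_sim_config(n_subjects = 16, seed = 3)
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 16)
  expect_length(unique(vapply(cohort, `[[`, "", "subject_id")), 16)

  cfg0 <- gait_sim_config(n_subjects = 5, stride_sd = 0, seed = 3)
  strides <- vapply(generate_cohort(cfg0), function(t) t$config$stride_duration, 0)
  expect_equal(unique(strides), cfg0$stride_duration)

  cfg2 <- gait_sim_config(n_subjects = 200, stride_sd = 0.05, seed = 9,
                          n_strides = 3)
  strides2 <- vapply(generate_cohort(cfg2), function(t) t$config$stride_duration, 0)
  expect_gt(sd(strides2), 0.04)
  expect_lt(sd(strides2), 0.06)
})

test_that("axis misalignment rotates the measured specific force", {
  ang <- 5
  cfg0 <- clean_trial_config(n_strides = 3)
  cfg1 <- clean_trial_config(n_strides = 3, axis_misalignment = ang)
  a0 <- generate_trial(cfg0, 1)$imu$acc   # world-frame specific force
  a1 <- generate_trial(cfg1, 1)$imu$acc
  R <- rot3(1, ang * pi / 180)
  expect_equal(a1, a0 %*% R, tolerance = 1e-12, ignore_attr = TRUE)
})
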