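test_that("default body model has 13 segments with unit total mass", {
  bm <- default_body_model()
  expect_s3_class(bm, "body_model")
  expect_equal(nrow(bm$segments), 13)
  expect_equal(sum(bm$segments$mass_fraction), 1, tolerance = 1e-9)
  expect_setequal(
    bm$segments$name,
    c("head_neck", "trunk", "pelvis",
      "upper_arm_l", "upper_arm_r", "forearm_hand_l", "forearm_hand_r",
      "thigh_l", "thigh_r", "shank_l", "shank_r", "foot_l", "foot_r"))
  # paired segments share anthropometrics
  segs <- bm$segments
  for (base in c("upper_arm", "forearm_hand", "thigh", "shank", "foot")) {
    l <- segs[segs$name == paste0(base, "_l"), ]
    r <- segs[segs$name == paste0(base, "_r"), ]
    expect_equal(l$mass_fraction, r$mass_fraction)
    expect_equal(l$com_ratio, r$com_ratio)
  }
})

test_that("body_model validates its invariants", {
  segs <- default_body_model()$segments
  bad <- segs; bad$mass_fraction[1] <- bad$mass_fraction[1] + 0.01
  expect_error(body_model(bad), "sum to 1")
  bad <- segs; bad$com_ratio[2] <- 1.2
  expect_error(body_model(bad), "com_ratio")
  bad <- segs; bad$mass_fraction[3] <- -bad$mass_fraction[3]
  expect_error(body_model(bad), "positive|sum")
})

test_that("segment_com interpolates between endpoint centroids", {
  mk <- marker_series(list(P = rbind(c(0, 0, 0)), D = rbind(c(1, 0, 0))), 100)
  seg <- list(proximal = "P", distal = "D", com_ratio = 0.5)
  expect_equal(unname(segment_com(seg, mk, 1)), c(0.5, 0, 0))
  seg$com_ratio <- 0
  expect_equal(unname(segment_com(seg, mk, 1)), c(0, 0, 0))
  # affine point against independent scalar arithmetic
  mk2 <- marker_series(list(P = rbind(c(1, 2, 3)), D = rbind(c(4, 8, 9))), 100)
  seg2 <- list(proximal = "P", distal = "D", com_ratio = 0.433)
  want <- c(1 + 0.433 * (4 - 1), 2 + 0.433 * (8 - 2), 3 + 0.433 * (9 - 3))
  expect_equal(unname(segment_com(seg2, mk2, 1)), want, tolerance = 1e-12)
  # centroid endpoints
  mk3 <- marker_series(list(P1 = rbind(c(0, 0, 0)), P2 = rbind(c(2, 0, 0)),
                            D = rbind(c(1, 4, 0))), 100)
  seg3 <- list(proximal = "P1,P2", distal = "D", com_ratio = 0.25)
  expect_equal(unname(segment_com(seg3, mk3, 1)), c(1, 1, 0))
})

test_that("missing markers raise a named data error", {
  mk <- marker_series(list(P = rbind(c(0, 0, 0))), 100)
  seg <- list(proximal = "P", distal = "NOPE", com_ratio = 0.5)
  expect_error(segment_com(seg, mk, 1), "NOPE")
  expect_error(segment_com(seg, mk, 7), "frame")
})

test_that("whole_body_com matches toy symmetry and normalization cases", {
  two_seg <- body_model(data.frame(
    name = c("a", "b"), proximal = c("A1", "B1"), distal = c("A2", "B2"),
    mass_fraction = c(0.5, 0.5), com_ratio = c(0.5, 0.5)))
  mk <- marker_series(list(A1 = rbind(c(-1, 0, 0)), A2 = rbind(c(1, 0, 0)),
                           B1 = rbind(c(0, 0, 0)), B2 = rbind(c(2, 0, 0))), 100)
  expect_equal(unname(whole_body_com(two_seg, mk)$com[1, ]), c(0.5, 0, 0))

  # all segment CoMs at the same point p -> CoM = p (fractions sum to 1)
  p <- c(0.3, -0.2, 1.1)
  pos <- lapply(model_names <- gaitcom:::model_marker_names(default_body_model()),
                function(nm) rbind(p))
  names(pos) <- model_names
  mk2 <- marker_series(pos, 100)
  expect_equal(unname(whole_body_com(default_body_model(), mk2)$com[1, ]), p,
               tolerance = 1e-12)
})

test_that("CoM is equivariant under translation and rotation", {
  tr <- generate_trial(clean_trial_config(n_strides = 3), 1)
  mk <- tr$markers
  sub <- lapply(mk$positions, function(p) p[1:40, , drop = FALSE])
  mk <- marker_series(sub, mk$rate)
  bm <- default_body_model()
  base <- whole_body_com(bm, mk)$com

  v <- c(1.5, -2.0, 0.25)
  shifted <- marker_series(lapply(mk$positions, function(p) sweep(p, 2, v, "+")),
                           mk$rate)
  expect_equal(whole_body_com(bm, shifted)$com, sweep(base, 2, v, "+"),
               tolerance = 1e-12)

  R <- rot3(3, 0.7) %*% rot3(1, -0.3)
  rotated <- marker_series(lapply(mk$positions, function(p) p %*% t(R)), mk$rate)
  expect_equal(whole_body_com(bm, rotated)$com, base %*% t(R),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("whole_body_com equals a brute-force per-frame loop", {
  set.seed(42)
  bm <- default_body_model()
  nms <- gaitcom:::model_marker_names(bm)
  pos <- lapply(nms, function(nm) matrix(rnorm(30 * 3), 30))
  names(pos) <- nms
  mk <- marker_series(pos, 50)
  fast <- whole_body_com(bm, mk)$com

  slow <- matrix(0, 30, 3)
  for (f in 1:30) {
    acc <- c(0, 0, 0)
    for (i in seq_len(nrow(bm$segments))) {
      s <- bm$segments[i, ]
      pm <- strsplit(s$proximal, ",")[[1]]
      dm <- strsplit(s$distal, ",")[[1]]
      pr <- colMeans(do.call(rbind, lapply(pm, function(m) mk$positions[[m]][f, ])))
      di <- colMeans(do.call(rbind, lapply(dm, function(m) mk$positions[[m]][f, ])))
      acc <- acc + s$mass_fraction * (pr + s$com_ratio * (di - pr))
    }
    slow[f, ] <- acc
  }
  expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-12)
})

test_that("noise-free synthetic trial reproduces the generator CoM truth", {
  tr <- generate_trial(clean_trial_config(), 1)
  com <- whole_body_com(default_body_model(), tr$markers)$com
  expect_lt(max(abs(com - tr$truth_com)), 1e-9)
})

test_that("body model YAML round trip preserves the table", {
  path <- tempfile(fileext = ".yaml")
  bm <- default_body_model()
  write_body_model(bm, path)
  back <- read_body_model(path)
  expect_equal(back$segments, bm$segments)
})
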