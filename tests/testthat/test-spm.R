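test_that("F field vanishes when conditions are identical", {
  set.seed(1)
  base <- matrix(rnorm(8 * 20), 8)
  Y <- array(0, c(8, 3, 20))
  for (j in 1:3) Y[, j, ] <- base
  an <- rm_anova_field(Y)
  expect_equal(an$F, rep(0, 20))
  expect_equal(an$dof, c(2, 14))
})

test_that("zero residual variance with a condition effect is flagged", {
  base <- matrix(rep(seq_len(20), each = 6), 6)
  Y <- array(0, c(6, 3, 20))
  for (j in 1:3) Y[, j, ] <- base + (j == 3) * 0.5
  an <- rm_anova_field(Y)
  expect_true(all(an$degenerate))
  expect_true(all(is.infinite(an$F)))
})

test_that("single-node F matches a hand-coded sums-of-squares decomposition", {
  set.seed(2)
  Y <- array(rnorm(4 * 3 * 7), c(4, 3, 7))
  an <- rm_anova_field(Y)
  for (node in c(1, 4, 7)) {
    tab <- Y[, , node]                       # 4 subjects x 3 conditions
    n <- nrow(tab); k <- ncol(tab)
    grand <- mean(tab)
    ss_cond <- n * sum((colMeans(tab) - grand)^2)
    ss_subj <- k * sum((rowMeans(tab) - grand)^2)
    ss_tot <- sum((tab - grand)^2)
    ss_err <- ss_tot - ss_cond - ss_subj
    Fref <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
    expect_lt(abs(an$F[node] - Fref), 1e-10)
  }
})

test_that("F field agrees with aov's repeated-measures decomposition", {
  set.seed(3)
  Y <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  an <- rm_anova_field(Y)
  node <- 2
  df <- data.frame(y = as.vector(Y[, , node]),
                   s = factor(rep(1:5, 3)), cond = factor(rep(1:3, each = 5)))
  fit <- summary(aov(y ~ cond + Error(s / cond), df))
  Fref <- fit[["Error: s:cond"]][[1]]["cond", "F value"]
  expect_equal(an$F[node], Fref, tolerance = 1e-10)
})

test_that("squared paired-t field equals the two-condition F field", {
  set.seed(4)
  Y <- null_design(n = 10, k = 2, q = 31, fwhm = 6)
  tfield <- posthoc_paired_t(Y, c(1, 2))$statistic
  Ffield <- rm_anova_field(Y)$F
  expect_lt(max(abs(tfield^2 - Ffield)), 1e-9)
  expect_true(all(Ffield >= 0))
})

test_that("white-noise residual smoothness is near one node", {
  set.seed(5)
  est <- replicate(1000, estimate_fwhm(matrix(rnorm(20 * 101), 20)))
  expect_gte(median(est), 0.8)
  expect_lte(median(est), 1.5)
})

test_that("known smoothing kernels are recovered within 15%", {
  set.seed(6)
  est <- replicate(100, estimate_fwhm(smooth_gauss_curves(20, 101, 10)))
  expect_lt(abs(median(est) - 10) / 10, 0.15)
})

test_that("constant residual curves flag infinite smoothness", {
  res <- matrix(rep(c(1, 2, 3, 4), 25), 4)  # constant along nodes
  res <- matrix(rep(c(1, 2, 3, 4), each = 25), 4, byrow = TRUE)
  out <- estimate_fwhm(res - rowMeans(res))
  expect_true(is.infinite(out))
  expect_true(isTRUE(attr(out, "degenerate")))
})

test_that("RFT threshold reduces to the pointwise quantile at zero resels", {
  expect_equal(rft_threshold(0.05, c(2, 30), 0), qf(0.95, 2, 30),
               tolerance = 1e-7)
  expect_equal(rft_threshold(0.025, c(1, 15), 0, stat = "t"),
               qt(0.975, 15), tolerance = 1e-7)
  # threshold grows strictly with field roughness
  u <- vapply(c(0, 2, 5, 10, 20), function(r) rft_threshold(0.05, c(2, 30), r),
              numeric(1))
  expect_true(all(diff(u) > 0))
  expect_error(rft_threshold(0, c(2, 30), 1), "alpha")
})

test_that("cluster extraction matches a brute-force scan", {
  field <- rep(0, 101)
  field[11:21] <- 10
  field[71:76] <- 8
  cl <- find_clusters(field, 5)
  expect_equal(cl$start_pct, c(10, 70))
  expect_equal(cl$end_pct, c(20, 75))
  expect_equal(nrow(find_clusters(rep(1, 101), 5)), 0)

  set.seed(7)
  for (rep in 1:20) {
    f <- as.numeric(smooth_gauss_curves(1, 101, 5))
    u <- quantile(f, 0.8)
    cl <- find_clusters(f, u)
    # brute-force: walk the field sample by sample
    runs <- list(); inrun <- FALSE
    for (i in seq_along(f)) {
      if (f[i] > u && !inrun) { start <- i; inrun <- TRUE }
      if ((f[i] <= u || i == length(f)) && inrun) {
        end <- if (f[i] <= u) i - 1 else i
        runs[[length(runs) + 1]] <- c(start, end); inrun <- FALSE
      }
    }
    ref <- do.call(rbind, runs)
    expect_equal(cl$start_pct, (ref[, 1] - 1) * 100 / 100)
    expect_equal(cl$end_pct, (ref[, 2] - 1) * 100 / 100)
  }
})

test_that("RFT threshold agrees with the permutation oracle on smooth nulls", {
  set.seed(8)
  Y <- null_design(n = 16, k = 3, q = 101, fwhm = 10)
  an <- rm_anova_field(Y)
  fwhm <- estimate_fwhm(an$residuals)
  u_rft <- rft_threshold(0.05, an$dof, (101 - 1) / fwhm)
  perm <- permutation_threshold(Y, n_perm = 1000, alpha = 0.05, seed = 99)
  expect_lt(abs(u_rft - perm$threshold) / perm$threshold, 0.10)
  # permutation threshold is by definition the (1 - alpha) quantile
  expect_equal(perm$threshold, quantile(perm$max_dist, 0.95, names = FALSE))
  # deterministic under a fixed seed
  perm2 <- permutation_threshold(Y, n_perm = 200, alpha = 0.05, seed = 42)
  perm3 <- permutation_threshold(Y, n_perm = 200, alpha = 0.05, seed = 42)
  expect_identical(perm2, perm3)
  expect_error(permutation_threshold(Y, n_perm = 10), "100")
})

test_that("post-hoc comparisons use the Bonferroni-corrected alpha", {
  expect_equal(round(0.05 / 3, 3), 0.017)
  set.seed(9)
  Y <- null_design(n = 8, k = 3, q = 31, fwhm = 8)
  ph <- posthoc_paired_t(Y, c(1, 2))
  expect_equal(ph$alpha, 0.017)
  expect_true(ph$two_tailed)
  # identical conditions: flat zero t field, no clusters
  Y[, 2, ] <- Y[, 1, ]
  ph0 <- posthoc_paired_t(Y, c(1, 2))
  expect_true(all(ph0$statistic == 0))
  expect_equal(nrow(ph0$clusters), 0)
})

test_that("a localized condition offset is detected with high power", {
  set.seed(10)
  hits <- 0
  window <- 1:11   # nodes 0-10 of the cycle
  for (r in 1:200) {
    Y <- null_design(n = 16, k = 2, q = 101, fwhm = 10)
    Y[, 2, window] <- Y[, 2, window] + 2   # effect = 2 x residual-scale SD
    ph <- posthoc_paired_t(Y, c(1, 2))
    cl <- ph$clusters
    if (nrow(cl) && any(cl$start_pct <= 10 & cl$end_pct >= 0)) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.90)
})

test_that("omnibus and post-hoc clusters cohere for an injected effect", {
  set.seed(11)
  Y <- null_design(n = 16, k = 3, q = 101, fwhm = 10)
  Y[, 3, 40:60] <- Y[, 3, 40:60] + 2.5
  om <- spm_rm_anova(Y)
  expect_gt(nrow(om$clusters), 0)
  ph <- posthoc_paired_t(Y, c(1, 3))
  expect_gt(nrow(ph$clusters), 0)
  overlap <- function(cl) any(cl$start_pct <= 60 & cl$end_pct >= 40)
  expect_true(overlap(om$clusters))
  expect_true(overlap(ph$clusters))
})
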