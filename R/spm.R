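#' Pointwise one-way repeated-measures ANOVA field
#'
#' At each node of the gait cycle independently, partitions the variance of
#' a complete balanced subject x condition design into condition, subject
#' and residual (condition x subject interaction) components and forms
#' `F = MS_condition / MS_residual` with `(k - 1, (k - 1)(n - 1))` degrees
#' of freedom. The centred residual field is returned for smoothness
#' estimation.
#'
#' @param Y `n_subjects x n_conditions x n_nodes` array.
#' @return List: `F` (length `n_nodes` field), `dof` (numerator,
#'   denominator), `residuals` (`(n * k) x n_nodes` matrix of residual
#'   curves), `degenerate` (logical field: nodes where the residual mean
#'   square vanishes, F reported as `Inf` there).
#' @export
rm_anova_field <- function(Y) {
  d <- dim(Y)
  if (length(d) != 3L) stop("Y must be subjects x conditions x nodes", call. = FALSE)
  n <- d[1L]; k <- d[2L]; q <- d[3L]
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (k < 2L) stop("need at least 2 conditions", call. = FALSE)
  grand <- apply(Y, 3L, mean)                       # q
  cond_m <- apply(Y, c(2L, 3L), mean)               # k x q
  subj_m <- apply(Y, c(1L, 3L), mean)               # n x q
  ss_cond <- n * rowSums((t(cond_m) - grand)^2)     # sum over the k conditions
  resid <- array(0, d)
  for (i in seq_len(n)) for (j in seq_len(k)) {
    resid[i, j, ] <- Y[i, j, ] - subj_m[i, ] - cond_m[j, ] + grand
  }
  ss_err <- apply(resid^2, 3L, sum)
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  scale <- mean(abs(Y)) + .Machine$double.eps
  degenerate <- ms_err <= (1e-24 * scale^2)
  f <- ifelse(degenerate, ifelse(ms_cond > 0, Inf, 0), ms_cond / ms_err)
  res_mat <- matrix(aperm(resid, c(3L, 1L, 2L)), nrow = n * k, byrow = TRUE)
  list(F = as.numeric(f), dof = c(df1, df2), residuals = res_mat,
       degenerate = degenerate)
}

#' Residual-field smoothness (FWHM)
#'
#' Estimates the full width at half maximum of the Gaussian kernel whose
#' smoothing would reproduce the observed residual roughness: residual
#' curves are normalized pointwise by their root sum of squares, the mean
#' squared node-to-node gradient is computed, and
#' `FWHM = sqrt(4 log 2 / <grad^2>)` (averaged as resels-per-node, the
#' standard 1D random-field estimator).
#'
#' @param residuals `m x n_nodes` matrix of residual curves.
#' @return FWHM in nodes; `Inf` (with attribute `degenerate = TRUE`) when
#'   the residuals are constant along the field.
#' @export
estimate_fwhm <- function(residuals) {
  residuals <- as.matrix(residuals)
  if (ncol(residuals) < 2L || nrow(residuals) < 2L) {
    stop("need >= 2 nodes and >= 2 residual curves", call. = FALSE)
  }
  ssq <- colSums(residuals^2)
  if (all(ssq <= .Machine$double.eps^2)) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  Rn <- sweep(residuals, 2L, sqrt(ssq + .Machine$double.eps), "/")
  g2 <- colSums(t(diff(t(Rn)))^2)     # forward differences between nodes
  if (all(g2 <= 0)) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  resels_per_node <- mean(sqrt(g2 / (4 * log(2))))
  1 / resels_per_node
}

# 1D Euler-characteristic density of t and F random fields at threshold u,
# in resel units (Worsley's unit-roughness form).
ec_density_1d <- function(u, dof, stat = c("F", "t")) {
  stat <- match.arg(stat)
  if (stat == "t") {
    v <- dof[length(dof)]
    sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / v)^(-(v - 1) / 2)
  } else {
    # Worsley's 1D F-field density; its (2*pi)^(-1/2) coefficient makes the
    # k = 1 case equal twice the one-tailed t density, as F = t^2 requires
    k <- dof[1L]; v <- dof[2L]
    sqrt(4 * log(2) / (2 * pi)) *
      exp(lgamma((v + k - 1) / 2) - lgamma(v / 2) - lgamma(k / 2)) *
      sqrt(2) * (k * u / v)^((k - 1) / 2) * (1 + k * u / v)^(-(v + k - 2) / 2)
  }
}

# Tail probability of the statistic at a point (the boundary term).
point_tail <- function(u, dof, stat) {
  if (stat == "t") stats::pt(u, dof[length(dof)], lower.tail = FALSE)
  else stats::pf(u, dof[1L], dof[2L], lower.tail = FALSE)
}

#' Random-field-theory critical threshold for a 1D statistic field
#'
#' Solves for the smallest threshold `u` at which the expected number of
#' suprathreshold features of a smooth 1D field --- the Euler-characteristic
#' density times the resel count, plus the point (boundary) tail
#' probability --- equals `alpha`. In the zero-resel limit this reduces to
#' the ordinary single-comparison critical value.
#'
#' @param alpha Family-wise error rate (per tail for two-tailed t use).
#' @param dof Degrees of freedom: `c(df1, df2)` for F, denominator df
#'   (possibly as `c(1, df)`) for t.
#' @param resels Resel count (field extent in nodes / FWHM).
#' @param stat `"F"` or `"t"`.
#' @return Critical statistic value (solved to 1e-8).
#' @export
rft_threshold <- function(alpha, dof, resels, stat = c("F", "t")) {
  stat <- match.arg(stat)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (resels < 0) stop("resels must be >= 0", call. = FALSE)
  expected <- function(u) point_tail(u, dof, stat) +
    resels * ec_density_1d(u, dof, stat)
  lo <- if (stat == "t") stats::qt(1 - alpha, dof[length(dof)])
        else stats::qf(1 - alpha, dof[1L], dof[2L])
  lo <- max(lo, 1e-8)
  hi <- lo
  for (i in 1:60) {
    if (expected(hi) < alpha) break
    hi <- hi * 2
    if (i == 60L) stop("RFT threshold search failed to bracket", call. = FALSE)
  }
  if (expected(lo) <= alpha) return(lo)
  stats::uniroot(function(u) expected(u) - alpha, c(lo, hi),
                 tol = 1e-8)$root
}

#' Suprathreshold clusters of a 1D field
#'
#' Maximal runs of consecutive nodes where the field exceeds the threshold,
#' reported in percent of the gait cycle.
#'
#' @param field Numeric vector over the cycle nodes.
#' @param threshold Scalar threshold.
#' @return data.frame with `start_pct`, `end_pct`, `n_nodes`, `max_stat`
#'   (zero rows when nothing exceeds the threshold).
#' @export
find_clusters <- function(field, threshold) {
  q <- length(field)
  above <- field > threshold
  if (!any(above)) {
    return(data.frame(start_pct = numeric(0), end_pct = numeric(0),
                      n_nodes = integer(0), max_stat = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  pct <- 100 / (q - 1L)
  data.frame(
    start_pct = (starts[keep] - 1L) * pct,
    end_pct = (ends[keep] - 1L) * pct,
    n_nodes = r$lengths[keep],
    max_stat = vapply(keep, function(i) max(field[starts[i]:ends[i]]), numeric(1))
  )
}

# RFT cluster p-value: expected number of features whose statistic exceeds
# the cluster's maximum, capped at 1.
cluster_p_rft <- function(max_stat, dof, resels, stat) {
  pmin(1, point_tail(max_stat, dof, stat) +
         resels * ec_density_1d(max_stat, dof, stat))
}

#' One-dimensional SPM repeated-measures ANOVA
#'
#' Runs [rm_anova_field()] over the cycle nodes, estimates residual
#' smoothness, computes the random-field-theory critical threshold at
#' `alpha`, and reports suprathreshold clusters in percent of the gait
#' cycle. When the residual field is degenerate (e.g. numerically identical
#' subjects), inference is suppressed and the result is flagged.
#'
#' @param Y `n_subjects x n_conditions x n_nodes` array (typically one
#'   direction of a normalized [cycle_set()]).
#' @param alpha Family-wise error rate.
#' @return An `spm_field` object: `statistic` field, `stat` ("F"), `dof`,
#'   `fwhm`, `resels`, `threshold`, `clusters`, `alpha`, `degenerate`.
#' @export
spm_rm_anova <- function(Y, alpha = 0.05) {
  an <- rm_anova_field(Y)
  q <- dim(Y)[3L]
  fwhm <- estimate_fwhm(an$residuals)
  degenerate <- any(an$degenerate) || !is.finite(fwhm)
  if (degenerate) {
    res <- list(statistic = an$F, stat = "F", dof = an$dof, fwhm = fwhm,
                resels = 0, threshold = NA_real_,
                clusters = find_clusters(an$F, Inf), alpha = alpha,
                two_tailed = FALSE, degenerate = TRUE)
    return(structure(res, class = "spm_field"))
  }
  resels <- (q - 1) / fwhm
  u <- rft_threshold(alpha, an$dof, resels, stat = "F")
  cl <- find_clusters(an$F, u)
  if (nrow(cl)) cl$p <- cluster_p_rft(cl$max_stat, an$dof, resels, "F")
  structure(list(statistic = an$F, stat = "F", dof = an$dof, fwhm = fwhm,
                 resels = resels, threshold = u, clusters = cl,
                 alpha = alpha, two_tailed = FALSE, degenerate = FALSE),
            class = "spm_field")
}

#' Post-hoc paired-t SPM field for a condition pair
#'
#' Pointwise paired t statistic (`n - 1` degrees of freedom) between two
#' conditions, thresholded by random field theory at the Bonferroni-
#' corrected post-hoc level (0.017 for three pairwise comparisons of three
#' conditions). Two-tailed by default: the threshold is solved at
#' `alpha / 2` per tail and applied to `|t|`.
#'
#' @param Y `n_subjects x n_conditions x n_nodes` array.
#' @param pair Indices or names (into the condition dimension) of the two
#'   conditions to compare.
#' @param alpha Post-hoc alpha (default 0.017).
#' @param two_tailed Threshold `|t|` at `alpha/2` per tail (default TRUE).
#' @return An `spm_field` with `stat = "t"`.
#' @export
posthoc_paired_t <- function(Y, pair, alpha = 0.017, two_tailed = TRUE) {
  d <- dim(Y)
  if (length(d) != 3L) stop("Y must be subjects x conditions x nodes", call. = FALSE)
  D <- Y[, pair[1L], ] - Y[, pair[2L], ]           # n x q differences
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  mbar <- colMeans(D)
  s <- apply(D, 2L, stats::sd)
  degenerate_nodes <- s <= 1e-12 * (mean(abs(Y)) + .Machine$double.eps)
  tfield <- ifelse(degenerate_nodes,
                   ifelse(abs(mbar) > 0, Inf * sign(mbar), 0),
                   mbar / (s / sqrt(n)))
  resid <- sweep(D, 2L, mbar)
  fwhm <- estimate_fwhm(resid)
  dof <- c(1L, n - 1L)
  degenerate <- any(degenerate_nodes) || !is.finite(fwhm)
  if (degenerate) {
    return(structure(list(statistic = tfield, stat = "t", dof = dof,
                          fwhm = fwhm, resels = 0, threshold = NA_real_,
                          clusters = find_clusters(abs(tfield), Inf),
                          alpha = alpha, two_tailed = two_tailed,
                          degenerate = TRUE),
                     class = "spm_field"))
  }
  if (n < 3L) {
    # one denominator df: the t-field EC density does not decay with u, so
    # no finite RFT threshold exists
    warning("fewer than 3 subjects: paired-t RFT inference suppressed",
            call. = FALSE)
    return(structure(list(statistic = tfield, stat = "t", dof = dof,
                          fwhm = fwhm, resels = (length(mbar) - 1) / fwhm,
                          threshold = NA_real_,
                          clusters = find_clusters(abs(tfield), Inf),
                          alpha = alpha, two_tailed = two_tailed,
                          degenerate = TRUE),
                     class = "spm_field"))
  }
  q <- length(mbar)
  resels <- (q - 1) / fwhm
  a <- if (two_tailed) alpha / 2 else alpha
  u <- rft_threshold(a, dof, resels, stat = "t")
  cl <- find_clusters(if (two_tailed) abs(tfield) else tfield, u)
  if (nrow(cl)) cl$p <- pmin(1, (1 + two_tailed) *
                               cluster_p_rft(cl$max_stat, dof, resels, "t"))
  structure(list(statistic = tfield, stat = "t", dof = dof, fwhm = fwhm,
                 resels = resels, threshold = u, clusters = cl,
                 alpha = alpha, two_tailed = two_tailed, degenerate = FALSE),
            class = "spm_field")
}

#' Permutation oracle for the field-maximum null distribution
#'
#' Permutes condition labels independently within each subject, recomputes
#' the F field, and records the field maximum; the critical threshold is
#' the `1 - alpha` quantile of that null distribution. Used to validate the
#' random-field-theory threshold.
#'
#' @param Y `n_subjects x n_conditions x n_nodes` array.
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Family-wise error rate.
#' @param seed Integer seed for the permutation stream.
#' @return List: `threshold`, `max_dist` (permutation field maxima),
#'   `n_perm`.
#' @export
permutation_threshold <- function(Y, n_perm = 1000L, alpha = 0.05,
                                  seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  d <- dim(Y)
  n <- d[1L]; k <- d[2L]
  if (factorial(k)^n < 1 / alpha) {
    warning("too few distinct permutations for the requested alpha",
            call. = FALSE)
  }
  set.seed(seed)
  maxes <- vapply(seq_len(n_perm), function(p) {
    Yp <- Y
    for (i in seq_len(n)) Yp[i, , ] <- Y[i, sample.int(k), ]
    max(rm_anova_field(Yp)$F)
  }, numeric(1))
  list(threshold = stats::quantile(maxes, 1 - alpha, names = FALSE,
                                   type = 7),
       max_dist = maxes, n_perm = n_perm)
}

#' @export
print.spm_field <- function(x, ...) {
  cat(sprintf("<spm_field> SPM{%s} over %d nodes, dof (%s)\n",
              x$stat, length(x$statistic), paste(x$dof, collapse = ", ")))
  if (x$degenerate) {
    cat("  degenerate residual field: inference suppressed\n")
  } else {
    cat(sprintf("  FWHM %.2f nodes, %.2f resels, RFT threshold %.3f at alpha %g%s\n",
                x$fwhm, x$resels, x$threshold, x$alpha,
                if (x$two_tailed) " (two-tailed)" else ""))
    if (nrow(x$clusters)) {
      for (i in seq_len(nrow(x$clusters))) {
        cat(sprintf("  cluster %d: %.0f-%.0f%% of cycle (max %.2f, p = %.4f)\n",
                    i, x$clusters$start_pct[i], x$clusters$end_pct[i],
                    x$clusters$max_stat[i], x$clusters$p[i]))
      }
    } else cat("  no suprathreshold clusters\n")
  }
  invisible(x)
}

#' @export
plot.spm_field <- function(x, ...) {
  pct <- seq(0, 100, length.out = length(x$statistic))
  y <- if (x$two_tailed) abs(x$statistic) else x$statistic
  graphics::plot(pct, y, type = "l", xlab = "% gait cycle",
                 ylab = sprintf("SPM{%s}", x$stat), ...)
  if (!x$degenerate) {
    graphics::abline(h = x$threshold, lty = 2, col = "red3")
    if (nrow(x$clusters)) {
      for (i in seq_len(nrow(x$clusters))) {
        graphics::rect(x$clusters$start_pct[i], graphics::par("usr")[3L],
                       x$clusters$end_pct[i], graphics::par("usr")[4L],
                       col = grDevices::grey(0.5, 0.25), border = NA)
      }
    }
  }
  invisible(x)
}
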