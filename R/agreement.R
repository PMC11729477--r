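#' Pool paired condition values across subjects, nodes and directions
#'
#' Flattens two conditions of a [cycle_set()] into aligned vectors for
#' correlation and Bland-Altman analysis, keeping direction labels for
#' plotting. With a complete set the pooled count is
#' `n_subjects * n_nodes * n_directions` (16 x 101 x 3 = 4848 for the
#' reference cohort design). No outlier removal is performed.
#'
#' @param cycles A [cycle_set()] (physical units for agreement analysis).
#' @param conditions Length-2 character vector naming the condition pair.
#' @return A `pooled_pairs` object: data.frame with columns `a`, `b`,
#'   `subject`, `direction`, `node`, plus attributes `pair_label` and `n`.
#' @export
pool_points <- function(cycles, conditions) {
  stopifnot(inherits(cycles, "cycle_set"), length(conditions) == 2L)
  dn <- dimnames(cycles)
  miss <- setdiff(conditions, dn$condition)
  if (length(miss)) stop("condition(s) not in cycle set: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  a <- cycles[, conditions[1L], , , drop = TRUE]
  b <- cycles[, conditions[2L], , , drop = TRUE]
  g <- expand.grid(subject = dn$subject, node = as.integer(dn$node),
                   direction = dn$direction, stringsAsFactors = FALSE)
  out <- data.frame(a = as.numeric(a), b = as.numeric(b),
                    subject = g$subject, direction = g$direction,
                    node = g$node)
  if (anyNA(out$a) || anyNA(out$b)) {
    stop("pooled conditions contain missing values", call. = FALSE)
  }
  structure(out, pair_label = paste(conditions, collapse = " vs "),
            n = nrow(out), class = c("pooled_pairs", "data.frame"))
}

#' Pooled Pearson correlation
#'
#' Product-moment correlation of the pooled pairs with the two-sided
#' p-value from the t transform on n - 2 degrees of freedom.
#'
#' @param pairs A [pool_points()] result (or data.frame with columns
#'   `a`, `b`).
#' @return List with `r`, `p`, `n` and `pair_label`.
#' @export
pearson_pooled <- function(pairs) {
  if (nrow(pairs) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(pairs$a) == 0 || stats::sd(pairs$b) == 0) {
    stop("zero variance in one of the pooled vectors", call. = FALSE)
  }
  ct <- stats::cor.test(pairs$a, pairs$b, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pairs),
       pair_label = attr(pairs, "pair_label"))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `a - b`; the bias is their mean, and the limits of
#' agreement are `bias +/- 1.96 * SD` (sample SD). The scatter pairs each
#' difference with the mean `(a + b) / 2`.
#'
#' @param pairs A [pool_points()] result, or anything with columns `a`,`b`;
#'   alternatively two numeric vectors via `a` and `b`.
#' @param a,b Optional numeric vectors used when `pairs` is missing.
#' @return A `bland_altman` object: `bias`, `sd`, `loa_lower`, `loa_upper`
#'   (all m/s^2 for acceleration input), `n`, and `scatter` (data.frame
#'   `mean`, `difference`, plus direction labels when available).
#' @export
bland_altman <- function(pairs = NULL, a = NULL, b = NULL) {
  if (is.null(pairs)) {
    pairs <- data.frame(a = a, b = b)
  }
  if (nrow(pairs) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- pairs$a - pairs$b
  bias <- mean(d)
  s <- stats::sd(d)
  scatter <- data.frame(mean = (pairs$a + pairs$b) / 2, difference = d)
  if (!is.null(pairs$direction)) scatter$direction <- pairs$direction
  structure(list(bias = bias, sd = s,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 n = nrow(pairs), scatter = scatter,
                 pair_label = attr(pairs, "pair_label")),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman>%s n = %d\n",
              if (is.null(x$pair_label)) "" else paste0(" ", x$pair_label, ","),
              x$n))
  cat(sprintf("  bias %.3f +/- %.3f; limits of agreement [%.3f, %.3f]\n",
              x$bias, x$sd, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$scatter$mean, x$scatter$difference,
                 xlab = "mean of methods", ylab = "difference",
                 main = x$pair_label %||% "Bland-Altman", pch = 16,
                 cex = 0.4, col = grDevices::grey(0.3, 0.5), ...)
  graphics::abline(h = c(x$bias, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2), col = "red3")
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
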