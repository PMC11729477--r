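#' Marker trajectory container
#'
#' Bundles named 3D marker trajectories sampled at a fixed rate into a
#' `marker_series` object, the camera-side raw input of the pipeline.
#' Coordinates follow the package convention: X = anteroposterior (walkway
#' axis), Y = mediolateral, Z = vertical, all in metres.
#'
#' @param positions Named list; each element an `n x 3` numeric matrix of
#'   per-frame positions (metres) for one marker. All markers must have the
#'   same number of frames.
#' @param rate Sampling rate in Hz.
#' @param t0 Time of the first frame in seconds (default 0).
#' @return An object of class `marker_series` with fields `positions`,
#'   `rate`, `time` (per-frame timestamps) and `n_frames`.
#' @examples
#' m <- marker_series(list(A = cbind(1:4, 0, 0)), rate = 100)
#' m$time
#' @export
marker_series <- function(positions, rate, t0 = 0) {
  if (!is.list(positions) || is.null(names(positions)) ||
      any(!nzchar(names(positions)))) {
    stop("`positions` must be a named list of n x 3 matrices", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  }
  positions <- lapply(positions, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 3L) stop("each marker needs 3 columns (X, Y, Z)", call. = FALSE)
    if (anyNA(p)) stop("marker positions must be gap-free at this layer", call. = FALSE)
    storage.mode(p) <- "double"
    colnames(p) <- c("X", "Y", "Z")
    p
  })
  nf <- vapply(positions, nrow, integer(1))
  if (length(unique(nf)) != 1L) {
    stop("all markers must share the same frame count", call. = FALSE)
  }
  structure(
    list(positions = positions, rate = as.numeric(rate),
         time = t0 + (seq_len(nf[[1L]]) - 1) / rate,
         n_frames = nf[[1L]]),
    class = "marker_series"
  )
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("<marker_series> %d markers x %d frames @ %g Hz (%.2f s)\n",
              length(x$positions), x$n_frames, x$rate, x$n_frames / x$rate))
  cat("  markers:", paste(utils::head(names(x$positions), 8L), collapse = ", "),
      if (length(x$positions) > 8L) "..." else "", "\n")
  invisible(x)
}

# Centroid trajectory (n x 3) of a set of markers; errors name the missing
# marker so data problems surface with context.
marker_centroid <- function(markers, names) {
  miss <- setdiff(names, names(markers$positions))
  if (length(miss)) {
    stop(sprintf("marker(s) not present: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  mats <- markers$positions[names]
  Reduce(`+`, mats) / length(mats)
}
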