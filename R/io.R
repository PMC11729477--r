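#' Read and write marker trajectories as tidy CSV
#'
#' Dialect: one row per frame, columns `time` plus `<marker>_X`,
#' `<marker>_Y`, `<marker>_Z` in metres. Timestamps must be uniform.
#'
#' @param path CSV file path.
#' @param markers A [marker_series()].
#' @param dialect Input format; only `"csv"` is supported (`"c3d"` raises
#'   an unsupported-format error).
#' @return `read_markers()` returns a [marker_series()];
#'   `write_markers()` returns `path` invisibly.
#' @export
read_markers <- function(path, dialect = c("csv", "c3d")) {
  dialect <- match.arg(dialect)
  if (dialect == "c3d") {
    stop("C3D input is not supported; export to the tidy marker CSV dialect",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("marker CSV lacks a `time` column", call. = FALSE)
  t <- df$time
  if (length(t) < 2L) stop("marker CSV needs at least 2 frames", call. = FALSE)
  dt <- diff(t)
  if (max(abs(dt - dt[1L])) > 1e-6) {
    stop("non-uniform timestamps in marker CSV", call. = FALSE)
  }
  cols <- setdiff(names(df), "time")
  base <- unique(sub("_[XYZ]$", "", cols))
  positions <- lapply(base, function(nm) {
    need <- paste0(nm, "_", c("X", "Y", "Z"))
    miss <- setdiff(need, cols)
    if (length(miss)) {
      stop(sprintf("marker CSV missing column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    as.matrix(df[, need])
  })
  names(positions) <- base
  marker_series(positions, rate = 1 / dt[1L], t0 = t[1L])
}

#' @rdname read_markers
#' @export
write_markers <- function(markers, path) {
  stopifnot(inherits(markers, "marker_series"))
  out <- data.frame(time = markers$time)
  for (nm in names(markers$positions)) {
    p <- markers$positions[[nm]]
    out[[paste0(nm, "_X")]] <- p[, 1L]
    out[[paste0(nm, "_Y")]] <- p[, 2L]
    out[[paste0(nm, "_Z")]] <- p[, 3L]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read and write IMU acceleration CSV
#'
#' Dialect: columns `time, acc_x, acc_y, acc_z` in m/s^2, gravity included
#' on the vertical (z) axis.
#'
#' @param path CSV file path.
#' @param imu An [imu_series()].
#' @return `read_imu()` returns an [imu_series()]; `write_imu()` returns
#'   `path` invisibly.
#' @export
read_imu <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("time", "acc_x", "acc_y", "acc_z")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("IMU CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dt <- diff(df$time)
  if (max(abs(dt - dt[1L])) > 1e-6) {
    stop("non-uniform timestamps in IMU CSV", call. = FALSE)
  }
  imu_series(as.matrix(df[, c("acc_x", "acc_y", "acc_z")]),
             rate = 1 / dt[1L], t0 = df$time[1L])
}

#' @rdname read_imu
#' @export
write_imu <- function(imu, path) {
  stopifnot(inherits(imu, "imu_series"))
  utils::write.csv(data.frame(time = imu$time, acc_x = imu$acc[, 1L],
                              acc_y = imu$acc[, 2L], acc_z = imu$acc[, 3L]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic trial to a directory
#'
#' Emits the marker CSV, the IMU CSV and a truth JSON (heel-strike times,
#' CoM trajectory file reference and config echo) so simulated data can be
#' consumed by the same readers as laboratory exports.
#'
#' @param trial A `gait_trial` from [generate_trial()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "gait_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- trial$subject_id
  paths <- c(markers = file.path(dir, paste0(id, "_markers.csv")),
             imu = file.path(dir, paste0(id, "_imu.csv")),
             com = file.path(dir, paste0(id, "_truth_com.csv")),
             truth = file.path(dir, paste0(id, "_truth.json")))
  write_markers(trial$markers, paths[["markers"]])
  write_imu(trial$imu, paths[["imu"]])
  utils::write.csv(data.frame(time = trial$markers$time,
                              com_x = trial$truth_com[, 1L],
                              com_y = trial$truth_com[, 2L],
                              com_z = trial$truth_com[, 3L]),
                   paths[["com"]], row.names = FALSE)
  cfg <- trial$config
  cfg$osc <- unlist(cfg$osc)
  jsonlite::write_json(
    list(subject_id = id, truth_hs = trial$truth_hs,
         truth_com_file = basename(paths[["com"]]),
         config = cfg[setdiff(names(cfg), "osc_fn")]),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
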