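#' Pipeline run configuration
#'
#' Bundles the full analysis settings with defaults matching the reference
#' acquisition: markers at 240 Hz filtered with a 4th-order zero-lag 12 Hz
#' Butterworth, IMU at 128 Hz filtered at 2nd order / 12 Hz, 101 cycle
#' nodes, omnibus alpha 0.05 and Bonferroni post-hoc alpha 0.017.
#'
#' @param sim A [gait_sim_config()] describing the synthetic cohort, or
#'   `NULL` when reading trials from `input_dir`.
#' @param input_dir Directory of `*_markers.csv` / `*_imu.csv` trial pairs
#'   (as written by [write_trial()]), used when `sim` is `NULL`.
#' @param marker_filter,imu_filter Lists with `order` and `cutoff` (Hz).
#' @param n_nodes Nodes per normalized gait cycle.
#' @param alpha,alpha_posthoc Omnibus and post-hoc family-wise error rates.
#' @param foot Which foot's heel defines the camera-side cycle stream.
#' @param event_tolerance Cross-system event pairing tolerance, seconds.
#' @param grf_threshold Vertical-force contact threshold, N (used only when
#'   force data are supplied).
#' @param out_dir Optional output directory for report and stage CSVs.
#' @param seed Seed forwarded to the simulator when `sim` has none set.
#' @return A `run_config` object.
#' @export
run_config <- function(sim = gait_sim_config(), input_dir = NULL,
                       marker_filter = list(order = 4, cutoff = 12),
                       imu_filter = list(order = 2, cutoff = 12),
                       n_nodes = 101L, alpha = 0.05, alpha_posthoc = 0.017,
                       foot = c("right", "left"), event_tolerance = 0.08,
                       grf_threshold = 20, out_dir = NULL, seed = NULL) {
  foot <- match.arg(foot)
  if (is.null(sim) && is.null(input_dir)) {
    stop("provide either a simulation config or an input directory", call. = FALSE)
  }
  if (!is.null(sim) && !inherits(sim, "gait_sim_config")) {
    stop("`sim` must be a gait_sim_config", call. = FALSE)
  }
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  for (fl in list(marker_filter, imu_filter)) {
    if (!all(c("order", "cutoff") %in% names(fl))) {
      stop("filter specs need `order` and `cutoff`", call. = FALSE)
    }
  }
  if (n_nodes < 2L) stop("n_nodes must be >= 2", call. = FALSE)
  structure(list(sim = sim, input_dir = input_dir,
                 marker_filter = marker_filter, imu_filter = imu_filter,
                 n_nodes = as.integer(n_nodes), alpha = alpha,
                 alpha_posthoc = alpha_posthoc, foot = foot,
                 event_tolerance = event_tolerance,
                 grf_threshold = grf_threshold, out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; the `sim` block maps
#' onto [gait_sim_config()] fields.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$sim)) {
    sim_args <- raw$sim
    if (!is.null(sim_args$osc_scale)) {
      sim_args$osc <- default_oscillations(sim_args$osc_scale)
      sim_args$osc_scale <- NULL
    }
    sim <- do.call(gait_sim_config, sim_args)
  }
  args <- raw[setdiff(names(raw), "sim")]
  do.call(run_config, c(list(sim = sim), args))
}

# One trial through conditioning, events and normalization; returns the
# per-condition 101 x 3 subject curves plus diagnostics.
process_trial <- function(trial, config) {
  sim_rate <- trial$markers$rate
  mspec <- filter_spec(config$marker_filter$order, config$marker_filter$cutoff,
                       sim_rate)
  ispec <- filter_spec(config$imu_filter$order, config$imu_filter$cutoff,
                       trial$imu$rate)
  filt_pos <- lapply(trial$markers$positions, butterworth_zero_lag, spec = mspec)
  fmark <- marker_series(filt_pos, sim_rate, t0 = trial$markers$time[1L])

  com_pos <- whole_body_com(default_body_model(), fmark)$com
  com_acc <- finite_difference(com_pos, sim_rate, deriv_order = 2L)
  ml5_acc <- finite_difference(filt_pos$ML5, sim_rate, deriv_order = 2L)

  imu_corr <- gravity_correct(trial$imu$acc, g = trial$config$gravity %||% 9.81)
  imu_filt <- butterworth_zero_lag(imu_corr, ispec)

  heel <- paste0(toupper(substr(config$foot, 1L, 1L)), "_HEEL")
  cam_ev <- detect_hs_camera(filt_pos[[heel]][, 3L], sim_rate,
                             t0 = fmark$time[1L], foot = config$foot)
  imu_ev <- detect_hs_imu(imu_filt[, 3L], trial$imu$rate,
                          t0 = trial$imu$time[1L])
  matched <- tryCatch(match_events(cam_ev, imu_ev, config$event_tolerance),
                      error = function(e) NULL)

  subject_curves <- function(acc, rate, events, t0) {
    cycles <- segment_cycles(acc, rate, events, t0 = t0, trim = TRUE)
    curves <- lapply(cycles, time_normalize, n_nodes = config$n_nodes)
    ensemble_average(curves)$mean
  }
  curves <- list(
    IMU = subject_curves(imu_filt, trial$imu$rate, imu_ev, trial$imu$time[1L]),
    ML5 = subject_curves(ml5_acc, sim_rate, cam_ev, fmark$time[1L]),
    CoM = subject_curves(com_acc, sim_rate, cam_ev, fmark$time[1L])
  )
  list(curves = curves,
       diagnostics = list(
         subject = trial$subject_id,
         n_camera_events = length(cam_ev$times),
         n_imu_events = length(imu_ev$times),
         clock_offset = if (is.null(matched)) NA_real_ else matched$offset,
         n_unpaired = if (is.null(matched)) NA_integer_ else
           length(matched$unpaired$camera) + length(matched$unpaired$imu)))
}

read_trials_dir <- function(dir) {
  mfiles <- sort(list.files(dir, "_markers\\.csv$", full.names = TRUE))
  if (!length(mfiles)) stop("no *_markers.csv files in ", dir, call. = FALSE)
  lapply(mfiles, function(mf) {
    id <- sub("_markers\\.csv$", "", basename(mf))
    imf <- file.path(dir, paste0(id, "_imu.csv"))
    if (!file.exists(imf)) stop("missing IMU file for subject ", id, call. = FALSE)
    structure(list(markers = read_markers(mf), imu = read_imu(imf),
                   truth_com = NULL, truth_hs = NULL, subject_id = id,
                   config = list(gravity = 9.81)),
              class = "gait_trial")
  })
}

#' Run the full comparison pipeline
#'
#' Simulates (or reads) a cohort, conditions the three acceleration streams
#' (IMU directly measured; ML5 = the marker on the sensor, twice
#' differentiated; CoM = the 13-segment weighted-sum model, twice
#' differentiated), detects heel strikes on each modality, normalizes gait
#' cycles to the node grid, and computes pooled Pearson / Bland-Altman
#' agreement per condition pair plus per-direction SPM repeated-measures
#' ANOVA with post-hoc paired-t fields on the amplitude-normalized curves.
#'
#' @param config A [run_config()].
#' @return A `gaitcom_run` object: `cycles` (physical-unit [cycle_set()]),
#'   `cycles_norm`, `agreement` (per pair: `pearson`, `bland_altman`),
#'   `spm` (per direction: `anova`, `posthoc`), `diagnostics`,
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  trials <- if (!is.null(config$sim)) generate_cohort(config$sim)
            else read_trials_dir(config$input_dir)

  processed <- lapply(trials, process_trial, config = config)
  names(processed) <- vapply(trials, `[[`, "", "subject_id")

  conditions <- c("IMU", "ML5", "CoM")
  curves <- lapply(processed, `[[`, "curves")
  cyc_phys <- cycle_set(curves, conditions)
  curves_norm <- lapply(curves, function(sc) lapply(sc, amplitude_normalize))
  cyc_norm <- cycle_set(curves_norm, conditions, normalized = TRUE)

  pair_list <- list(c("IMU", "CoM"), c("IMU", "ML5"), c("ML5", "CoM"))
  agreement <- lapply(pair_list, function(pr) {
    pooled <- pool_points(cyc_phys, pr)
    list(pair = paste(pr, collapse = "_vs_"),
         pearson = pearson_pooled(pooled),
         bland_altman = bland_altman(pooled))
  })
  names(agreement) <- vapply(agreement, `[[`, "", "pair")

  warnings <- character(0)
  spm <- NULL
  if (length(trials) >= 2L) {
    dirs <- dimnames(cyc_norm)$direction
    spm <- lapply(dirs, function(dd) {
      Y <- unclass(cyc_norm)[, , , dd]
      anova <- spm_rm_anova(Y, alpha = config$alpha)
      posthoc <- lapply(pair_list, function(pr) {
        posthoc_paired_t(Y, match(pr, conditions), alpha = config$alpha_posthoc)
      })
      names(posthoc) <- vapply(pair_list, paste, "", collapse = "_vs_")
      list(direction = dd, anova = anova, posthoc = posthoc)
    })
    names(spm) <- dirs
  } else {
    warnings <- c(warnings, "single subject: SPM stage skipped")
    warning("single subject: SPM stage skipped", call. = FALSE)
  }

  run <- structure(
    list(cycles = cyc_phys, cycles_norm = cyc_norm, agreement = agreement,
         spm = spm,
         diagnostics = lapply(processed, `[[`, "diagnostics"),
         warnings = warnings,
         provenance = list(
           package_version = as.character(utils::packageVersion("gaitcom")),
           seed = if (!is.null(config$sim)) config$sim$seed else NA_integer_,
           n_subjects = length(trials),
           config = config,
           timestamp = format(t_start, "%Y-%m-%dT%H:%M:%S%z"))),
    class = "gaitcom_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' Serialize a pipeline run
#'
#' Writes the machine-readable JSON report plus the long-format cycle CSVs
#' and per-pair scatter CSVs into a directory.
#'
#' @param run A `gaitcom_run`.
#' @param dir Output directory.
#' @return The report path, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(run$cycles),
                   file.path(dir, "cycles_physical.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$cycles_norm),
                   file.path(dir, "cycles_normalized.csv"), row.names = FALSE)
  for (nm in names(run$agreement)) {
    utils::write.csv(run$agreement[[nm]]$bland_altman$scatter,
                     file.path(dir, paste0("scatter_", nm, ".csv")),
                     row.names = FALSE)
  }
  report <- run_report(run)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Plain-list view of the run results (numbers only, no arrays of cycles).
run_report <- function(run) {
  list(
    provenance = run$provenance[c("package_version", "seed", "n_subjects",
                                  "timestamp")],
    agreement = lapply(run$agreement, function(ag) {
      ba <- ag$bland_altman
      list(pair = ag$pair, r = ag$pearson$r, p = ag$pearson$p,
           n = ag$pearson$n, bias = ba$bias, sd = ba$sd,
           loa_lower = ba$loa_lower, loa_upper = ba$loa_upper)
    }),
    spm = if (is.null(run$spm)) NULL else lapply(run$spm, function(sd) {
      list(direction = sd$direction,
           anova = spm_block(sd$anova),
           posthoc = lapply(sd$posthoc, spm_block))
    }),
    warnings = run$warnings
  )
}

spm_block <- function(x) {
  list(stat = x$stat, dof = x$dof, fwhm = x$fwhm, resels = x$resels,
       threshold = x$threshold, alpha = x$alpha, degenerate = x$degenerate,
       clusters = x$clusters)
}

#' @export
print.gaitcom_run <- function(x, ...) {
  cat(sprintf("<gaitcom_run> %d subjects, seed %s\n",
              x$provenance$n_subjects, x$provenance$seed))
  for (ag in x$agreement) {
    ba <- ag$bland_altman
    cat(sprintf("  %-12s r = %.3f (n = %d); bias %.3f +/- %.3f m/s^2, LoA [%.2f, %.2f]\n",
                ag$pair, ag$pearson$r, ag$pearson$n, ba$bias, ba$sd,
                ba$loa_lower, ba$loa_upper))
  }
  if (!is.null(x$spm)) {
    for (sd in x$spm) {
      ncl <- nrow(sd$anova$clusters)
      cat(sprintf("  SPM %s: %s\n", sd$direction,
                  if (sd$anova$degenerate) "degenerate (inference suppressed)"
                  else sprintf("%d significant cluster(s)", ncl)))
    }
  }
  invisible(x)
}

#' @export
summary.gaitcom_run <- function(object, ...) {
  print(object)
  if (!is.null(object$spm)) {
    for (sd in object$spm) {
      cat(sprintf("-- direction %s --\n", sd$direction))
      print(sd$anova)
      for (nm in names(sd$posthoc)) {
        cat(sprintf(" post-hoc %s:\n", nm))
        print(sd$posthoc[[nm]])
      }
    }
  }
  invisible(object)
}
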