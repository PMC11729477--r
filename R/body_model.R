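#' 13-link body model for segmental CoM estimation
#'
#' A `body_model` is a table of 13 body segments (head and neck, trunk,
#' pelvis, paired upper arms, forearms-with-hands, thighs, shanks and feet).
#' Each segment is defined by the markers whose centroid forms its proximal
#' and distal endpoints, a mass fraction \eqn{m_i/M}, and the position of the
#' segment CoM as a ratio along the proximal-to-distal line. The whole-body
#' CoM is the mass-fraction-weighted sum of the segment CoMs.
#'
#' @param segments A data.frame with columns `name`, `proximal`, `distal`
#'   (comma-separated marker names), `mass_fraction`, `com_ratio`.
#' @return An object of class `body_model`.
#' @seealso [default_body_model()], [whole_body_com()]
#' @export
body_model <- function(segments) {
  req <- c("name", "proximal", "distal", "mass_fraction", "com_ratio")
  if (!is.data.frame(segments) || !all(req %in% names(segments))) {
    stop("`segments` must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  segments <- segments[, req]
  segments$name <- as.character(segments$name)
  if (anyDuplicated(segments$name)) stop("duplicate segment names", call. = FALSE)
  if (any(segments$mass_fraction <= 0)) {
    stop("mass fractions must be positive", call. = FALSE)
  }
  if (any(segments$com_ratio < 0 | segments$com_ratio > 1)) {
    stop("com_ratio must lie in [0, 1]", call. = FALSE)
  }
  total <- sum(segments$mass_fraction)
  if (abs(total - 1) > 1e-6) {
    stop(sprintf("segment mass fractions must sum to 1 (got %.8f)", total),
         call. = FALSE)
  }
  structure(list(segments = segments, total_mass_fraction = total),
            class = "body_model")
}

#' Default 13-segment body model (Dempster anthropometrics)
#'
#' Mass fractions and segment-CoM position ratios follow the classical
#' Dempster cadaver data as tabulated in Winter's biomechanics textbook:
#' head+neck 0.081, upper arm 0.028, forearm+hand 0.022, thigh 0.100,
#' shank 0.0465, foot 0.0145, and trunk+pelvis 0.497 (split here 0.355 /
#' 0.142 between a thorax-dominated trunk segment and the pelvis). CoM
#' ratios from the proximal endpoint: upper arm 0.436, forearm+hand 0.682,
#' thigh 0.433, shank 0.433; axial segments and feet use the midpoint.
#' Segment endpoints are centroids of the named markers (e.g. the trunk runs
#' from the mid-shoulder point to the mid-ASIS point). The mapping of
#' markers to endpoints is a declared convention of this package, editable
#' via [write_body_model()] / [read_body_model()].
#'
#' @return A `body_model` with 13 segments whose mass fractions sum to 1.
#' @export
default_body_model <- function() {
  seg <- function(name, prox, dist, mf, cr) {
    data.frame(name = name, proximal = prox, distal = dist,
               mass_fraction = mf, com_ratio = cr,
               stringsAsFactors = FALSE)
  }
  segments <- rbind(
    seg("head_neck",      "C7",             "VERTEX",         0.0810, 0.500),
    seg("trunk",          "L_SHOULDER,R_SHOULDER", "L_ASIS,R_ASIS", 0.3550, 0.500),
    seg("pelvis",         "L_ASIS,R_ASIS",  "L_HIP,R_HIP",    0.1420, 0.500),
    seg("upper_arm_l",    "L_SHOULDER",     "L_ELBOW",        0.0280, 0.436),
    seg("upper_arm_r",    "R_SHOULDER",     "R_ELBOW",        0.0280, 0.436),
    seg("forearm_hand_l", "L_ELBOW",        "L_WRIST",        0.0220, 0.682),
    seg("forearm_hand_r", "R_ELBOW",        "R_WRIST",        0.0220, 0.682),
    seg("thigh_l",        "L_HIP",          "L_KNEE",         0.1000, 0.433),
    seg("thigh_r",        "R_HIP",          "R_KNEE",         0.1000, 0.433),
    seg("shank_l",        "L_KNEE",         "L_ANKLE",        0.0465, 0.433),
    seg("shank_r",        "R_KNEE",         "R_ANKLE",        0.0465, 0.433),
    seg("foot_l",         "L_HEEL",         "L_TOE",          0.0145, 0.500),
    seg("foot_r",         "R_HEEL",         "R_TOE",          0.0145, 0.500)
  )
  body_model(segments)
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("<body_model> %d segments, mass fractions sum to %.6f\n",
              nrow(x$segments), x$total_mass_fraction))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

split_markers <- function(s) trimws(strsplit(s, ",", fixed = TRUE)[[1L]])

#' Segment CoM position at one frame
#'
#' The segment CoM is the affine point `proximal + com_ratio * (distal -
#' proximal)`, the endpoints being centroids of the segment's proximal and
#' distal marker sets.
#'
#' @param segment One row of a `body_model`'s `segments` table (data.frame
#'   or list with fields `proximal`, `distal`, `com_ratio`).
#' @param markers A [marker_series()].
#' @param frame Frame index (1-based).
#' @return Length-3 numeric vector (X, Y, Z) in metres.
#' @export
segment_com <- function(segment, markers, frame) {
  if (frame < 1L || frame > markers$n_frames) {
    stop(sprintf("frame %d outside 1..%d", frame, markers$n_frames),
         call. = FALSE)
  }
  tr <- segment_com_trajectory(segment, markers)
  tr[frame, ]
}

# Full n x 3 segment-CoM trajectory; shared by segment_com and
# whole_body_com so both are a single vectorised code path.
segment_com_trajectory <- function(segment, markers) {
  p <- marker_centroid(markers, split_markers(segment$proximal))
  d <- marker_centroid(markers, split_markers(segment$distal))
  p + segment$com_ratio * (d - p)
}

#' Whole-body CoM trajectory from markers
#'
#' Applies the weighted-sum model per frame and axis:
#' \deqn{x_0 = \sum_i (m_i/M)\, x_i}
#' where \eqn{(x_i, y_i, z_i)} is the CoM of segment \eqn{i} computed by
#' [segment_com()] and \eqn{m_i/M} its mass fraction.
#'
#' @param model A [body_model()].
#' @param markers A [marker_series()] containing every marker the model
#'   references.
#' @return A `com_trajectory`: list with `com` (`n x 3` matrix, metres),
#'   `rate`, `time`.
#' @export
whole_body_com <- function(model, markers) {
  stopifnot(inherits(model, "body_model"), inherits(markers, "marker_series"))
  total <- sum(model$segments$mass_fraction)
  if (abs(total - 1) > 1e-6) {
    stop("body model mass fractions do not sum to 1", call. = FALSE)
  }
  com <- matrix(0, markers$n_frames, 3L, dimnames = list(NULL, c("X", "Y", "Z")))
  for (i in seq_len(nrow(model$segments))) {
    s <- model$segments[i, ]
    com <- com + s$mass_fraction * segment_com_trajectory(s, markers)
  }
  structure(list(com = com, rate = markers$rate, time = markers$time),
            class = "com_trajectory")
}

#' @export
print.com_trajectory <- function(x, ...) {
  cat(sprintf("<com_trajectory> %d frames @ %g Hz\n", nrow(x$com), x$rate))
  invisible(x)
}

#' Read / write a body model as a YAML table
#'
#' Serializes the segment table (name, endpoint marker lists, mass fraction,
#' CoM ratio) so the anthropometric assumptions stay human-editable.
#'
#' @param path File path.
#' @param model A `body_model`.
#' @return `read_body_model()` returns a `body_model`;
#'   `write_body_model()` returns `path` invisibly.
#' @export
read_body_model <- function(path) {
  raw <- yaml::read_yaml(path)
  segments <- do.call(rbind, lapply(raw$segments, function(s) {
    data.frame(name = s$name,
               proximal = paste(s$proximal, collapse = ","),
               distal = paste(s$distal, collapse = ","),
               mass_fraction = s$mass_fraction,
               com_ratio = s$com_ratio,
               stringsAsFactors = FALSE)
  }))
  body_model(segments)
}

#' @rdname read_body_model
#' @export
write_body_model <- function(model, path) {
  stopifnot(inherits(model, "body_model"))
  segs <- lapply(seq_len(nrow(model$segments)), function(i) {
    s <- model$segments[i, ]
    list(name = s$name,
         proximal = split_markers(s$proximal),
         distal = split_markers(s$distal),
         mass_fraction = s$mass_fraction,
         com_ratio = s$com_ratio)
  })
  yaml::write_yaml(list(segments = segs), path)
  invisible(path)
}

# Union of all marker names a model references.
model_marker_names <- function(model) {
  unique(unlist(lapply(seq_len(nrow(model$segments)), function(i) {
    s <- model$segments[i, ]
    c(split_markers(s$proximal), split_markers(s$distal))
  })))
}
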