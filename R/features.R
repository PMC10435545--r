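#' Tracked body-part coordinates
#'
#' Container for a pose track: per-frame x/y coordinates and tracking
#' likelihood for the eight tracked body parts (nose, neck, left ear,
#' right ear, microendoscope camera, body center, tail start, tail end).
#' Coordinates are in cm in the arena plane viewed from above; the y axis
#' points "down" in image coordinates.
#'
#' @param parts Named list of data.frames with columns `x`, `y`,
#'   `likelihood`, one per body part; all of equal length.
#' @param frame_rate Frames per second (behavior video, typically 40).
#' @return Object of class `pose_track`.
#' @export
pose_track <- function(parts, frame_rate) {
  required <- pose_part_names()
  if (!all(required %in% names(parts)))
    stop("missing body parts: ",
         paste(setdiff(required, names(parts)), collapse = ", "))
  n <- nrow(parts[[1]])
  for (p in names(parts)) {
    stopifnot(all(c("x", "y", "likelihood") %in% names(parts[[p]])),
              nrow(parts[[p]]) == n)
    lk <- parts[[p]]$likelihood
    if (any(lk < 0 | lk > 1, na.rm = TRUE))
      stop("likelihood must lie in [0, 1]")
  }
  structure(list(parts = parts[required], frame_rate = frame_rate,
                 n_frames = n), class = "pose_track")
}

#' @rdname pose_track
#' @export
pose_part_names <- function() {
  c("nose", "neck", "left_ear", "right_ear", "camera",
    "body_center", "tail_start", "tail_end")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("pose_track: %d frames at %g fps, %d body parts\n",
              x$n_frames, x$frame_rate, length(x$parts)))
  invisible(x)
}

#' Remove low-confidence coordinates
#'
#' Coordinates tracked with a likelihood below the threshold are set to
#' missing (`NA`); downstream feature computation propagates the mask
#' rather than interpolating.
#'
#' @param pose A [pose_track()].
#' @param threshold Likelihood threshold in `[0, 1]`; coordinates with
#'   likelihood strictly below it are masked. Default 0.9.
#' @return A `pose_track` with masked coordinates.
#' @export
filter_low_confidence <- function(pose, threshold = 0.9) {
  stopifnot(inherits(pose, "pose_track"),
            threshold >= 0, threshold <= 1)
  for (p in names(pose$parts)) {
    bad <- pose$parts[[p]]$likelihood < threshold
    bad[is.na(bad)] <- TRUE
    pose$parts[[p]]$x[bad] <- NA_real_
    pose$parts[[p]]$y[bad] <- NA_real_
  }
  pose
}

#' Per-frame posture features
#'
#' Container for the six posture features: body speed (cm/s), head speed
#' (cm/s), movement angle (rad, signed; positive = right turn in image
#' coordinates), body length (cm), neck elongation (cm), head elevation
#' (cm, a top-down-view proxy for head pitch). `valid` marks frames on
#' which all six features are defined.
#'
#' @param data Numeric matrix, frames x 6, with the feature columns.
#' @param frame_rate Frames per second.
#' @return Object of class `feature_series`.
#' @export
feature_series <- function(data, frame_rate) {
  stopifnot(is.matrix(data), ncol(data) == 6)
  colnames(data) <- feature_names()
  mode(data) <- "numeric"
  structure(list(data = data, frame_rate = frame_rate,
                 valid = rowSums(!is.finite(data)) == 0),
            class = "feature_series")
}

#' @rdname feature_series
#' @export
feature_names <- function() {
  c("body_speed", "head_speed", "movement_angle",
    "body_length", "neck_elongation", "head_elevation")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("feature_series: %d frames at %g fps, %d valid\n",
              nrow(x$data), x$frame_rate, sum(x$valid)))
  invisible(x)
}

# central differences (per second); one-sided at the ends; NA-propagating
.velocity <- function(x, frame_rate) {
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n >= 3)
    v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * frame_rate / 2
  if (n >= 2) {
    v[1] <- (x[2] - x[1]) * frame_rate
    v[n] <- (x[n] - x[n - 1]) * frame_rate
  }
  v
}

#' Compute the six posture features from a pose track
#'
#' Features follow the top-down-view definitions used for open-field mouse
#' posture:
#' * body speed: projection of the body-center velocity on the body axis
#'   (unit vector from body center toward the neck);
#' * head speed: norm of the difference between the body-center velocity
#'   and the camera velocity;
#' * movement angle: signed angle between the body-center velocity at the
#'   previous and the subsequent frame (positive = right turn, with image
#'   y pointing down);
#' * body length: distance(neck, body center) + distance(body center,
#'   tail start);
#' * neck elongation: distance(neck, body center);
#' * head elevation: distance between the neck and the orthogonal
#'   projection of the camera position onto the line through the two ears.
#'
#' Velocities use central differences (one-sided at the series ends), so
#' frames adjacent to masked coordinates are masked in derivative-based
#' features.
#'
#' @param pose A [pose_track()], typically after [filter_low_confidence()].
#' @return A [feature_series()] at the pose frame rate.
#' @export
compute_features <- function(pose) {
  stopifnot(inherits(pose, "pose_track"))
  n <- pose$n_frames
  if (n < 3) stop("need at least 3 frames")
  fr <- pose$frame_rate
  P <- lapply(pose$parts, function(d) cbind(d$x, d$y))
  if (all(is.na(P$body_center[, 1]))) stop("all frames masked")

  vbx <- .velocity(P$body_center[, 1], fr)
  vby <- .velocity(P$body_center[, 2], fr)
  vcx <- .velocity(P$camera[, 1], fr)
  vcy <- .velocity(P$camera[, 2], fr)

  # body axis: body center -> neck
  ax <- P$neck[, 1] - P$body_center[, 1]
  ay <- P$neck[, 2] - P$body_center[, 2]
  an <- sqrt(ax^2 + ay^2)
  body_speed <- (vbx * ax + vby * ay) / an
  body_speed[!is.finite(body_speed) & !is.na(vbx)] <- NA_real_

  head_speed <- sqrt((vbx - vcx)^2 + (vby - vcy)^2)

  # movement angle at t: angle from v(t-1) to v(t+1)
  movement_angle <- rep(NA_real_, n)
  if (n >= 3) {
    i <- 2:(n - 1)
    x1 <- vbx[i - 1]; y1 <- vby[i - 1]
    x2 <- vbx[i + 1]; y2 <- vby[i + 1]
    cross <- x1 * y2 - y1 * x2
    dot <- x1 * x2 + y1 * y2
    ang <- atan2(cross, dot)
    mag <- sqrt(x1^2 + y1^2) * sqrt(x2^2 + y2^2)
    ang[!is.na(mag) & mag == 0] <- 0 # stationary: no turning
    movement_angle[i] <- ang
  }

  neck_elongation <- an
  body_length <- an + sqrt((P$body_center[, 1] - P$tail_start[, 1])^2 +
                             (P$body_center[, 2] - P$tail_start[, 2])^2)

  # projection of camera on the inter-ear line
  ex <- P$right_ear[, 1] - P$left_ear[, 1]
  ey <- P$right_ear[, 2] - P$left_ear[, 2]
  en <- sqrt(ex^2 + ey^2)
  ux <- ex / en; uy <- ey / en
  dx <- P$camera[, 1] - P$left_ear[, 1]
  dy <- P$camera[, 2] - P$left_ear[, 2]
  t <- dx * ux + dy * uy
  px <- P$left_ear[, 1] + t * ux
  py <- P$left_ear[, 2] + t * uy
  head_elevation <- sqrt((P$neck[, 1] - px)^2 + (P$neck[, 2] - py)^2)

  feature_series(cbind(body_speed, head_speed, movement_angle,
                       body_length, neck_elongation, head_elevation),
                 fr)
}

#' Moving-average smoothing of posture features
#'
#' Mask-aware centered moving average: each output frame averages the
#' non-missing values inside its window; the mask itself is preserved
#' (frames with a missing feature stay missing). For an even window `w`
#' the window spans `w/2` frames back and `w/2 - 1` frames forward.
#'
#' @param features A [feature_series()].
#' @param window_frames Window length in frames (default 20, i.e. 0.5 s at
#'   40 fps).
#' @return A smoothed [feature_series()] of the same length.
#' @export
smooth_features <- function(features, window_frames = 20) {
  stopifnot(inherits(features, "feature_series"), window_frames >= 1)
  n <- nrow(features$data)
  if (window_frames > n) stop("window longer than series")
  if (window_frames == 1) return(features)
  back <- floor(window_frames / 2)
  fwd <- window_frames - back - 1L
  sm <- apply(features$data, 2, function(x) {
    miss <- is.na(x)
    xz <- ifelse(miss, 0, x)
    cs <- cumsum(c(0, xz))
    cn <- cumsum(c(0, !miss))
    i <- seq_len(n)
    lo <- pmax(i - back, 1L)
    hi <- pmin(i + fwd, n)
    s <- cs[hi + 1L] - cs[lo]
    k <- cn[hi + 1L] - cn[lo]
    out <- ifelse(k > 0, s / k, NA_real_)
    out[miss] <- NA_real_
    out
  })
  feature_series(sm, features$frame_rate)
}
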