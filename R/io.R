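#' Read a DeepLabCut-style pose CSV
#'
#' Parses the three-row header layout written by DeepLabCut (scorer /
#' bodyparts / coords) followed by one row per frame, first column the
#' frame index and then x, y, likelihood triplets per body part.
#'
#' @param path CSV file path.
#' @param frame_rate Frame rate of the behavior video (default 40 fps).
#' @return A [pose_track()].
#' @export
read_dlc_csv <- function(path, frame_rate = 40) {
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                         colClasses = "character")
  body <- utils::read.csv(path, header = FALSE, skip = 3)
  parts_row <- as.character(hdr[2, -1])
  coords_row <- as.character(hdr[3, -1])
  dat <- as.matrix(body[, -1, drop = FALSE])
  parts <- list()
  for (p in unique(parts_row)) {
    sel <- which(parts_row == p)
    cols <- coords_row[sel]
    parts[[p]] <- data.frame(
      x = dat[, sel[cols == "x"]],
      y = dat[, sel[cols == "y"]],
      likelihood = dat[, sel[cols == "likelihood"]]
    )
  }
  pose_track(parts, frame_rate)
}

#' Write a pose track as a DeepLabCut-style CSV
#'
#' @param pose A [pose_track()].
#' @param path Output file path.
#' @param scorer Scorer name placed in the first header row.
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(pose, path, scorer = "synthetic") {
  stopifnot(inherits(pose, "pose_track"))
  parts <- names(pose$parts)
  h1 <- c("scorer", rep(scorer, 3 * length(parts)))
  h2 <- c("bodyparts", rep(parts, each = 3))
  h3 <- c("coords", rep(c("x", "y", "likelihood"), length(parts)))
  dat <- do.call(cbind, lapply(pose$parts, function(d)
    cbind(d$x, d$y, d$likelihood)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(h1, collapse = ","), con)
  writeLines(paste(h2, collapse = ","), con)
  writeLines(paste(h3, collapse = ","), con)
  utils::write.table(cbind(seq_len(nrow(dat)) - 1L, dat), con, sep = ",",
                     col.names = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write behavior labels as CSV
#'
#' The label CSV has columns `frame` (0-based) and `behavior_id`
#' (0-11 or empty for unlabeled).
#'
#' @param labels A [behavior_labels()].
#' @param path File path.
#' @param frame_rate Frame rate used when reading.
#' @return `write_labels_csv`: `path` invisibly; `read_labels_csv`: a
#'   [behavior_labels()].
#' @export
write_labels_csv <- function(labels, path) {
  stopifnot(inherits(labels, "behavior_labels"))
  utils::write.csv(
    data.frame(frame = seq_along(labels$labels) - 1L,
               behavior_id = labels$labels),
    path, row.names = FALSE, na = ""
  )
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path, frame_rate = 40) {
  d <- utils::read.csv(path)
  behavior_labels(d$behavior_id, frame_rate)
}

#' Deconvolved event raster
#'
#' Container for a neurons x frames matrix of nonnegative deconvolved
#' calcium event amplitudes at the imaging frame rate, tagged with the
#' SPN pathway it was recorded from.
#'
#' @param events Neurons x frames matrix, nonnegative and finite.
#' @param rate Imaging frame rate (frames/s, typically 20).
#' @param pathway `"dSPN"` or `"iSPN"`.
#' @param session_id Optional session identifier.
#' @return Object of class `event_raster`.
#' @export
event_raster <- function(events, rate = 20, pathway = c("dSPN", "iSPN"),
                         session_id = NA_character_) {
  pathway <- match.arg(pathway)
  stopifnot(is.matrix(events), rate > 0)
  if (any(!is.finite(events)) || any(events < 0))
    stop("event amplitudes must be finite and nonnegative")
  structure(list(events = events, rate = rate, pathway = pathway,
                 session_id = session_id), class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("event_raster: %d neurons x %d frames at %g fps (%s)\n",
              nrow(x$events), ncol(x$events), x$rate, x$pathway))
  invisible(x)
}

#' Read/write an event raster as CSV (neurons x frames)
#'
#' @param raster An [event_raster()].
#' @param path File path.
#' @param rate,pathway Metadata applied when reading.
#' @return `write_raster_csv`: `path` invisibly; `read_raster_csv`: an
#'   [event_raster()].
#' @export
write_raster_csv <- function(raster, path) {
  stopifnot(inherits(raster, "event_raster"))
  utils::write.table(raster$events, path, sep = ",",
                     col.names = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path, rate = 20, pathway = "dSPN") {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  event_raster(m, rate = rate, pathway = pathway)
}

#' Cross-session cell registry
#'
#' Pairing of cell indices across two imaging sessions (as produced by a
#' probabilistic cell-registration tool) together with cell centroid
#' coordinates, which the closest-neighbor registration control requires.
#'
#' @param pairs data.frame with integer columns `cell_a`, `cell_b`
#'   (1-based indices into the two session rasters).
#' @param centroids_a,centroids_b Numeric matrices (cells x 2) of cell
#'   centroid x/y coordinates for every cell of each session.
#' @return Object of class `cell_registry`.
#' @export
cell_registry <- function(pairs, centroids_a = NULL, centroids_b = NULL) {
  stopifnot(is.data.frame(pairs), all(c("cell_a", "cell_b") %in% names(pairs)))
  if (anyDuplicated(pairs$cell_a) || anyDuplicated(pairs$cell_b))
    stop("each cell may appear in at most one pair")
  structure(list(pairs = pairs, centroids_a = centroids_a,
                 centroids_b = centroids_b), class = "cell_registry")
}

#' Read/write a cell registry as CSV
#'
#' Columns: `cell_a`, `cell_b`, `x_a`, `y_a`, `x_b`, `y_b` (centroids of
#' the paired cells).
#'
#' @param registry A [cell_registry()].
#' @param path File path.
#' @return `write_registry_csv`: `path` invisibly; `read_registry_csv`: a
#'   [cell_registry()] (centroids only for registered cells).
#' @export
write_registry_csv <- function(registry, path) {
  stopifnot(inherits(registry, "cell_registry"))
  p <- registry$pairs
  d <- data.frame(cell_a = p$cell_a, cell_b = p$cell_b)
  if (!is.null(registry$centroids_a)) {
    d$x_a <- registry$centroids_a[p$cell_a, 1]
    d$y_a <- registry$centroids_a[p$cell_a, 2]
  }
  if (!is.null(registry$centroids_b)) {
    d$x_b <- registry$centroids_b[p$cell_b, 1]
    d$y_b <- registry$centroids_b[p$cell_b, 2]
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry_csv
#' @export
read_registry_csv <- function(path) {
  d <- utils::read.csv(path)
  ca <- cb <- NULL
  if (all(c("x_a", "y_a") %in% names(d))) {
    ca <- matrix(NA_real_, max(d$cell_a), 2)
    ca[d$cell_a, ] <- cbind(d$x_a, d$y_a)
  }
  if (all(c("x_b", "y_b") %in% names(d))) {
    cb <- matrix(NA_real_, max(d$cell_b), 2)
    cb[d$cell_b, ] <- cbind(d$x_b, d$y_b)
  }
  cell_registry(data.frame(cell_a = d$cell_a, cell_b = d$cell_b), ca, cb)
}

#' Write synthetic ground truth as a JSON sidecar
#'
#' @param truth Ground-truth list as returned by the synthetic generators.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  keep <- truth[setdiff(names(truth), c("true_labels", "true_registry"))]
  if (!is.null(truth$true_labels))
    keep$true_label_vector <- truth$true_labels$labels
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
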