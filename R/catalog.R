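#' The 12-behavior open-field catalog
#'
#' Fixed, ordered catalog of the behaviors a mouse expresses during
#' self-paced open-field exploration, as used throughout the package.
#' Behavior ids are the integers 0 to 11 in the order listed below; this
#' order is part of the package contract (lower id wins documented
#' tie-breaks).
#'
#' @return An object of class `behavior_catalog`: a list with `names`
#'   (character, length 12) and `ids` (integer `0:11`).
#' @examples
#' behavior_catalog()$names
#' @export
behavior_catalog <- function() {
  names <- c(
    "locomotion fast", "locomotion straight", "locomotion turn right",
    "locomotion turn left", "still turn right", "still turn left",
    "head up", "rearing", "grooming", "locomotion sniffing",
    "still sniffing", "immobility"
  )
  structure(list(names = names, ids = 0:11), class = "behavior_catalog")
}

#' @export
print.behavior_catalog <- function(x, ...) {
  cat("Behavior catalog (", length(x$ids), " behaviors)\n", sep = "")
  for (i in seq_along(x$ids)) cat(sprintf("  %2d  %s\n", x$ids[i], x$names[i]))
  invisible(x)
}

#' Ambulatory and static behavior subsets
#'
#' Ambulatory behaviors involve locomotion or turning (with or without
#' displacement); static behaviors are postural states without ongoing
#' turning or locomotion (head up, rearing, grooming, still sniffing,
#' immobility).
#'
#' @param catalog A [behavior_catalog()].
#' @return Integer vector of behavior ids.
#' @export
ambulatory_behaviors <- function(catalog = behavior_catalog()) {
  amb <- c(
    "locomotion fast", "locomotion straight", "locomotion turn right",
    "locomotion turn left", "still turn right", "still turn left",
    "locomotion sniffing"
  )
  catalog$ids[match(amb, catalog$names)]
}

#' @rdname ambulatory_behaviors
#' @export
static_behaviors <- function(catalog = behavior_catalog()) {
  setdiff(catalog$ids, ambulatory_behaviors(catalog))
}

#' Per-frame behavior labels with episode structure
#'
#' Container for a per-frame behavior label sequence. Unlabeled frames are
#' `NA`. The episode table lists maximal runs of identical labels as
#' half-open frame intervals `[start, end)`.
#'
#' @param labels Integer vector of behavior ids (0-11) or `NA` for
#'   unlabeled frames.
#' @param frame_rate Frames per second of the label sequence.
#' @return An object of class `behavior_labels`: list with `labels`,
#'   `frame_rate`, and `episodes` (data.frame `start`, `end`, `behavior`;
#'   `end` exclusive, 1-based `start`).
#' @export
behavior_labels <- function(labels, frame_rate) {
  stopifnot(is.numeric(frame_rate), frame_rate > 0, length(labels) > 0)
  labels <- as.integer(labels)
  if (any(!is.na(labels) & (labels < 0L | labels > 11L)))
    stop("behavior ids must lie in 0..11")
  structure(
    list(labels = labels, frame_rate = frame_rate,
         episodes = episodes_from_labels(labels)),
    class = "behavior_labels"
  )
}

#' @export
print.behavior_labels <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf(
    "behavior_labels: %d frames at %g fps (%.1f s), %d episodes, %d unlabeled\n",
    n, x$frame_rate, n / x$frame_rate, nrow(x$episodes), sum(is.na(x$labels))
  ))
  invisible(x)
}

#' Episode table of a label sequence
#'
#' @param labels Integer label vector (`NA` = unlabeled; unlabeled runs are
#'   not episodes).
#' @return data.frame with columns `start` (1-based, inclusive), `end`
#'   (exclusive), `behavior`.
#' @export
episodes_from_labels <- function(labels) {
  n <- length(labels)
  if (n == 0L)
    return(data.frame(start = integer(), end = integer(), behavior = integer()))
  key <- ifelse(is.na(labels), -1L, as.integer(labels))
  change <- c(TRUE, key[-1] != key[-n])
  starts <- which(change)
  ends <- c(starts[-1], n + 1L)
  beh <- key[starts]
  keep <- beh >= 0L
  data.frame(start = starts[keep], end = ends[keep], behavior = beh[keep])
}

#' Align behavior labels to a lower frame rate
#'
#' Behavior video runs at a higher frame rate (40 fps) than calcium imaging
#' (20 fps). Alignment takes every k-th behavior frame, where k is the
#' (integer) ratio of the two rates, starting at the first frame.
#'
#' @param labels A [behavior_labels()] object.
#' @param to_rate Target frame rate; must divide the label frame rate.
#' @param n_frames Optional target length (trimmed or error if too short).
#' @return A [behavior_labels()] object at `to_rate`.
#' @export
align_labels <- function(labels, to_rate, n_frames = NULL) {
  stopifnot(inherits(labels, "behavior_labels"))
  ratio <- labels$frame_rate / to_rate
  if (abs(ratio - round(ratio)) > 1e-8 || ratio < 1)
    stop("target rate must be an integer divisor of the label frame rate")
  ratio <- as.integer(round(ratio))
  lab <- labels$labels[seq(1L, length(labels$labels), by = ratio)]
  if (!is.null(n_frames)) {
    if (length(lab) < n_frames) stop("label sequence shorter than raster")
    lab <- lab[seq_len(n_frames)]
  }
  behavior_labels(lab, to_rate)
}

#' Occupancy (fraction of labeled time) per behavior
#'
#' @param labels A [behavior_labels()] object.
#' @param catalog A [behavior_catalog()].
#' @return Named numeric vector over the 12 behaviors summing to 1 (over
#'   labeled frames).
#' @export
behavior_occupancy <- function(labels, catalog = behavior_catalog()) {
  lab <- labels$labels[!is.na(labels$labels)]
  if (length(lab) == 0L) stop("no labeled frames")
  counts <- tabulate(lab + 1L, nbins = length(catalog$ids))
  stats::setNames(counts / sum(counts), catalog$names)
}
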