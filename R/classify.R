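#' Behavior information of a single cell
#'
#' Mutual-information-style tuning statistic in bits per event:
#' `BI = sum_i p_i (f_i / f) log2(f_i / f)`, where `p_i` is the fraction
#' of (labeled) time spent in behavior `i`, `f_i` the cell's mean event
#' frequency during behavior `i`, and `f` its overall mean event
#' frequency. Behaviors with `f_i = 0` contribute 0 (the x log x limit).
#'
#' @param events Numeric vector of per-frame event amplitudes for one
#'   cell.
#' @param labels [behavior_labels()] at the raster frame rate.
#' @return List of class `behavior_information`: `bi` (bits; `NA` for a
#'   never-active cell), `p` (occupancy), `f_i` (per-behavior rates),
#'   `f` (overall rate).
#' @export
behavior_information <- function(events, labels) {
  stopifnot(inherits(labels, "behavior_labels"),
            length(events) == length(labels$labels))
  ok <- !is.na(labels$labels)
  lab <- labels$labels[ok]
  ev <- events[ok]
  counts <- tabulate(lab + 1L, nbins = 12)
  p <- counts / sum(counts)
  sums <- vapply(0:11, function(b) sum(ev[lab == b]), numeric(1))
  f_i <- ifelse(counts > 0, sums / (counts / labels$frame_rate), 0)
  f <- sum(ev) / (length(ev) / labels$frame_rate)
  bi <- if (f > 0) {
    r <- f_i / f
    sum(ifelse(p > 0 & r > 0, p * r * log2(r), 0))
  } else NA_real_
  structure(list(bi = bi, p = p, f_i = f_i, f = f), class = "behavior_information")
}

# shuffled per-behavior amplitude-sum matrix (n_shuffles x 12) for one cell;
# "permute" re-draws event positions uniformly, "circular" shifts the whole
# train (preserving inter-event structure and autocorrelation)
.shuffled_sums <- function(events, labels, n_shuffles,
                           method = c("permute", "circular")) {
  method <- match.arg(method)
  ok <- !is.na(labels$labels)
  lab <- labels$labels[ok]
  ev <- events[ok]
  if (method == "permute") {
    amps <- ev[ev > 0]
    return(cpp_shuffle_behavior_sums(amps, as.integer(lab), 12L,
                                     as.integer(n_shuffles)))
  }
  n <- length(ev)
  pos <- which(ev > 0)
  amps <- ev[pos]
  shifts <- sample.int(n, n_shuffles, replace = TRUE)
  out <- matrix(0, n_shuffles, 12)
  for (s in seq_len(n_shuffles)) {
    b <- lab[((pos - 1L + shifts[s]) %% n) + 1L]
    sums <- rowsum(amps, b)
    out[s, as.integer(rownames(sums)) + 1L] <- sums[, 1]
  }
  out
}

.bi_from_sums <- function(sums, p, counts, frame_rate, f) {
  # sums: n x 12 amplitude sums; returns BI per row
  time_i <- counts / frame_rate
  r <- sweep(sums, 2, ifelse(time_i > 0, time_i, Inf), "/") / f
  term <- ifelse(r > 0, r * log2(r), 0)
  as.numeric(term %*% p)
}

#' Detect a behavior-active cell by shuffle significance of BI
#'
#' The cell's events are randomly re-positioned among the labeled frames
#' (`n_shuffles` independent permutations); the cell is behavior-active
#' when its observed behavior information exceeds the shuffled mean by
#' more than `sigma_threshold` shuffled SDs.
#'
#' @param events Per-frame event amplitudes of one cell.
#' @param labels [behavior_labels()] at the raster rate.
#' @param n_shuffles Number of event permutations (default 1000).
#' @param sigma_threshold Significance threshold in shuffled SDs
#'   (default 4).
#' @param method Null model: `"permute"` (uniform re-positioning of the
#'   events, the default) or `"circular"` (random circular shift of the
#'   whole train, preserving its autocorrelation).
#' @param seed RNG seed.
#' @return List with `is_active`, `sigma_level`, `bi`, `shuffle_mean`,
#'   `shuffle_sd`.
#' @export
classify_behavior_active <- function(events, labels, n_shuffles = 1000,
                                     sigma_threshold = 4,
                                     method = c("permute", "circular"),
                                     seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  obs <- behavior_information(events, labels)
  if (is.na(obs$bi) || obs$f == 0)
    return(list(is_active = FALSE, sigma_level = NA_real_, bi = NA_real_,
                shuffle_mean = NA_real_, shuffle_sd = NA_real_))
  ok <- !is.na(labels$labels)
  counts <- tabulate(labels$labels[ok] + 1L, nbins = 12)
  sums <- .shuffled_sums(events, labels, n_shuffles, method)
  bi_null <- .bi_from_sums(sums, obs$p, counts, labels$frame_rate, obs$f)
  m <- mean(bi_null); s <- stats::sd(bi_null)
  if (!is.finite(s) || s == 0)
    return(list(is_active = FALSE, sigma_level = NA_real_, bi = obs$bi,
                shuffle_mean = m, shuffle_sd = s))
  sigma_level <- (obs$bi - m) / s
  list(is_active = sigma_level > sigma_threshold, sigma_level = sigma_level,
       bi = obs$bi, shuffle_mean = m, shuffle_sd = s)
}

#' Behavior-active detection for all cells of a raster
#'
#' @param raster An [event_raster()].
#' @param labels [behavior_labels()] at the raster rate.
#' @inheritParams classify_behavior_active
#' @return data.frame with one row per neuron (`is_active`,
#'   `sigma_level`, `bi`).
#' @export
classify_cells_active <- function(raster, labels, n_shuffles = 1000,
                                  sigma_threshold = 4,
                                  method = c("permute", "circular"),
                                  seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(raster$events)), function(i) {
    r <- classify_behavior_active(raster$events[i, ], labels,
                                  n_shuffles, sigma_threshold, method)
    data.frame(neuron = i, is_active = r$is_active,
               sigma_level = r$sigma_level, bi = r$bi)
  })
  do.call(rbind, rows)
}

#' Per-behavior activation significance by event shuffling
#'
#' One-sided per-behavior alternative to the session-level BI criterion:
#' the cell's in-behavior event rate is compared with the rate
#' distribution under random event permutations; the cell is active for
#' the behavior when its rate exceeds the shuffled mean by more than
#' `sigma_threshold` shuffled SDs. Behaviors occupying less than
#' `min_duration_s` are excluded (`NA`).
#'
#' @inheritParams classify_behavior_active
#' @param behavior_id Behavior id (0-11).
#' @param min_duration_s Occupancy floor (default 5 s).
#' @return List with `is_active`, `sigma_level`, `rate`.
#' @export
classify_active_per_behavior <- function(events, labels, behavior_id,
                                         n_shuffles = 1000,
                                         sigma_threshold = 4,
                                         min_duration_s = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ok <- !is.na(labels$labels)
  counts <- tabulate(labels$labels[ok] + 1L, nbins = 12)
  occ_s <- counts[behavior_id + 1L] / labels$frame_rate
  if (occ_s < min_duration_s)
    return(list(is_active = NA, sigma_level = NA_real_, rate = NA_real_))
  obs_rate <- sum(events[ok][labels$labels[ok] == behavior_id]) / occ_s
  sums <- .shuffled_sums(events, labels, n_shuffles)
  null_rates <- sums[, behavior_id + 1L] / occ_s
  m <- mean(null_rates); s <- stats::sd(null_rates)
  if (!is.finite(s) || s == 0)
    return(list(is_active = FALSE, sigma_level = NA_real_, rate = obs_rate))
  z <- (obs_rate - m) / s
  list(is_active = z > sigma_threshold, sigma_level = z, rate = obs_rate)
}

#' Activation occurrence of a cell for one behavior
#'
#' Fraction of the behavior's episodes during which the cell emits at
#' least one deconvolved event (any positive amplitude).
#'
#' @param events Per-frame event amplitudes of one cell.
#' @param labels [behavior_labels()] at the raster rate.
#' @param behavior_id Behavior id.
#' @return Fraction in `[0, 1]`.
#' @export
activation_occurrence <- function(events, labels, behavior_id) {
  ep <- labels$episodes[labels$episodes$behavior == behavior_id, ,
                        drop = FALSE]
  if (nrow(ep) == 0) stop("behavior has no episodes")
  hits <- vapply(seq_len(nrow(ep)), function(i)
    any(events[ep$start[i]:(ep$end[i] - 1L)] > 0), logical(1))
  mean(hits)
}

#' Behavior-silent classification from activation occurrence
#'
#' A cell is behavior-silent for a behavior when its activation
#' occurrence is strictly below the threshold (default 0.025, i.e.
#' active in fewer than 2.5% of the behavior's episodes).
#'
#' @param occurrence Numeric vector/matrix of occurrence values.
#' @param threshold Strict upper bound (default 0.025).
#' @return Logical of the same shape.
#' @export
classify_behavior_silent <- function(occurrence, threshold = 0.025) {
  occurrence < threshold
}

#' Behavior-inactive classification from mean in-behavior rate
#'
#' Alternate definition: a cell is behavior-inactive for a behavior when
#' its mean event rate during that behavior is strictly below
#' `rate_threshold` (default 0.1 events/s). Behaviors occupying less than
#' `min_duration_s` yield `NA`.
#'
#' @param raster An [event_raster()].
#' @param labels [behavior_labels()] at the raster rate.
#' @param rate_threshold Strict rate bound (default 0.1 events/s).
#' @param min_duration_s Occupancy floor (default 5 s).
#' @return Logical matrix, neurons x 12 behaviors.
#' @export
classify_behavior_inactive <- function(raster, labels, rate_threshold = 0.1,
                                       min_duration_s = 5) {
  out <- matrix(NA, nrow(raster$events), 12)
  for (b in 0:11) {
    sel <- which(!is.na(labels$labels) & labels$labels == b)
    occ_s <- length(sel) / raster$rate
    if (occ_s < min_duration_s) next
    rates <- rowSums(raster$events[, sel, drop = FALSE]) / occ_s
    out[, b + 1L] <- rates < rate_threshold
  }
  out
}

#' Behavior-silent classification against a shuffled null
#'
#' Shuffle-based variant: the observed activation occurrence is compared
#' with the distribution of occurrences obtained from random permutations
#' of the cell's events; the cell is silent when the observed occurrence
#' falls strictly below the `percentile` quantile of that distribution.
#'
#' @inheritParams activation_occurrence
#' @param n_shuffles Number of permutations (default 1000).
#' @param percentile Lower quantile of the shuffled distribution
#'   (default 0.025).
#' @param seed RNG seed.
#' @return List with `is_silent`, `occurrence`, `null_quantile`.
#' @export
classify_silent_by_shuffle <- function(events, labels, behavior_id,
                                       n_shuffles = 1000,
                                       percentile = 0.025, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- activation_occurrence(events, labels, behavior_id)
  ok <- !is.na(labels$labels)
  ep <- labels$episodes[labels$episodes$behavior == behavior_id, ,
                        drop = FALSE]
  ep_id <- integer(length(labels$labels))
  for (i in seq_len(nrow(ep))) ep_id[ep$start[i]:(ep$end[i] - 1L)] <- i
  n_events <- sum(events[ok] > 0)
  if (n_events == 0)
    return(list(is_silent = TRUE, occurrence = obs, null_quantile = 0))
  null_occ <- cpp_shuffle_occurrence(as.integer(n_events),
                                     as.integer(ep_id[ok]),
                                     as.integer(nrow(ep)),
                                     as.integer(n_shuffles))
  q <- stats::quantile(null_occ, percentile, names = FALSE, type = 1)
  list(is_silent = obs < q, occurrence = obs, null_quantile = q)
}

#' Analytic silent-flag probability for a homogeneous Poisson cell
#'
#' Probability that a cell firing homogeneously at `rate` events/s is
#' flagged behavior-silent (occurrence strictly below `threshold`) given
#' the behavior's episode durations: the number of active episodes is
#' Poisson-binomial with per-episode success probabilities
#' `1 - exp(-rate * duration)`.
#'
#' @param durations_s Episode durations in seconds.
#' @param rate Event rate (events/s).
#' @param threshold Occurrence threshold (default 0.025).
#' @return Probability in `[0, 1]`.
#' @export
silent_flag_probability <- function(durations_s, rate, threshold = 0.025) {
  p <- 1 - exp(-rate * durations_s)
  m <- length(p)
  # exact Poisson-binomial pmf by dynamic-programming convolution
  pmf <- c(1, rep(0, m))
  for (pi in p) pmf <- c(pmf, 0)[1:(m + 1)] * (1 - pi) +
      c(0, pmf[1:m]) * pi
  k_max <- ceiling(threshold * m) - 1  # occurrence < threshold
  if (k_max < 0) return(0)
  sum(pmf[seq_len(k_max + 1)])
}

#' Full per-cell classification table
#'
#' Computes, for every neuron and behavior: activation occurrence,
#' behavior-silent and behavior-inactive flags, and the session-level
#' behavior-active flag (BI shuffle criterion).
#'
#' @param raster An [event_raster()].
#' @param labels [behavior_labels()] at the raster rate.
#' @param n_shuffles Shuffles for the BI criterion (default 1000).
#' @param sigma_threshold BI significance threshold (default 4).
#' @param occurrence_threshold Silent threshold (default 0.025).
#' @param rate_threshold Inactive threshold (default 0.1 events/s).
#' @param seed RNG seed.
#' @return List of class `cell_class_table`: `active` (per-neuron
#'   logical + sigma levels), `occurrence`, `silent`, `inactive`
#'   (neurons x behaviors matrices).
#' @export
cell_class_table <- function(raster, labels, n_shuffles = 1000,
                             sigma_threshold = 4,
                             occurrence_threshold = 0.025,
                             rate_threshold = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  act <- classify_cells_active(raster, labels, n_shuffles, sigma_threshold)
  n <- nrow(raster$events)
  occ <- matrix(NA_real_, n, 12)
  for (b in 0:11) {
    if (!any(labels$episodes$behavior == b)) next
    occ[, b + 1L] <- vapply(seq_len(n), function(i)
      activation_occurrence(raster$events[i, ], labels, b), numeric(1))
  }
  structure(list(
    active = act,
    occurrence = occ,
    silent = classify_behavior_silent(occ, occurrence_threshold),
    inactive = classify_behavior_inactive(raster, labels, rate_threshold)
  ), class = "cell_class_table")
}

#' Jaccard stability of cell classifications across sessions
#'
#' Intersection over union of the (registered cell, behavior) attribute
#' sets of two sessions, restricted to registered cell pairs. Measures
#' how consistently cells keep their behavior-active or behavior-silent
#' classification over time.
#'
#' @param flags_a,flags_b Logical matrices (neurons x behaviors) for the
#'   two sessions, or per-neuron logical vectors.
#' @param registry A [cell_registry()] mapping session-A to session-B
#'   cells.
#' @param behaviors Optional behavior-id subset (0-based columns).
#' @return Jaccard index in `[0, 1]`, or `NA` when the union is empty.
#' @export
jaccard_stability <- function(flags_a, flags_b, registry,
                              behaviors = NULL) {
  stopifnot(inherits(registry, "cell_registry"))
  p <- registry$pairs
  if (nrow(p) == 0) stop("empty registry")
  if (is.vector(flags_a)) flags_a <- matrix(flags_a, ncol = 1)
  if (is.vector(flags_b)) flags_b <- matrix(flags_b, ncol = 1)
  cols <- if (is.null(behaviors)) seq_len(ncol(flags_a)) else behaviors + 1L
  a <- flags_a[p$cell_a, cols, drop = FALSE]
  b <- flags_b[p$cell_b, cols, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  inter <- sum(a & b & ok, na.rm = TRUE)
  uni <- sum((a | b) & ok, na.rm = TRUE)
  if (uni == 0) return(NA_real_)
  inter / uni
}

#' Control registries for longitudinal analyses
#'
#' Two negative controls for cell registration:
#' * `shuffle_pairs`: randomly permutes the session-B cells among the
#'   registered pairs (fixed-point-free, so no pair keeps its partner);
#' * `closest_neighbor`: replaces every session-B cell with its nearest
#'   other session-B cell by centroid distance.
#'
#' @param registry A [cell_registry()] with centroids for the
#'   closest-neighbor mode.
#' @param mode Control mode.
#' @param seed RNG seed (shuffle mode).
#' @return A control [cell_registry()] of the same size.
#' @export
registry_controls <- function(registry,
                              mode = c("shuffle_pairs", "closest_neighbor"),
                              seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(registry, "cell_registry"))
  p <- registry$pairs
  n <- nrow(p)
  if (mode == "shuffle_pairs") {
    if (n < 2) stop("need at least 2 pairs to shuffle")
    if (!is.null(seed)) set.seed(seed)
    perm <- sample.int(n)
    fixed <- which(perm == seq_len(n))
    # break fixed points by cyclically swapping them
    if (length(fixed) == 1) {
      j <- if (fixed[1] == 1L) 2L else 1L
      perm[c(fixed, j)] <- perm[c(j, fixed)]
    } else if (length(fixed) > 1) {
      perm[fixed] <- perm[c(fixed[-1], fixed[1])]
    }
    p$cell_b <- p$cell_b[perm]
  } else {
    cb <- registry$centroids_b
    if (is.null(cb)) stop("closest_neighbor requires session-B centroids")
    if (nrow(cb) < 2) stop("need at least 2 session-B cells")
    p$cell_b <- vapply(p$cell_b, function(i) {
      d <- sqrt(rowSums(sweep(cb, 2, cb[i, ])^2))
      d[i] <- Inf
      d[!is.finite(rowSums(cb))] <- Inf
      which.min(d)
    }, integer(1))
  }
  structure(list(pairs = p, centroids_a = registry$centroids_a,
                 centroids_b = registry$centroids_b),
            class = "cell_registry")
}
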