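#' Neuronal activation map for one behavior
#'
#' Per-neuron mean deconvolved activity (events/s) restricted to the
#' frames of one behavior inside a time window. The map is flagged
#' invalid when the behavior occupies less than `min_duration_s` inside
#' the window (such maps are excluded from similarity analyses rather
#' than raising an error).
#'
#' @param raster An [event_raster()].
#' @param labels A [behavior_labels()] at the raster frame rate (use
#'   [align_labels()] first if needed).
#' @param behavior_id Behavior id (0-11).
#' @param frame_window Integer frame indices defining the window
#'   (default: the whole session).
#' @param min_duration_s Minimum sampled duration (default 5 s).
#' @return Object of class `activation_map`: list with `x` (per-neuron
#'   rate), `behavior`, `duration_s`, `valid`.
#' @export
activation_map <- function(raster, labels, behavior_id,
                           frame_window = NULL, min_duration_s = 5) {
  stopifnot(inherits(raster, "event_raster"),
            inherits(labels, "behavior_labels"))
  if (length(labels$labels) != ncol(raster$events))
    stop("labels and raster must cover the same frames")
  if (is.null(frame_window)) frame_window <- seq_len(ncol(raster$events))
  sel <- frame_window[!is.na(labels$labels[frame_window]) &
                        labels$labels[frame_window] == behavior_id]
  duration <- length(sel) / raster$rate
  x <- if (length(sel)) rowMeans(raster$events[, sel, drop = FALSE]) *
    raster$rate else rep(0, nrow(raster$events))
  structure(list(x = x, behavior = behavior_id, duration_s = duration,
                 valid = duration >= min_duration_s),
            class = "activation_map")
}

#' Activation similarity between two population maps
#'
#' Negative Euclidean distance between the unit-normalized activation
#' vectors: 0 for proportional maps, -sqrt(2) for orthogonal maps, and
#' -2 for anti-parallel maps. Scale-invariant and symmetric.
#'
#' @param x1,x2 [activation_map()] objects or plain numeric vectors.
#' @param require_valid Error if a map is flagged invalid (default TRUE).
#' @return Similarity in `[-2, 0]`.
#' @export
activation_similarity <- function(x1, x2, require_valid = TRUE) {
  v1 <- if (inherits(x1, "activation_map")) x1$x else x1
  v2 <- if (inherits(x2, "activation_map")) x2$x else x2
  if (require_valid &&
      ((inherits(x1, "activation_map") && !x1$valid) ||
       (inherits(x2, "activation_map") && !x2$valid)))
    stop("activation map invalid (sampled duration below the minimum)")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("similarity undefined for a zero vector")
  -sqrt(sum((v1 / n1 - v2 / n2)^2))
}

#' Cosine similarity between two population maps
#'
#' Dot product of the unit-normalized activation vectors, in `[-1, 1]`;
#' the alternate similarity metric.
#'
#' @inheritParams activation_similarity
#' @return Cosine similarity.
#' @export
dot_product_similarity <- function(x1, x2, require_valid = TRUE) {
  v1 <- if (inherits(x1, "activation_map")) x1$x else x1
  v2 <- if (inherits(x2, "activation_map")) x2$x else x2
  if (require_valid &&
      ((inherits(x1, "activation_map") && !x1$valid) ||
       (inherits(x2, "activation_map") && !x2$valid)))
    stop("activation map invalid (sampled duration below the minimum)")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("similarity undefined for a zero vector")
  sum(v1 * v2) / (n1 * n2)
}

#' Split-half and related similarity partitions
#'
#' Computes, for each behavior, the activation similarity between two
#' complementary partitions of the session:
#' * `halves`: first vs second half of the session;
#' * `five_min_partitions`: all balanced two-colorings of six 5-min
#'   slices (10 distinct splits up to swapping the halves);
#' * `odd_even_frames`: odd vs even frames;
#' * `alternating_episodes`: every other episode vs the rest.
#' Behaviors sampled for less than the minimum duration in either part
#' yield `NA`.
#'
#' @param raster An [event_raster()].
#' @param labels [behavior_labels()] at the raster rate.
#' @param scheme Partition scheme.
#' @param behaviors Behavior ids (default all 12).
#' @param min_duration_s Validity floor per part (default 5 s).
#' @return data.frame with columns `behavior`, `split`, `similarity`.
#' @export
similarity_partitions <- function(raster, labels,
                                  scheme = c("halves", "five_min_partitions",
                                             "odd_even_frames",
                                             "alternating_episodes"),
                                  behaviors = 0:11, min_duration_s = 5) {
  scheme <- match.arg(scheme)
  n <- ncol(raster$events)
  windows <- switch(scheme,
    halves = list(list(a = seq_len(n %/% 2), b = (n %/% 2 + 1L):n)),
    five_min_partitions = {
      slice_len <- floor(n / 6)
      slices <- lapply(0:5, function(k)
        (k * slice_len + 1L):(if (k == 5) n else (k + 1L) * slice_len))
      sets <- utils::combn(6, 3, simplify = FALSE)
      sets <- Filter(function(s) 1 %in% s, sets) # unordered: fix slice 1 in A
      lapply(sets, function(s)
        list(a = sort(unlist(slices[s])), b = sort(unlist(slices[-s]))))
    },
    odd_even_frames = list(list(a = seq(1L, n, 2L), b = seq(2L, n, 2L))),
    alternating_episodes = NULL)

  rows <- list()
  for (b in behaviors) {
    if (scheme == "alternating_episodes") {
      ep <- labels$episodes[labels$episodes$behavior == b, , drop = FALSE]
      if (nrow(ep) < 2) {
        rows[[length(rows) + 1L]] <-
          data.frame(behavior = b, split = 1L, similarity = NA_real_)
        next
      }
      fr <- function(rows_ep) unlist(lapply(seq_len(nrow(rows_ep)),
        function(i) rows_ep$start[i]:(rows_ep$end[i] - 1L)))
      odd <- ep[seq(1, nrow(ep), 2), , drop = FALSE]
      even <- ep[seq(2, nrow(ep), 2), , drop = FALSE]
      windows <- list(list(a = fr(odd), b = fr(even)))
    }
    for (w in seq_along(windows)) {
      m1 <- activation_map(raster, labels, b, windows[[w]]$a, min_duration_s)
      m2 <- activation_map(raster, labels, b, windows[[w]]$b, min_duration_s)
      sim <- if (m1$valid && m2$valid &&
                 sum(m1$x^2) > 0 && sum(m2$x^2) > 0)
        activation_similarity(m1, m2) else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(behavior = b, split = w, similarity = sim)
    }
  }
  do.call(rbind, rows)
}

#' Spatial-shuffle control for activation similarity
#'
#' Mean activation similarity after randomly permuting the neuron indices
#' of the second map, breaking the cell-to-cell correspondence while
#' preserving the value distribution.
#'
#' @param x1,x2 [activation_map()] objects or numeric vectors.
#' @param n_shuffles Number of permutations (default 10).
#' @param seed RNG seed.
#' @return Mean shuffled similarity.
#' @export
spatial_shuffle_similarity <- function(x1, x2, n_shuffles = 10,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v2 <- if (inherits(x2, "activation_map")) x2$x else x2
  mean(vapply(seq_len(n_shuffles), function(s)
    activation_similarity(x1, sample(v2), require_valid = FALSE),
    numeric(1)))
}

#' Inverse coefficient of variation of episode-wise activation
#'
#' Quantifies the consistency of a behavior's ensemble activation across
#' its episodes. Two aggregation schemes:
#' * `per_neuron` (default): per neuron, mean episode rate divided by its
#'   SD across episodes, averaged over neurons with a defined ratio;
#' * `ensemble`: the ensemble-mean activity is computed per episode and a
#'   single mean/SD ratio is taken across episodes.
#'
#' @param raster An [event_raster()].
#' @param labels [behavior_labels()] at the raster rate.
#' @param behavior_id Behavior id.
#' @param scheme Aggregation scheme.
#' @return Inverse CV (possibly `NA` when the SD is 0 everywhere).
#' @export
inverse_cv <- function(raster, labels, behavior_id,
                       scheme = c("per_neuron", "ensemble")) {
  scheme <- match.arg(scheme)
  ep <- labels$episodes[labels$episodes$behavior == behavior_id, ,
                        drop = FALSE]
  if (nrow(ep) < 2) stop("need at least 2 episodes of the behavior")
  rates <- vapply(seq_len(nrow(ep)), function(i) {
    fr <- ep$start[i]:(ep$end[i] - 1L)
    rowMeans(raster$events[, fr, drop = FALSE]) * raster$rate
  }, numeric(nrow(raster$events))) # neurons x episodes
  if (scheme == "ensemble") {
    ens <- colMeans(rates)
    s <- stats::sd(ens)
    return(if (s > 0) mean(ens) / s else NA_real_)
  }
  mu <- rowMeans(rates)
  s <- apply(rates, 1, stats::sd)
  icv <- ifelse(s > 0, mu / s, NA_real_)
  if (all(is.na(icv))) return(NA_real_)
  mean(icv, na.rm = TRUE)
}

#' Behavioral distance between two behaviors
#'
#' Sum over the six posture features of the exact 1-D Wasserstein-1
#' distance between the two behaviors' empirical feature distributions.
#' Symmetric, zero iff the empirical distributions coincide.
#'
#' @param features A [feature_series()].
#' @param labels [behavior_labels()] at the feature frame rate.
#' @param behavior_i,behavior_j Behavior ids.
#' @param min_frames Minimum valid frames per behavior (default 20).
#' @return Nonnegative distance.
#' @export
behavioral_distance <- function(features, labels, behavior_i, behavior_j,
                                min_frames = 20) {
  stopifnot(inherits(features, "feature_series"),
            inherits(labels, "behavior_labels"))
  sel_i <- which(labels$labels == behavior_i & features$valid)
  sel_j <- which(labels$labels == behavior_j & features$valid)
  if (length(sel_i) < min_frames || length(sel_j) < min_frames)
    stop("behavior has too few valid frames")
  sum(vapply(seq_len(6), function(k)
    wasserstein_1d(features$data[sel_i, k], features$data[sel_j, k]),
    numeric(1)))
}

#' Pairwise behavioral distance matrix
#'
#' @inheritParams behavioral_distance
#' @param behaviors Behavior ids (default all 12).
#' @return Symmetric matrix with `NA` for behaviors below the frame floor.
#' @export
behavioral_distance_matrix <- function(features, labels, behaviors = 0:11,
                                       min_frames = 20) {
  k <- length(behaviors)
  d <- matrix(NA_real_, k, k,
              dimnames = list(behaviors, behaviors))
  diag(d) <- 0
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    v <- tryCatch(behavioral_distance(features, labels, behaviors[a],
                                      behaviors[b], min_frames),
                  error = function(e) NA_real_)
    d[a, b] <- d[b, a] <- v
  }
  d
}

#' Coupling between neural and behavioral similarity
#'
#' For every pair of behaviors, compares the activation similarity
#' between the two behaviors' population maps (computed over the whole
#' session or a restricted window) with the behavioral similarity (the
#' negative behavioral distance). The coupling is the Spearman rank
#' correlation over the valid behavior pairs (66 pairs for a complete
#' 12-behavior catalog).
#'
#' @param raster An [event_raster()].
#' @param labels [behavior_labels()] at the behavior-video rate; aligned
#'   internally to the raster.
#' @param features [feature_series()] at the behavior-video rate.
#' @param window_s Optional activity-averaging window length (seconds from
#'   session start) for the recording-length analysis.
#' @param min_duration_s Activation-map validity floor (default 5 s).
#' @return List with `neural` and `behavioral` (12 x 12 similarity
#'   matrices), `rho` (Spearman), `n_pairs`.
#' @export
similarity_coupling <- function(raster, labels, features, window_s = NULL,
                                min_duration_s = 5) {
  lab20 <- align_labels(labels, raster$rate, ncol(raster$events))
  window <- if (is.null(window_s)) NULL
            else seq_len(min(ncol(raster$events),
                             round(window_s * raster$rate)))
  maps <- lapply(0:11, function(b)
    activation_map(raster, lab20, b, window, min_duration_s))
  neural <- matrix(NA_real_, 12, 12)
  for (a in 1:11) for (b in (a + 1):12) {
    if (maps[[a]]$valid && maps[[b]]$valid &&
        sum(maps[[a]]$x^2) > 0 && sum(maps[[b]]$x^2) > 0)
      neural[a, b] <- neural[b, a] <-
        activation_similarity(maps[[a]], maps[[b]])
  }
  dist_b <- behavioral_distance_matrix(features, labels)
  behavioral <- -dist_b
  iu <- upper.tri(neural)
  ok <- iu & !is.na(neural) & !is.na(behavioral)
  if (sum(ok) < 3) stop("fewer than 3 valid behavior pairs")
  rho <- stats::cor(neural[ok], behavioral[ok], method = "spearman")
  list(neural = neural, behavioral = behavioral, rho = rho,
       n_pairs = sum(ok))
}
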