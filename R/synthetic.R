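#' Default per-behavior posture-feature distributions
#'
#' Per-behavior means and standard deviations of the six posture features
#' used by the synthetic generator. Values are chosen to be realistic for
#' a mouse in a 40 x 40 cm open field and to satisfy the same qualitative
#' criteria that define the behaviors (fast locomotion above ~15 cm/s,
#' turns with a nonzero signed movement angle, sniffing with an elongated
#' body, rearing/head-up with high head elevation, grooming with large
#' movement-angle variability and a moving head on a still body,
#' immobility with a still head). Means of distinct behaviors are at least
#' ~5 SDs apart in at least one feature.
#'
#' @return Named list, one entry per behavior name, each a list with
#'   numeric `mean` and `sd` vectors of length 6 (ordered as
#'   [feature_names()]).
#' @export
default_feature_params <- function() {
  # columns: body_speed, head_speed, movement_angle, body_length,
  #          neck_elongation, head_elevation
  m <- rbind(
    "locomotion fast"       = c(20.0, 4.0,  0.00, 6.0, 3.0, 0.8),
    "locomotion straight"   = c( 8.0, 4.0,  0.00, 6.0, 3.0, 0.8),
    "locomotion turn right" = c( 8.0, 9.0,  0.10, 6.0, 3.0, 0.8),
    "locomotion turn left"  = c( 8.0, 9.0, -0.10, 6.0, 3.0, 0.8),
    "still turn right"      = c( 0.5, 9.0,  0.10, 6.0, 3.0, 0.8),
    "still turn left"       = c( 0.5, 9.0, -0.10, 6.0, 3.0, 0.8),
    "head up"               = c( 0.3, 1.5,  0.00, 6.0, 1.5, 3.0),
    "rearing"               = c( 0.3, 1.5,  0.00, 3.5, 1.5, 3.5),
    "grooming"              = c( 0.3, 5.0,  0.00, 4.0, 2.5, 0.8),
    "locomotion sniffing"   = c( 6.0, 4.0,  0.00, 8.5, 4.5, 0.8),
    "still sniffing"        = c( 0.4, 2.0,  0.00, 8.5, 4.5, 0.8),
    "immobility"            = c(0.15, 0.3,  0.00, 6.0, 3.0, 0.8)
  )
  s <- rbind(
    "locomotion fast"       = c(2.00, 0.50, 0.020, 0.30, 0.20, 0.15),
    "locomotion straight"   = c(1.20, 0.50, 0.020, 0.30, 0.20, 0.15),
    "locomotion turn right" = c(1.20, 0.80, 0.020, 0.30, 0.20, 0.15),
    "locomotion turn left"  = c(1.20, 0.80, 0.020, 0.30, 0.20, 0.15),
    "still turn right"      = c(0.15, 0.80, 0.020, 0.30, 0.20, 0.15),
    "still turn left"       = c(0.15, 0.80, 0.020, 0.30, 0.20, 0.15),
    "head up"               = c(0.10, 0.30, 0.020, 0.30, 0.15, 0.15),
    "rearing"               = c(0.10, 0.30, 0.020, 0.25, 0.15, 0.15),
    "grooming"              = c(0.10, 0.60, 0.200, 0.25, 0.20, 0.15),
    "locomotion sniffing"   = c(1.00, 0.50, 0.020, 0.30, 0.20, 0.15),
    "still sniffing"        = c(0.15, 0.40, 0.020, 0.30, 0.20, 0.15),
    "immobility"            = c(0.08, 0.10, 0.010, 0.30, 0.20, 0.15)
  )
  cat <- behavior_catalog()
  stats::setNames(lapply(seq_along(cat$ids), function(i)
    list(mean = stats::setNames(m[cat$names[i], ], feature_names()),
         sd = stats::setNames(s[cat$names[i], ], feature_names()))),
    cat$names)
}

#' Ground-truth behavioral distance between Gaussian feature models
#'
#' Sum over the six features of the exact 1-D Wasserstein-1 distance
#' between the two behaviors' (Gaussian) feature distributions; for
#' N(m1, s1) and N(m2, s2) this is `E|dm + ds * Z|` with `dm = m1 - m2`,
#' `ds = s1 - s2`, `Z` standard normal.
#'
#' @param params Feature parameters as from [default_feature_params()].
#' @param i,j Behavior ids (0-11) or names.
#' @return Nonnegative distance (the `true_behavioral_distance_matrix`
#'   variant returns the full 12 x 12 matrix).
#' @export
true_behavioral_distance <- function(params, i, j) {
  cat <- behavior_catalog()
  if (is.numeric(i)) i <- cat$names[i + 1L]
  if (is.numeric(j)) j <- cat$names[j + 1L]
  dm <- params[[i]]$mean - params[[j]]$mean
  ds <- params[[i]]$sd - params[[j]]$sd
  w <- ifelse(abs(ds) < 1e-12, abs(dm), {
    c0 <- dm / ds
    abs(ds) * (2 * stats::dnorm(c0) + c0 * (2 * stats::pnorm(c0) - 1))
  })
  sum(w)
}

#' @rdname true_behavioral_distance
#' @export
true_behavioral_distance_matrix <- function(params = default_feature_params()) {
  cat <- behavior_catalog()
  n <- length(cat$ids)
  d <- matrix(0, n, n, dimnames = list(cat$names, cat$names))
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    d[a, b] <- d[b, a] <- true_behavioral_distance(params, cat$names[a],
                                                   cat$names[b])
  }
  d
}

#' Ground-truth tuning specification for synthetic neurons
#'
#' Plants three neuron classes: behavior-active cells whose event rate is
#' multiplied during behaviors similar to a preferred behavior,
#' behavior-silent cells that emit no events during their preferred
#' behavior, and untuned cells firing homogeneously. Active cells carry a
#' per-episode multiplicative lognormal gain (mean 1, sd
#' `episode_gain_sd`) emulating episode-to-episode ensemble variability;
#' untuned and silent cells are homogeneous so that they form a clean null
#' class. Tuning of active cells decays with ground-truth behavioral
#' distance from the preferred behavior with scale `tuning_width` (0 means
#' strictly one assigned behavior).
#'
#' @param n_neurons Number of neurons (default 300).
#' @param frac_active,frac_silent Fractions of planted behavior-active and
#'   behavior-silent cells (defaults 0.1 each); the remainder is untuned.
#' @param baseline_rate Baseline event rate, events/s (default 0.5).
#' @param active_gain Multiplicative rate factor at the preferred behavior
#'   (default 5; must exceed 1).
#' @param silent_rate Event rate of silent cells during their preferred
#'   behavior (default 0).
#' @param episode_gain_sd SD of the per-episode lognormal gain of active
#'   cells (default 0.5).
#' @param tuning_width Behavioral-distance scale of graded tuning
#'   (default 1.5; same units as [true_behavioral_distance()]).
#' @param silent_radius Behavioral-distance radius of silencing: a silent
#'   cell is silent for every behavior within this distance of its
#'   preferred behavior (default 1.5; 0 restricts silencing to the
#'   preferred behavior alone). Cells are thus silent during one to a few
#'   behaviors, as observed in vivo.
#' @param seed RNG seed for class and preferred-behavior assignment.
#' @return Object of class `tuning_spec`.
#' @export
tuning_spec <- function(n_neurons = 300, frac_active = 0.1,
                        frac_silent = 0.1, baseline_rate = 0.5,
                        active_gain = 5, silent_rate = 0,
                        episode_gain_sd = 0.5, tuning_width = 1.5,
                        silent_radius = 1.5, seed = NULL) {
  stopifnot(baseline_rate >= 0, silent_rate >= 0, active_gain > 1,
            episode_gain_sd >= 0, tuning_width >= 0, silent_radius >= 0,
            frac_active + frac_silent <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_act <- round(frac_active * n_neurons)
  n_sil <- round(frac_silent * n_neurons)
  class_of <- rep("untuned", n_neurons)
  idx <- sample.int(n_neurons)
  class_of[idx[seq_len(n_act)]] <- "active"
  class_of[idx[n_act + seq_len(n_sil)]] <- "silent"
  preferred <- rep(NA_integer_, n_neurons)
  tuned <- class_of != "untuned"
  preferred[tuned] <- sample(0:11, sum(tuned), replace = TRUE)
  structure(list(n_neurons = n_neurons, class_of = class_of,
                 preferred = preferred, baseline_rate = baseline_rate,
                 active_gain = active_gain, silent_rate = silent_rate,
                 episode_gain_sd = episode_gain_sd,
                 tuning_width = tuning_width,
                 silent_radius = silent_radius),
            class = "tuning_spec")
}

#' dSPN-like and iSPN-like generator presets
#'
#' Two tuning presets emulating the qualitative contrast between the
#' direct and indirect striatal pathway: the dSPN-like preset has more
#' planted behavior-active cells, low episode-to-episode gain variability
#' (consistent activation) and smoothly distance-graded tuning, so that
#' its population similarity structure tracks behavioral similarity; the
#' iSPN-like preset has more planted behavior-silent cells, high episode
#' variability and narrow tuning (inconsistent activation, encoding
#' biased toward silencing, weaker coupling to behavioral similarity).
#'
#' @param n_neurons Number of neurons.
#' @param seed RNG seed.
#' @return A [tuning_spec()].
#' @export
dspn_tuning <- function(n_neurons = 300, seed = NULL) {
  tuning_spec(n_neurons, frac_active = 0.25, frac_silent = 0.08,
              episode_gain_sd = 0.25, tuning_width = 3, seed = seed)
}

#' @rdname dspn_tuning
#' @export
ispn_tuning <- function(n_neurons = 300, seed = NULL) {
  tuning_spec(n_neurons, frac_active = 0.15, frac_silent = 0.25,
              episode_gain_sd = 1.0, tuning_width = 0.75, seed = seed)
}

#' Per-neuron, per-behavior ground-truth event rates
#'
#' @param tuning A [tuning_spec()].
#' @param behavior_distances 12 x 12 ground-truth behavioral distance
#'   matrix (defaults to the one implied by [default_feature_params()]).
#' @return Matrix (neurons x 12) of event rates in events/s.
#' @export
tuning_rate_table <- function(tuning,
                              behavior_distances =
                                true_behavioral_distance_matrix()) {
  n_beh <- 12L
  rates <- matrix(tuning$baseline_rate, tuning$n_neurons, n_beh)
  for (i in seq_len(tuning$n_neurons)) {
    if (tuning$class_of[i] == "active") {
      d <- behavior_distances[tuning$preferred[i] + 1L, ]
      k <- if (tuning$tuning_width > 0) exp(-d / tuning$tuning_width)
           else as.numeric(d == 0)
      rates[i, ] <- tuning$baseline_rate * (1 + (tuning$active_gain - 1) * k)
    } else if (tuning$class_of[i] == "silent") {
      d <- behavior_distances[tuning$preferred[i] + 1L, ]
      radius <- if (is.null(tuning$silent_radius)) 0 else tuning$silent_radius
      rates[i, d <= radius] <- tuning$silent_rate
    }
  }
  rates
}

#' Generate a Markovian behavior label sequence
#'
#' Episodes are drawn from a stationary Markov chain over the 12-behavior
#' catalog; dwell times are geometric at frame resolution with the
#' requested per-behavior means, emulating the episodic structure of
#' open-field behavior.
#'
#' @param catalog A [behavior_catalog()].
#' @param duration_s Session duration in seconds.
#' @param transition 12 x 12 row-stochastic transition matrix between
#'   episodes (default: uniform over the 11 other behaviors).
#' @param dwell_mean_s Mean episode dwell time in seconds, scalar or
#'   per-behavior vector (default 2.5 s; must be at least 0.1 s).
#' @param frame_rate Frames per second (default 40).
#' @param seed RNG seed.
#' @return A [behavior_labels()] with no unlabeled frames.
#' @export
generate_behavior_sequence <- function(catalog = behavior_catalog(),
                                       duration_s,
                                       transition = NULL,
                                       dwell_mean_s = 2.5,
                                       frame_rate = 40,
                                       seed = NULL) {
  n_beh <- length(catalog$ids)
  if (is.null(transition)) {
    transition <- matrix(1 / (n_beh - 1), n_beh, n_beh)
    diag(transition) <- 0
  }
  stopifnot(is.matrix(transition), nrow(transition) == n_beh,
            ncol(transition) == n_beh, frame_rate > 0)
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
    stop("transition matrix must be row-stochastic")
  dwell_mean_s <- rep_len(dwell_mean_s, n_beh)
  if (any(dwell_mean_s < 0.1)) stop("dwell_mean_s must be >= 0.1 s")
  n_frames <- round(duration_s * frame_rate)
  if (n_frames < 1) stop("duration too short to contain one episode")
  if (!is.null(seed)) set.seed(seed)

  labels <- integer(0)
  state <- sample.int(n_beh, 1)
  while (length(labels) < n_frames) {
    mean_frames <- dwell_mean_s[state] * frame_rate
    dwell <- stats::rgeom(1, prob = 1 / mean_frames) + 1L
    labels <- c(labels, rep(state - 1L, dwell))
    state <- sample.int(n_beh, 1, prob = transition[state, ])
  }
  behavior_labels(labels[seq_len(n_frames)], frame_rate)
}

#' Generate posture features from a label sequence
#'
#' Draws each frame's six-feature vector independently from the
#' per-behavior Gaussian in `feature_params`, with SDs scaled by
#' `noise_sd`. The parameters are attached as attribute
#' `"feature_params"` so ground-truth behavioral distances remain
#' available downstream.
#'
#' @param labels A [behavior_labels()].
#' @param feature_params Per-behavior distributions
#'   ([default_feature_params()] layout).
#' @param noise_sd Global multiplier on the per-behavior SDs (default 1;
#'   0 gives point masses at the means).
#' @param seed RNG seed.
#' @return A [feature_series()].
#' @export
generate_feature_series <- function(labels,
                                    feature_params = default_feature_params(),
                                    noise_sd = 1, seed = NULL) {
  stopifnot(inherits(labels, "behavior_labels"), noise_sd >= 0)
  cat <- behavior_catalog()
  missing_b <- setdiff(cat$names[unique(labels$labels) + 1L],
                       names(feature_params))
  if (length(missing_b))
    stop("feature_params missing behaviors: ",
         paste(missing_b, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels$labels)
  out <- matrix(NA_real_, n, 6)
  for (b in unique(labels$labels)) {
    idx <- which(labels$labels == b)
    p <- feature_params[[cat$names[b + 1L]]]
    noise <- matrix(stats::rnorm(length(idx) * 6), length(idx), 6)
    out[idx, ] <- rep(p$mean, each = length(idx)) +
      noise * rep(p$sd * noise_sd, each = length(idx))
  }
  fs <- feature_series(out, labels$frame_rate)
  attr(fs, "feature_params") <- feature_params
  fs
}

#' Construct a pose track realizing a feature series
#'
#' Inverse construction used to exercise the feature computation end to
#' end: a body-center trajectory is integrated from the body-speed and
#' movement-angle channels, and the eight body parts are placed around it
#' so that [compute_features()] recovers the input features. Head speed is
#' realized by the rotation of the head offset plus a forward-backward
#' head-bob oscillation whose amplitude is matched in root-mean-square;
#' it is therefore recovered in time-averaged (smoothed) value rather than
#' frame by frame. Documented round-trip tolerances (mean absolute error
#' after 20-frame smoothing, interior frames): body speed 0.6 cm/s,
#' movement angle 0.03 rad, body length / neck elongation / head elevation
#' 0.05 cm, head speed 25% relative.
#'
#' @param features A [feature_series()].
#' @param seed RNG seed (used for the low-likelihood injection only).
#' @param low_likelihood_fraction Fraction of (frame, body part) cells
#'   whose likelihood is set below 0.9 to exercise confidence filtering.
#' @param origin Starting body-center position (cm).
#' @return A [pose_track()] at the feature frame rate.
#' @export
generate_pose_track <- function(features, seed = NULL,
                                low_likelihood_fraction = 0,
                                origin = c(20, 20)) {
  stopifnot(inherits(features, "feature_series"),
            low_likelihood_fraction >= 0, low_likelihood_fraction <= 1)
  f <- features$data
  if (any(!is.finite(f))) stop("features must be finite")
  bs <- f[, "body_speed"]; hs <- f[, "head_speed"]
  ang <- f[, "movement_angle"]; bl <- f[, "body_length"]
  ne <- f[, "neck_elongation"]; he <- f[, "head_elevation"]
  if (any(ne <= 0) || any(bl - ne <= 0) || any(he < 0))
    stop("infeasible feature combination (nonpositive segment lengths)")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(f)
  fps <- features$frame_rate

  # Posture cannot jump rigidly from frame to frame: the geometry channels
  # (angles, segment lengths, target head speed) are low-passed over 0.5 s
  # before constructing the skeleton, which is why round-trip accuracy is
  # stated on 20-frame-smoothed features.
  lp <- function(v) {
    w <- min(20L, n)
    as.numeric(stats::filter(c(rep(v[1], w), v, rep(v[n], w)),
                             rep(1 / w, w), sides = 2))[(w + 1):(w + n)]
  }
  ang <- lp(ang); bl <- lp(bl); ne <- lp(ne); he <- lp(he); hs <- lp(hs)

  omega <- ang / 2                       # heading increment per frame
  theta <- cumsum(c(0, omega[-n]))
  ux <- cos(theta); uy <- sin(theta)
  px <- -uy; py <- ux                    # left-hand perpendicular

  step <- bs / fps
  x <- origin[1] + cumsum(c(0, (step * ux)[-n]))
  y <- origin[2] + cumsum(c(0, (step * uy)[-n]))

  # head-bob oscillation along the body axis; amplitude matches the target
  # head speed in RMS after accounting for the rotation-induced component
  c_off <- ne + he + 0.5                 # camera offset from body center
  rot_speed <- c_off * abs(omega) * fps
  osc_freq <- 4                          # Hz
  Omega <- 2 * pi * osc_freq
  attn <- sin(Omega / fps) / (Omega / fps)  # central-difference attenuation
  a_vel <- sqrt(2 * pmax(hs^2 - rot_speed^2, 0))
  a_pos <- a_vel / (Omega * attn)
  osc <- a_pos * sin(Omega * (seq_len(n) - 1) / fps)

  neck_x <- x + ne * ux; neck_y <- y + ne * uy
  tail_x <- x - (bl - ne) * ux; tail_y <- y - (bl - ne) * uy
  mid_x <- neck_x + he * ux; mid_y <- neck_y + he * uy
  parts <- list(
    nose = cbind(mid_x + 1.5 * ux, mid_y + 1.5 * uy),
    neck = cbind(neck_x, neck_y),
    left_ear = cbind(mid_x - 0.75 * px, mid_y - 0.75 * py),
    right_ear = cbind(mid_x + 0.75 * px, mid_y + 0.75 * py),
    camera = cbind(mid_x + (0.5 + osc) * ux, mid_y + (0.5 + osc) * uy),
    body_center = cbind(x, y),
    tail_start = cbind(tail_x, tail_y),
    tail_end = cbind(tail_x - 1.5 * ux, tail_y - 1.5 * uy)
  )

  lik <- matrix(1, n, 8)
  n_low <- round(low_likelihood_fraction * n * 8)
  if (n_low > 0) {
    cells <- sample.int(n * 8, n_low)
    lik[cells] <- stats::runif(n_low, 0.5, 0.89)
  }
  pose_track(
    stats::setNames(lapply(seq_along(parts), function(i)
      data.frame(x = parts[[i]][, 1], y = parts[[i]][, 2],
                 likelihood = lik[, i])), names(parts)),
    fps
  )
}

#' Generate a deconvolved event raster with planted tuning
#'
#' Per-frame event counts are inhomogeneous Poisson at the ground-truth
#' per-behavior rates of [tuning_rate_table()], converted to the imaging
#' frame rate. Active cells are additionally multiplied by an independent
#' per-neuron, per-episode lognormal gain (mean 1, sd
#' `tuning$episode_gain_sd`). Silent cells emit exactly zero events during
#' their preferred behavior.
#'
#' @param labels A [behavior_labels()] (behavior video rate); internally
#'   aligned to `imaging_rate` by frame decimation.
#' @param tuning A [tuning_spec()].
#' @param imaging_rate Imaging frames/s (default 20); the label frame rate
#'   must be an integer multiple.
#' @param seed RNG seed.
#' @param pathway Pathway tag for the raster.
#' @param behavior_distances Optional 12 x 12 ground-truth distance matrix
#'   for graded tuning.
#' @return List with `raster` (an [event_raster()]) and `truth` (aligned
#'   labels, tuning, rate table).
#' @export
generate_event_raster <- function(labels, tuning, imaging_rate = 20,
                                  seed = NULL, pathway = "dSPN",
                                  behavior_distances =
                                    true_behavioral_distance_matrix()) {
  stopifnot(inherits(labels, "behavior_labels"),
            inherits(tuning, "tuning_spec"))
  if (!is.null(seed)) set.seed(seed)
  lab20 <- align_labels(labels, imaging_rate)
  lab <- lab20$labels
  n_frames <- length(lab)
  rates <- tuning_rate_table(tuning, behavior_distances)

  # per-frame episode index (for the episode gain)
  ep <- lab20$episodes
  ep_of_frame <- integer(n_frames)
  for (e in seq_len(nrow(ep)))
    ep_of_frame[ep$start[e]:(ep$end[e] - 1L)] <- e

  lam_base <- rates[, lab + 1L, drop = FALSE] / imaging_rate
  events <- matrix(0, tuning$n_neurons, n_frames)
  active <- tuning$class_of == "active"
  sd_g <- tuning$episode_gain_sd
  for (i in seq_len(tuning$n_neurons)) {
    lam <- lam_base[i, ]
    if (active[i] && sd_g > 0) {
      sigma <- sqrt(log(1 + sd_g^2))
      g <- stats::rlnorm(nrow(ep), meanlog = -sigma^2 / 2, sdlog = sigma)
      lam <- lam * g[ep_of_frame]
    }
    events[i, ] <- stats::rpois(n_frames, lam)
  }
  raster <- event_raster(events, rate = imaging_rate, pathway = pathway)
  list(raster = raster,
       truth = list(true_labels = lab20, tuning = tuning,
                    rate_table = rates))
}

#' Generate a pair of sessions with partial cell overlap
#'
#' Emulates longitudinal imaging: a fraction of cells is shared between
#' the two sessions (listed in the returned registry together with cell
#' centroids); shared cells keep their tuning except for a `remap_fraction`
#' whose class and preferred behavior are redrawn, and non-shared cells
#' are fresh draws. The number of shared cells is
#' `round(overlap_fraction * n_neurons)`.
#'
#' @param tuning A [tuning_spec()] for session A.
#' @param overlap_fraction Fraction of cells present in both sessions.
#' @param remap_fraction Fraction of shared cells whose tuning is redrawn
#'   in session B.
#' @param seed RNG seed.
#' @param duration_s Session duration (default 900 s each).
#' @param pathway Pathway tag.
#' @param dwell_mean_s Mean episode dwell passed to the label generator.
#' @return List with `raster_a`, `raster_b`, `labels_a`, `labels_b`
#'   (behavior-rate labels), `registry` (a [cell_registry()]), and `truth`
#'   (both tunings and the shared-cell map).
#' @export
generate_session_pair <- function(tuning, overlap_fraction = 0.34,
                                  remap_fraction = 0, seed = NULL,
                                  duration_s = 900, pathway = "dSPN",
                                  dwell_mean_s = 2.5) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1,
            remap_fraction >= 0, remap_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- tuning$n_neurons
  n_shared <- round(overlap_fraction * n)
  if (n_shared < 2) stop("overlap yields fewer than 2 shared cells")

  shared_a <- sort(sample.int(n, n_shared))
  shared_b <- sample.int(n, n_shared) # positions in session B

  class_pool <- tuning$class_of
  tuning_b <- tuning
  tuning_b$class_of <- sample(class_pool, n, replace = TRUE)
  tuning_b$preferred <- ifelse(tuning_b$class_of == "untuned", NA_integer_,
                               sample(0:11, n, replace = TRUE))
  # shared cells inherit session-A tuning, except the remapped subset
  keep <- rep(TRUE, n_shared)
  n_remap <- round(remap_fraction * n_shared)
  if (n_remap > 0) keep[sample.int(n_shared, n_remap)] <- FALSE
  tuning_b$class_of[shared_b[keep]] <- tuning$class_of[shared_a[keep]]
  tuning_b$preferred[shared_b[keep]] <- tuning$preferred[shared_a[keep]]

  centroids_a <- matrix(stats::runif(2 * n, 0, 400), n, 2)
  centroids_b <- matrix(stats::runif(2 * n, 0, 400), n, 2)
  centroids_b[shared_b, ] <- centroids_a[shared_a, ] +
    matrix(stats::rnorm(2 * n_shared, 0, 2), n_shared, 2)

  labels_a <- generate_behavior_sequence(duration_s = duration_s,
                                         dwell_mean_s = dwell_mean_s)
  labels_b <- generate_behavior_sequence(duration_s = duration_s,
                                         dwell_mean_s = dwell_mean_s)
  ra <- generate_event_raster(labels_a, tuning, pathway = pathway)
  rb <- generate_event_raster(labels_b, tuning_b, pathway = pathway)
  registry <- cell_registry(
    data.frame(cell_a = shared_a, cell_b = shared_b),
    centroids_a, centroids_b
  )
  list(raster_a = ra$raster, raster_b = rb$raster,
       labels_a = labels_a, labels_b = labels_b, registry = registry,
       truth = list(tuning_a = tuning, tuning_b = tuning_b,
                    shared_a = shared_a, shared_b = shared_b,
                    remapped_a = shared_a[!keep]))
}

#' Destroy behavior locking by per-neuron circular time shifts
#'
#' Applies an independent circular shift to each neuron's event train,
#' preserving per-neuron event counts, amplitudes and autocorrelation
#' while destroying the relation to the behavior time series (emulating a
#' pharmacological disruption of behavior tuning).
#'
#' @param raster An [event_raster()].
#' @param seed RNG seed.
#' @param shifts Optional integer vector of per-neuron shifts (default:
#'   drawn uniformly over the session length).
#' @return An [event_raster()] of identical dimensions.
#' @export
scramble_tuning <- function(raster, seed = NULL, shifts = NULL) {
  stopifnot(inherits(raster, "event_raster"))
  if (!is.null(seed)) set.seed(seed)
  n_frames <- ncol(raster$events)
  n_neurons <- nrow(raster$events)
  if (is.null(shifts)) shifts <- sample.int(n_frames, n_neurons) - 1L
  shifts <- rep_len(as.integer(shifts), n_neurons) %% n_frames
  out <- raster$events
  for (i in seq_len(n_neurons)) {
    s <- shifts[i]
    if (s > 0)
      out[i, ] <- raster$events[i, c((n_frames - s + 1L):n_frames,
                                     1L:(n_frames - s))]
  }
  raster$events <- out
  raster
}
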