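#' Archetype partition of a frame subset
#'
#' A clustering of a fixed subset of frames, as produced by one
#' (embedding, mixture-replicate) pair or by the consensus step. Cluster
#' ids are contiguous starting at 1; `NA` marks frames dropped from the
#' partition (e.g. clusters below the size floor).
#'
#' @param frames Integer indices (into the full feature series) of the
#'   clustered frames.
#' @param cluster Integer cluster id per frame (or `NA`).
#' @param provenance Free-form list describing how the partition was
#'   produced.
#' @return Object of class `archetype_partition`.
#' @export
archetype_partition <- function(frames, cluster, provenance = list()) {
  stopifnot(length(frames) == length(cluster))
  keep_ids <- sort(unique(cluster[!is.na(cluster)]))
  cluster <- match(cluster, keep_ids)
  structure(list(frames = as.integer(frames), cluster = as.integer(cluster),
                 provenance = provenance), class = "archetype_partition")
}

#' @export
print.archetype_partition <- function(x, ...) {
  cat(sprintf("archetype_partition: %d frames, %d clusters, %d unassigned\n",
              length(x$frames), length(unique(stats::na.omit(x$cluster))),
              sum(is.na(x$cluster))))
  invisible(x)
}

#' Replicated nonlinear embedding of posture features
#'
#' Standardizes the six features (z-score over valid frames), draws a
#' subsample of frames, verifies the choice of embedding dimension against
#' the criterion that the leading principal components explain at least
#' 70% of the variance, and computes `n_replicates` t-SNE embeddings of
#' the same subsample (replicates differ by their random initialization).
#'
#' @param features A [feature_series()].
#' @param subsample_fraction Fraction of valid frames to embed
#'   (default 0.25).
#' @param n_dims Embedding dimension (default 3).
#' @param n_replicates Number of t-SNE replicates (default 10).
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity (default 30).
#' @param max_points Hard cap on the number of embedded frames
#'   (default 1500), keeping the exact t-SNE affordable.
#' @param max_iter t-SNE gradient-descent iterations (default 500).
#' @return List of class `feature_embeddings`: `frames` (the common
#'   subsample), `embeddings` (list of n x n_dims matrices), `pca_dims`
#'   (dimension suggested by the 70%-variance criterion).
#' @export
embed_features <- function(features, subsample_fraction = 0.25, n_dims = 3,
                           n_replicates = 10, seed = NULL, perplexity = 30,
                           max_points = 1500, max_iter = 500) {
  stopifnot(inherits(features, "feature_series"),
            subsample_fraction > 0, subsample_fraction <= 1,
            n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  valid <- which(features$valid)
  n_sub <- min(floor(subsample_fraction * length(valid)), max_points)
  if (n_sub <= 3 * perplexity + 2)
    stop("too few points for the requested perplexity")
  frames <- sort(sample(valid, n_sub))
  x <- scale(features$data[frames, , drop = FALSE])
  x <- x[, apply(is.finite(x), 2, all), drop = FALSE] # drop constant cols

  pca <- stats::prcomp(x)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  pca_dims <- which(cum >= 0.70)[1]
  if (!is.na(pca_dims) && pca_dims != n_dims)
    warning(sprintf(
      "70%%-variance PCA criterion suggests %d dimensions (using %d)",
      pca_dims, n_dims))

  embeddings <- lapply(seq_len(n_replicates), function(r) {
    y0 <- matrix(stats::rnorm(nrow(x) * n_dims, sd = 1e-4), nrow(x), n_dims)
    cpp_tsne_exact(x, y0, perplexity = perplexity, max_iter = max_iter)
  })
  structure(list(frames = frames, embeddings = embeddings,
                 pca_dims = pca_dims), class = "feature_embeddings")
}

#' Replicated Gaussian-mixture clustering of the embeddings
#'
#' For each embedding the number of mixture components is selected by BIC
#' over `g_range` (full-covariance model), and `n_gmm_replicates`
#' clusterings with random initializations (EM started from random
#' subsets) are fitted at that component count. With the defaults of 10
#' embeddings and 50 replicates this yields 500 partitions of the frame
#' subsample.
#'
#' @param embeddings A `feature_embeddings` object from [embed_features()].
#' @param n_gmm_replicates Mixture replicates per embedding (default 50).
#' @param g_range Candidate component counts for the BIC selection
#'   (default 8:30; deliberately above the 12-behavior catalog so that
#'   over-segmentation precedes merging).
#' @param seed RNG seed.
#' @return List of [archetype_partition()] objects.
#' @export
cluster_embeddings <- function(embeddings, n_gmm_replicates = 50,
                               g_range = 8:30, seed = NULL) {
  stopifnot(inherits(embeddings, "feature_embeddings"))
  if (!is.null(seed)) set.seed(seed)
  frames <- embeddings$frames
  n <- length(frames)
  partitions <- list()
  for (r in seq_along(embeddings$embeddings)) {
    y <- embeddings$embeddings[[r]]
    if (all(apply(y, 2, stats::sd) < 1e-12))
      stop("degenerate embedding: all points identical")
    sel <- mclust::Mclust(y, G = g_range, modelNames = "VVV",
                          verbose = FALSE)
    if (is.null(sel)) stop("mixture model selection failed")
    g_best <- sel$G
    for (j in seq_len(n_gmm_replicates)) {
      fit <- if (j == 1L) sel else
        tryCatch(
          mclust::Mclust(y, G = g_best, modelNames = "VVV", verbose = FALSE,
                         initialization = list(
                           subset = sample.int(n, min(n, 300)))),
          error = function(e) NULL)
      if (is.null(fit)) next
      partitions[[length(partitions) + 1L]] <- archetype_partition(
        frames, fit$classification,
        provenance = list(embedding = r, replicate = j, G = fit$G))
    }
  }
  if (!length(partitions)) stop("all mixture fits failed")
  partitions
}

#' Consensus partition from replicated clusterings
#'
#' Frames are grouped by how consistently they are co-assigned across the
#' input partitions: the frame-by-frame Hamming disagreement (1 minus the
#' fraction of partitions placing the two frames in the same cluster) is
#' clustered by average-linkage agglomeration and cut at
#' `cut_dissimilarity`. Consensus clusters smaller than
#' `min_cluster_frames` are dropped (their frames become unassigned).
#'
#' @param partitions List of [archetype_partition()] objects over the same
#'   frame subset.
#' @param min_cluster_frames Size floor (default 20 frames).
#' @param cut_dissimilarity Tree cut height in `[0, 1]` (default 0.5).
#' @return An [archetype_partition()]; the co-assignment frequency matrix
#'   is attached as attribute `"coassignment"`.
#' @export
consensus_clusters <- function(partitions, min_cluster_frames = 20,
                               cut_dissimilarity = 0.5) {
  stopifnot(length(partitions) >= 2)
  frames <- partitions[[1]]$frames
  for (p in partitions)
    if (!identical(p$frames, frames))
      stop("partitions must cover the same frame subset")
  n <- length(frames)
  co <- matrix(0, n, n)
  used <- 0L
  for (p in partitions) {
    cl <- p$cluster
    ok <- !is.na(cl)
    z <- matrix(0, n, max(cl[ok]))
    z[cbind(which(ok), cl[ok])] <- 1
    co <- co + tcrossprod(z)
    used <- used + 1L
  }
  co <- co / used
  hc <- stats::hclust(stats::as.dist(1 - co), method = "average")
  cl <- stats::cutree(hc, h = cut_dissimilarity)
  sizes <- table(cl)
  cl[cl %in% as.integer(names(sizes)[sizes < min_cluster_frames])] <- NA
  if (all(is.na(cl)))
    stop("all consensus clusters below the size floor")
  out <- archetype_partition(frames, cl,
                             provenance = list(consensus_of = used))
  attr(out, "coassignment") <- co
  out
}

#' Exact 1-D Wasserstein-1 distance between empirical samples
#'
#' Computed from the empirical quantile functions (no binning):
#' the integral of |F_x - F_y| over the merged support.
#'
#' @param x,y Numeric samples.
#' @return Nonnegative distance.
#' @export
wasserstein_1d <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("empty sample")
  all_v <- sort(c(x, y))
  if (length(all_v) < 2) return(0)
  sx <- sort(x); sy <- sort(y)
  t <- all_v[-length(all_v)]
  fx <- findInterval(t, sx) / length(sx)
  fy <- findInterval(t, sy) / length(sy)
  sum(abs(fx - fy) * diff(all_v))
}

# summed six-feature Wasserstein distance between two frame sets
.cluster_feature_distance <- function(feat_mat, idx_a, idx_b) {
  sum(vapply(seq_len(ncol(feat_mat)), function(k)
    wasserstein_1d(feat_mat[idx_a, k], feat_mat[idx_b, k]), numeric(1)))
}

#' Merge archetype clusters by Wasserstein distance
#'
#' Iterative agglomeration: while the smallest inter-cluster distance
#' (sum over the six features of 1-D Wasserstein distances between the
#' clusters' feature distributions) is below `cutoff`, the closest pair
#' is merged. Features are z-scored beforehand (over the partition's
#' assigned frames) so that the cutoff of 1 refers to SD units.
#'
#' @param partition An [archetype_partition()].
#' @param features The [feature_series()] the partition indexes into.
#' @param cutoff Merge threshold (default 1).
#' @param standardize z-score features before computing distances
#'   (default TRUE).
#' @return A merged [archetype_partition()].
#' @export
merge_clusters_wasserstein <- function(partition, features, cutoff = 1,
                                       standardize = TRUE) {
  stopifnot(inherits(partition, "archetype_partition"),
            inherits(features, "feature_series"))
  ok <- !is.na(partition$cluster)
  fm <- features$data[partition$frames, , drop = FALSE]
  if (standardize) fm <- scale(fm)
  fm[!is.finite(fm)] <- 0
  members <- split(which(ok), partition$cluster[ok])
  while (length(members) > 1) {
    k <- length(members)
    d <- matrix(Inf, k, k)
    for (a in 1:(k - 1)) for (b in (a + 1):k)
      d[a, b] <- .cluster_feature_distance(fm, members[[a]], members[[b]])
    min_d <- min(d)
    if (min_d >= cutoff) break
    idx <- which(d == min_d, arr.ind = TRUE)[1, ]
    members[[idx[1]]] <- c(members[[idx[1]]], members[[idx[2]]])
    members[[idx[2]]] <- NULL
  }
  cl <- rep(NA_integer_, length(partition$frames))
  for (i in seq_along(members)) cl[members[[i]]] <- i
  archetype_partition(partition$frames, cl,
                      provenance = c(partition$provenance,
                                     list(merged_at = cutoff)))
}

#' Default rule set for cluster registration
#'
#' Threshold predicates on cluster-median features implementing the
#' qualitative definitions of the 12 behaviors (fast locomotion above
#' ~15 cm/s, turns with nonzero signed movement angle, sniffing postures
#' with a long body and elongated neck, rearing/head-up with high head
#' elevation, grooming with a moving head, large movement-angle
#' variability and a compact body on a still trunk, immobility with a
#' still head). Rules are evaluated in order; the first match wins.
#'
#' @param fast_speed,loco_speed Body-speed thresholds (cm/s) for fast
#'   locomotion and for locomotion vs. stillness.
#' @param turn_angle Absolute movement-angle threshold (rad) for turns.
#' @param long_body,short_body Body-length thresholds (cm).
#' @param high_neck,low_neck Neck-elongation thresholds (cm).
#' @param high_elevation Head-elevation threshold (cm).
#' @param still_head,moving_head Head-speed thresholds (cm/s) for
#'   immobility and for grooming.
#' @param angle_var Movement-angle SD threshold (rad) for grooming.
#' @return Ordered list of rules (name + predicate on the cluster summary).
#' @export
default_registration_rules <- function(fast_speed = 15, loco_speed = 2,
                                       turn_angle = 0.05, long_body = 7,
                                       short_body = 5, high_neck = 3.8,
                                       low_neck = 2.2, high_elevation = 2,
                                       still_head = 1, moving_head = 3) {
  rule <- function(name, pred) list(name = name, pred = pred)
  list(
    rule("locomotion fast", function(s) s["body_speed"] > fast_speed),
    rule("locomotion sniffing", function(s)
      s["body_speed"] > loco_speed && s["body_length"] > long_body &&
        s["neck_elongation"] > high_neck),
    rule("locomotion turn right", function(s)
      s["body_speed"] > loco_speed && s["movement_angle"] > turn_angle),
    rule("locomotion turn left", function(s)
      s["body_speed"] > loco_speed && s["movement_angle"] < -turn_angle),
    rule("locomotion straight", function(s) s["body_speed"] > loco_speed),
    rule("still sniffing", function(s)
      s["body_length"] > long_body && s["neck_elongation"] > high_neck),
    rule("rearing", function(s)
      s["head_elevation"] > high_elevation && s["body_length"] < short_body &&
        s["neck_elongation"] < low_neck),
    rule("head up", function(s)
      s["head_elevation"] > high_elevation &&
        s["neck_elongation"] < low_neck),
    rule("grooming", function(s)
      s["head_speed"] > moving_head && s["body_length"] < short_body),
    rule("grooming", function(s)
      s["angle_sd"] > 0.1 && s["head_speed"] > moving_head),
    rule("still turn right", function(s) s["movement_angle"] > turn_angle),
    rule("still turn left", function(s) s["movement_angle"] < -turn_angle),
    rule("immobility", function(s) s["head_speed"] < still_head),
    rule("immobility", function(s) s["head_speed"] < moving_head &&
           s["body_speed"] < loco_speed)
  )
}

#' Register archetype clusters to the 12-behavior catalog
#'
#' Maps every surviving cluster of a partition to one behavior, either by
#' an explicit map (emulating manual registration by visual inspection)
#' or by the rule engine of [default_registration_rules()] applied to the
#' cluster's feature medians (plus the movement-angle SD, used by the
#' grooming rule). An explicit map entry always overrides the rules.
#'
#' @param partition An [archetype_partition()] (after merging).
#' @param features The [feature_series()] the partition indexes into.
#' @param catalog A [behavior_catalog()].
#' @param map Optional named vector: names are cluster ids (as characters),
#'   values behavior names or ids.
#' @param rules Rule list (default [default_registration_rules()]).
#' @return Named integer vector: behavior id per cluster id.
#' @export
register_clusters <- function(partition, features,
                              catalog = behavior_catalog(), map = NULL,
                              rules = default_registration_rules()) {
  stopifnot(inherits(partition, "archetype_partition"))
  ok <- !is.na(partition$cluster)
  cl_ids <- sort(unique(partition$cluster[ok]))
  fm <- features$data[partition$frames, , drop = FALSE]
  out <- stats::setNames(rep(NA_integer_, length(cl_ids)),
                         as.character(cl_ids))
  for (cl in cl_ids) {
    key <- as.character(cl)
    if (!is.null(map) && key %in% names(map)) {
      v <- map[[key]]
      out[key] <- if (is.numeric(v)) as.integer(v)
                  else catalog$ids[match(v, catalog$names)]
      next
    }
    rows <- fm[partition$cluster == cl & ok, , drop = FALSE]
    s <- apply(rows, 2, stats::median, na.rm = TRUE)
    s <- c(s, angle_sd = stats::sd(rows[, "movement_angle"], na.rm = TRUE))
    hit <- NA_integer_
    for (r in rules) {
      if (isTRUE(unname(r$pred(s)))) {
        hit <- catalog$ids[match(r$name, catalog$names)]
        break
      }
    }
    if (is.na(hit))
      stop(sprintf(
        "unregistered cluster %s; feature medians: %s", key,
        paste(sprintf("%s=%.2f", names(s), s), collapse = ", ")))
    out[key] <- hit
  }
  out
}

#' Maximum-likelihood frame assignment
#'
#' Fits a full-covariance Gaussian in the six-feature space for each
#' registered behavior (pooling the frames of all clusters mapped to it)
#' and assigns every valid frame of the session, including frames outside
#' the clustering subsample, to the behavior with the highest likelihood.
#' Ties are broken toward the lower behavior id. Singular covariance fits
#' are ridge-regularized with a warning.
#'
#' @param features A [feature_series()] (full session).
#' @param partition Registered [archetype_partition()].
#' @param mapping Cluster-to-behavior map from [register_clusters()].
#' @param min_frames Minimum frames needed to fit a behavior model
#'   (default 10).
#' @param keep_likelihood Attach the frames x behaviors log-likelihood
#'   matrix as attribute `"loglik"` (default TRUE).
#' @return A [behavior_labels()]; frames with missing features stay
#'   unlabeled (resolve with [postprocess_labels()]).
#' @export
assign_frames_max_likelihood <- function(features, partition, mapping,
                                         min_frames = 10,
                                         keep_likelihood = TRUE) {
  stopifnot(inherits(features, "feature_series"))
  ok <- !is.na(partition$cluster)
  beh_ids <- sort(unique(mapping))
  models <- list()
  for (b in beh_ids) {
    cls <- as.integer(names(mapping)[mapping == b])
    rows <- partition$frames[ok & partition$cluster %in% cls]
    x <- features$data[rows, , drop = FALSE]
    x <- x[stats::complete.cases(x), , drop = FALSE]
    if (nrow(x) < min_frames)
      stop(sprintf("behavior %d has fewer than %d frames", b, min_frames))
    mu <- colMeans(x)
    sigma <- stats::cov(x)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) {
      warning("singular covariance; applying ridge regularization")
      sigma <- sigma + diag(1e-6 * max(diag(sigma), 1e-12), ncol(x))
      ch <- chol(sigma)
    }
    models[[as.character(b)]] <- list(mu = mu, chol = ch)
  }
  n <- nrow(features$data)
  ll <- matrix(-Inf, n, length(beh_ids),
               dimnames = list(NULL, as.character(beh_ids)))
  valid <- features$valid
  x_all <- features$data[valid, , drop = FALSE]
  for (k in seq_along(beh_ids)) {
    m <- models[[k]]
    z <- backsolve(m$chol, t(x_all) - m$mu, transpose = TRUE)
    ll[valid, k] <- -0.5 * colSums(z^2) - sum(log(diag(m$chol))) -
      0.5 * ncol(x_all) * log(2 * pi)
  }
  lab <- rep(NA_integer_, n)
  lab[valid] <- beh_ids[max.col(ll[valid, , drop = FALSE],
                                ties.method = "first")]
  out <- behavior_labels(lab, features$frame_rate)
  if (keep_likelihood) attr(out, "loglik") <- ll
  out
}

#' Post-process a label sequence into clean episodes
#'
#' Removes behavior episodes shorter than `min_frames` (their frames
#' become unlabeled), then resolves every unlabeled run by attributing its
#' first half to the preceding behavior and its second half to the
#' following behavior (odd lengths: the extra frame goes to the preceding
#' behavior; runs at the sequence edge take their single neighbor).
#' The output has no unlabeled frames and no episode shorter than
#' `min_frames`.
#'
#' @param labels A [behavior_labels()].
#' @param min_frames Minimum episode length in frames (default 4,
#'   i.e. 100 ms at 40 fps).
#' @return A cleaned [behavior_labels()].
#' @export
postprocess_labels <- function(labels, min_frames = 4) {
  stopifnot(inherits(labels, "behavior_labels"), min_frames >= 1)
  lab <- labels$labels
  ep <- labels$episodes
  short <- ep[ep$end - ep$start < min_frames, , drop = FALSE]
  for (e in seq_len(nrow(short)))
    lab[short$start[e]:(short$end[e] - 1L)] <- NA_integer_
  if (all(is.na(lab))) stop("no episode survives the minimum duration")

  n <- length(lab)
  miss <- is.na(lab)
  if (any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      prev <- if (s > 1L) lab[s - 1L] else NA_integer_
      nxt <- if (e < n) lab[e + 1L] else NA_integer_
      if (is.na(prev) && is.na(nxt)) next
      if (is.na(prev)) { lab[s:e] <- nxt; next }
      if (is.na(nxt)) { lab[s:e] <- prev; next }
      len <- e - s + 1L
      n_prev <- ceiling(len / 2)
      lab[s:(s + n_prev - 1L)] <- prev
      if (n_prev < len) lab[(s + n_prev):e] <- nxt
    }
  }
  behavior_labels(lab, labels$frame_rate)
}

#' Rand index between two partitions of the same frames
#'
#' Pair-counting agreement: the fraction of frame pairs on which the two
#' partitions agree (placed together in both, or separated in both).
#' Invariant to cluster relabeling.
#'
#' @param a,b [archetype_partition()] objects over the same frames, or
#'   plain label vectors of equal length.
#' @return Rand index in `[0, 1]`.
#' @export
partition_agreement <- function(a, b) {
  if (inherits(a, "archetype_partition")) {
    if (!identical(a$frames, b$frames))
      stop("partitions must cover the same frames")
    ok <- !is.na(a$cluster) & !is.na(b$cluster)
    x <- a$cluster[ok]; y <- b$cluster[ok]
  } else {
    stopifnot(length(a) == length(b))
    ok <- !is.na(a) & !is.na(b)
    x <- a[ok]; y <- b[ok]
  }
  n <- length(x)
  if (n < 2) stop("need at least two jointly assigned frames")
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  a_pairs <- comb2(as.vector(tab))
  row_pairs <- comb2(rowSums(tab))
  col_pairs <- comb2(colSums(tab))
  total <- n * (n - 1) / 2
  (total + 2 * a_pairs - row_pairs - col_pairs) / total
}

#' Full unsupervised behavior segmentation
#'
#' Convenience wrapper chaining [embed_features()],
#' [cluster_embeddings()], [consensus_clusters()],
#' [merge_clusters_wasserstein()], [register_clusters()],
#' [assign_frames_max_likelihood()] and [postprocess_labels()].
#'
#' @param features A [feature_series()] (typically smoothed).
#' @param seed RNG seed for all stochastic stages.
#' @param n_tsne,n_gmm Replicate counts (defaults 10 and 50).
#' @param subsample_fraction,max_points Subsampling of the clustering
#'   stage (see [embed_features()]).
#' @param g_range BIC range for the mixture component count.
#' @param cutoff Wasserstein merge cutoff (default 1).
#' @param min_cluster_frames Consensus size floor (default 20).
#' @param min_episode_frames Episode floor (default 4).
#' @param map Optional explicit cluster-to-behavior map.
#' @return List with `labels` (post-processed [behavior_labels()]),
#'   `partition`, `mapping`, and `embeddings`.
#' @export
segment_behaviors <- function(features, seed = NULL, n_tsne = 10,
                              n_gmm = 50, subsample_fraction = 0.25,
                              max_points = 1500, g_range = 8:30,
                              cutoff = 1, min_cluster_frames = 20,
                              min_episode_frames = 4, map = NULL) {
  emb <- embed_features(features, subsample_fraction = subsample_fraction,
                        n_replicates = n_tsne, seed = seed,
                        max_points = max_points)
  parts <- cluster_embeddings(emb, n_gmm_replicates = n_gmm,
                              g_range = g_range)
  cons <- consensus_clusters(parts, min_cluster_frames = min_cluster_frames)
  merged <- merge_clusters_wasserstein(cons, features, cutoff = cutoff)
  mapping <- register_clusters(merged, features, map = map)
  raw <- assign_frames_max_likelihood(features, merged, mapping)
  list(labels = postprocess_labels(raw, min_episode_frames),
       partition = merged, mapping = mapping, embeddings = emb)
}
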