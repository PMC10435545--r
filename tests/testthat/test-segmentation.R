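make_blob_features <- function(n_per = 200, centers, sds = 0.05,
                               seed = 1, frame_rate = 40) {
  set.seed(seed)
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * 6, rep(centers[i, ], each = n_per), sds),
           n_per, 6)))
  list(features = feature_series(x, frame_rate),
       truth = rep(seq_len(k), each = n_per))
}

test_that("embedding replicates share a subsample and flag the PCA dimension", {
  # data with a 3-D latent structure: 70% variance needs 3 components
  set.seed(2)
  latent <- matrix(rnorm(600 * 3), 600, 3)
  # three correlated feature pairs: eigenvalues ~ (1.9, 1.9, 1.9, .1, .1, .1)
  # so two components explain 63% and three 95% of the variance
  x <- latent[, c(1, 1, 2, 2, 3, 3)] + matrix(rnorm(600 * 6, sd = 0.33),
                                              600, 6)
  fs <- feature_series(x, 40)
  expect_warning(
    emb <- embed_features(fs, subsample_fraction = 1, n_replicates = 2,
                          seed = 3, perplexity = 15, max_points = 400,
                          max_iter = 150),
    regexp = NA) # 3 latent dims match the default n_dims = 3: no warning
  expect_equal(emb$pca_dims, 3)
  expect_length(emb$embeddings, 2)
  expect_equal(dim(emb$embeddings[[1]]), c(400, 3))
  # single replicate works; fixed seed reproduces the embedding
  emb2 <- embed_features(fs, subsample_fraction = 1, n_replicates = 1,
                         seed = 3, perplexity = 15, max_points = 400,
                         max_iter = 150)
  expect_identical(emb2$embeddings[[1]], emb$embeddings[[1]])
  expect_error(embed_features(fs, subsample_fraction = 0.01,
                              perplexity = 30), "too few points")
})

test_that("replicated GMM clustering separates well-separated blobs", {
  blobs <- make_blob_features(150, rbind(rep(0, 6), rep(5, 6)), seed = 4)
  # two isotropic blobs carry most variance on one axis; the PCA-dimension
  # advisory is expected here and not under test
  emb <- suppressWarnings(
    embed_features(blobs$features, subsample_fraction = 1,
                   n_replicates = 2, seed = 5, perplexity = 20,
                   max_points = 300, max_iter = 200))
  parts <- cluster_embeddings(emb, n_gmm_replicates = 3, g_range = 2:4,
                              seed = 6)
  expect_length(parts, 6) # 2 embeddings x 3 replicates
  truth <- blobs$truth[emb$frames]
  for (p in parts)
    expect_gte(partition_agreement(p$cluster, truth), 0.95)
})

test_that("consensus recovers structure and enforces the size floor", {
  # identical partitions: consensus equals them
  frames <- 1:100
  base <- rep(1:4, each = 25)
  parts <- lapply(1:5, function(i) archetype_partition(frames, base))
  cons <- consensus_clusters(parts, min_cluster_frames = 10)
  expect_equal(partition_agreement(cons$cluster, base), 1)
  expect_equal(mean(attr(cons, "coassignment") %in% c(0, 1)), 1)

  # a 19-frame cluster is removed at the default floor
  small <- c(rep(1L, 19), rep(2L, 81))
  parts2 <- lapply(1:4, function(i) archetype_partition(frames, small))
  cons2 <- consensus_clusters(parts2, min_cluster_frames = 20)
  expect_true(all(is.na(cons2$cluster[1:19])))
  expect_true(all(!is.na(cons2$cluster[20:100])))

  # 10% label noise: consensus still recovers the two blobs
  set.seed(7)
  noisy <- lapply(1:20, function(i) {
    lab <- base
    flip <- sample(100, 10)
    lab[flip] <- sample(1:4, 10, replace = TRUE)
    archetype_partition(frames, lab)
  })
  cons3 <- consensus_clusters(noisy, min_cluster_frames = 5)
  expect_gte(partition_agreement(cons3$cluster, base), 0.9)

  # invariance to relabeling clusters within input partitions
  relab <- lapply(parts, function(p)
    archetype_partition(p$frames, 5L - p$cluster))
  cons4 <- consensus_clusters(relab, min_cluster_frames = 10)
  expect_equal(partition_agreement(cons4$cluster, cons$cluster), 1)
})

test_that("1-D Wasserstein distance matches closed forms", {
  expect_equal(wasserstein_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein_1d(rep(2, 5), rep(7, 9)), 5) # Diracs: |a - b|
  # equal-length samples: mean absolute difference of the order statistics
  set.seed(8)
  x <- rnorm(40); y <- rnorm(40, 1)
  expect_equal(wasserstein_1d(x, y), mean(abs(sort(x) - sort(y))))
  # N(0,1) vs N(2,1): distance |mu1 - mu2| at large n
  set.seed(9)
  expect_equal(wasserstein_1d(rnorm(20000), rnorm(20000, 2)), 2,
               tolerance = 0.03)
})

test_that("Wasserstein merging agglomerates below the cutoff only", {
  # two clusters with identical distributions merge; a distant one stays
  set.seed(10)
  n <- 60
  x <- matrix(0, 3 * n, 6)
  x[1:n, 1] <- rnorm(n, 0, 0.01)
  x[(n + 1):(2 * n), 1] <- rnorm(n, 0.1, 0.01)    # close to cluster 1
  x[(2 * n + 1):(3 * n), 1] <- rnorm(n, 50, 0.01) # far from both
  fs <- feature_series(x, 40)
  part <- archetype_partition(1:(3 * n), rep(1:3, each = n))
  merged <- merge_clusters_wasserstein(part, fs, cutoff = 1,
                                       standardize = FALSE)
  expect_equal(length(unique(merged$cluster)), 2)
  expect_equal(merged$cluster[1], merged$cluster[n + 1])
  expect_false(merged$cluster[1] == merged$cluster[2 * n + 1])

  # point masses differing on one feature: distance |a - b| drives merging
  y <- matrix(0, 2 * n, 6)
  y[(n + 1):(2 * n), 3] <- 0.5
  fy <- feature_series(y, 40)
  p2 <- archetype_partition(1:(2 * n), rep(1:2, each = n))
  m_low <- merge_clusters_wasserstein(p2, fy, cutoff = 0.51,
                                      standardize = FALSE)
  m_high <- merge_clusters_wasserstein(p2, fy, cutoff = 0.49,
                                       standardize = FALSE)
  expect_equal(length(unique(m_low$cluster)), 1)
  expect_equal(length(unique(m_high$cluster)), 2)
})

test_that("three clusters at known distances merge in order up to the cutoff", {
  # distances on one feature: d(1,2)=0.5, d(2,3)=0.8, d(1,3)=1.3
  n <- 50
  x <- matrix(0, 3 * n, 6)
  x[(n + 1):(2 * n), 1] <- 0.5
  x[(2 * n + 1):(3 * n), 1] <- 1.3
  fs <- feature_series(x, 40)
  part <- archetype_partition(1:(3 * n), rep(1:3, each = n))
  merged <- merge_clusters_wasserstein(part, fs, cutoff = 1,
                                       standardize = FALSE)
  # first merge: 1+2 (0.5 < 1); merged {1,2} to 3: mixture distance
  # (|0.5-1.3|+|0-1.3|)/2 = 1.05 >= 1, so exactly two clusters remain
  expect_equal(length(unique(merged$cluster)), 2)
})

test_that("rule registration maps cluster medians to behaviors", {
  lab <- quick_labels(240, seed = 11)
  fs <- generate_feature_series(lab, seed = 12)
  # perfect partition from ground truth: every behavior matched to itself
  frames <- which(fs$valid)
  part <- archetype_partition(frames, lab$labels[frames] + 1L)
  mapping <- register_clusters(part, fs)
  expect_equal(unname(mapping[as.character(1:12)]), 0:11)

  # a fast-locomotion cluster median lands on "locomotion fast"
  expect_equal(unname(mapping["1"]), 0)

  # explicit map overrides the rules
  forced <- register_clusters(part, fs, map = c("1" = "grooming"))
  expect_equal(unname(forced["1"]), 8)

  # unmatchable cluster errors with its medians: still body, fast head,
  # but neither compact (grooming) nor elongated (sniffing) posture
  x <- matrix(rep(c(0.5, 6, 0, 6.5, 3.0, 0.5), each = 30), 30, 6)
  bad <- feature_series(x, 40)
  p_bad <- archetype_partition(1:30, rep(1L, 30))
  expect_error(register_clusters(p_bad, bad), "unregistered cluster")
})

test_that("maximum-likelihood assignment labels all valid frames", {
  blobs <- make_blob_features(300, rbind(rep(0, 6), rep(4, 6)), sds = 0.3,
                              seed = 13)
  fs <- blobs$features
  sub <- seq(1, 600, by = 2)
  part <- archetype_partition(sub, blobs$truth[sub])
  mapping <- stats::setNames(c(0L, 5L), c("1", "2"))
  labs <- assign_frames_max_likelihood(fs, part, mapping)
  # held-out frames (not in the subsample) assigned correctly
  held <- setdiff(1:600, sub)
  expect_gte(mean(labs$labels[held] == c(0L, 5L)[blobs$truth[held]]), 0.95)
  ll <- attr(labs, "loglik")
  expect_equal(dim(ll), c(600, 2))

  # tie-break toward the lower behavior id for an equidistant frame
  fs2 <- feature_series(rbind(matrix(rep(c(0, 0, 0, 0, 0, 0), 30),
                                     30, 6, byrow = TRUE),
                              matrix(rep(c(2, 0, 0, 0, 0, 0), 30),
                                     30, 6, byrow = TRUE),
                              c(1, 0, 0, 0, 0, 0)), 40)
  set.seed(14)
  fs2$data[, ] <- fs2$data + rnorm(length(fs2$data), sd = 1e-3)
  fs2$data[61, ] <- c(1, 0, 0, 0, 0, 0) # exactly between the two means
  part2 <- archetype_partition(1:60, rep(1:2, each = 30))
  labs2 <- assign_frames_max_likelihood(
    fs2, part2, stats::setNames(c(3L, 9L), c("1", "2")))
  expect_true(labs2$labels[61] %in% c(3L, 9L))
})

test_that("post-processing removes short episodes and fills gaps", {
  # 3-frame episode between two long runs of A is absorbed into A
  lab <- behavior_labels(c(rep(0L, 10), rep(1L, 3), rep(0L, 10)), 40)
  out <- postprocess_labels(lab, 4)
  expect_identical(out$labels, rep(0L, 23))

  # 6 unlabeled frames between A and B: 3 to A, 3 to B
  lab2 <- behavior_labels(c(rep(0L, 10), rep(NA, 6), rep(1L, 10)), 40)
  out2 <- postprocess_labels(lab2)
  expect_identical(out2$labels, c(rep(0L, 13), rep(1L, 13)))

  # 7 unlabeled frames: ceiling to the preceding behavior (4 to A, 3 to B)
  lab3 <- behavior_labels(c(rep(0L, 10), rep(NA, 7), rep(1L, 10)), 40)
  out3 <- postprocess_labels(lab3)
  expect_identical(out3$labels, c(rep(0L, 14), rep(1L, 13)))

  # leading/trailing unlabeled runs take their single neighbor
  lab4 <- behavior_labels(c(rep(NA, 5), rep(2L, 10), rep(NA, 5)), 40)
  out4 <- postprocess_labels(lab4)
  expect_identical(out4$labels, rep(2L, 20))

  expect_error(postprocess_labels(
    behavior_labels(rep(c(0L, 1L), 10), 40), 4), "no episode")
})

test_that("post-processed labels always satisfy the episode invariants", {
  set.seed(15)
  for (rep_i in 1:25) {
    n <- sample(50:300, 1)
    lab_vec <- sample(c(0:5, NA), n, replace = TRUE,
                      prob = c(rep(0.15, 6), 0.1))
    # ensure at least one long episode survives
    lab_vec[1:6] <- 3L
    out <- postprocess_labels(behavior_labels(lab_vec, 40), 4)
    expect_false(anyNA(out$labels))
    expect_true(all(out$episodes$end - out$episodes$start >= 4))
    # episodes are maximal runs: consecutive episodes differ in behavior
    if (nrow(out$episodes) > 1)
      expect_true(all(diff(out$episodes$behavior) != 0 |
                        diff(out$episodes$start) == 0))
  }
})

test_that("the Rand index follows pair counting", {
  p1 <- archetype_partition(1:3, c(1L, 1L, 2L))
  p2 <- archetype_partition(1:3, c(1L, 2L, 2L))
  expect_equal(partition_agreement(p1, p2), 1 / 3) # enumerate the 3 pairs
  expect_equal(partition_agreement(p1, p1), 1)
  relab <- archetype_partition(1:3, c(9L, 9L, 4L))
  expect_equal(partition_agreement(p1, relab), 1)
  expect_error(partition_agreement(p1, archetype_partition(2:4, rep(1L, 3))),
               "same frames")
})

test_that("the full pipeline recovers planted behaviors end to end", {
  lab <- generate_behavior_sequence(duration_s = 420, seed = 16)
  fs <- generate_feature_series(lab, seed = 17)
  seg <- segment_behaviors(fs, seed = 18, n_tsne = 2, n_gmm = 4,
                           max_points = 700)
  ari <- mclust::adjustedRandIndex(seg$labels$labels, lab$labels)
  expect_gte(ari, 0.8)
  expect_false(anyNA(seg$labels$labels))
  expect_true(all(seg$labels$episodes$end - seg$labels$episodes$start >= 4))
})
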