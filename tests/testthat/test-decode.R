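# small separable decoding problem: each behavior drives its own neurons
separable_session <- function(n_per_class = 120, n_classes = 4,
                              n_noise = 5, seed = 80) {
  set.seed(seed)
  n <- n_per_class * n_classes
  # aperiodic episode structure (geometric dwells, random order)
  lab_vec <- integer(0)
  while (length(lab_vec) < n)
    lab_vec <- c(lab_vec, rep(sample.int(n_classes, 1) - 1L,
                              rgeom(1, 1 / 20) + 4L))
  lab_vec <- lab_vec[seq_len(n)]
  ev <- matrix(rpois(n_classes * n, 0.05), n_classes, n)
  for (b in seq_len(n_classes) - 1L)
    ev[b + 1, lab_vec == b] <- ev[b + 1, lab_vec == b] + 5
  ev <- rbind(ev, matrix(rpois(n_noise * n, 0.2), n_noise, n))
  list(raster = event_raster(ev, 20, "dSPN"),
       labels = behavior_labels(lab_vec, 20))
}

test_that("boxcar preprocessing has the closed-form impulse response", {
  ev <- matrix(0, 2, 100)
  ev[1, 50] <- 1
  r <- event_raster(ev, 20, "dSPN")
  f <- preprocess_activity(r, 500) # 10 frames at 20 fps
  expect_equal(sum(f[, 1] > 0), 10) # plateau of 10 frames
  expect_equal(max(f[, 1]), 1 / 10)
  expect_true(all(f[, 2] == 0)) # all-zero raster stays zero
  expect_error(preprocess_activity(r, 10), "window")
})

test_that("a 12-behavior catalog yields 66 pairwise classifiers", {
  lab40 <- generate_behavior_sequence(duration_s = 300, seed = 81)
  tun <- tuning_spec(40, frac_active = 0.5, seed = 82)
  g <- generate_event_raster(lab40, tun, seed = 83)
  feats <- preprocess_activity(g$raster)
  mod <- train_decoder(feats, g$truth$true_labels, cost_grid = 1,
                       seed = 84)
  expect_equal(ncol(mod$pairs), 66)
  expect_equal(sum(!mod$degenerate), 66)
  # fixed seed: identical split
  mod2 <- train_decoder(feats, g$truth$true_labels, cost_grid = 1,
                        seed = 84)
  expect_identical(mod$test_idx, mod2$test_idx)
})

test_that("separable classes decode nearly perfectly", {
  s <- separable_session()
  feats <- preprocess_activity(s$raster)
  mod <- train_decoder(feats, s$labels, cost_grid = 1, seed = 85)
  rep <- evaluate_decoding(mod, feats, s$labels)
  expect_gte(rep$accuracy, 0.9)
  pp <- rep$per_pair[!is.na(rep$per_pair$accuracy), ]
  expect_gte(min(pp$accuracy), 0.9)
  # away from episode boundaries (where the 500 ms boxcar mixes classes)
  # the separable classes decode essentially perfectly
  lab_vec <- s$labels$labels
  interior <- rep$frames[vapply(rep$frames, function(i) {
    w <- max(1, i - 5):min(length(lab_vec), i + 5)
    length(unique(lab_vec[w])) == 1
  }, logical(1))]
  pred_int <- rep$predicted[match(interior, rep$frames)]
  expect_gte(mean(pred_int == lab_vec[interior]), 0.98)
  # reconstruction error is 0 iff accuracy is 1 (given positive distances)
  D <- matrix(1, 12, 12); diag(D) <- 0
  rep2 <- evaluate_decoding(mod, feats, s$labels, D)
  expect_equal(rep2$error == 0, rep2$accuracy == 1)
})

test_that("vote ties break toward the lower behavior id", {
  model <- structure(list(
    models = list(list(w = c(1, 0), rho = 0, pos = 4L, neg = 7L)),
    pairs = matrix(c(4L, 7L), 2, 1), costs = 1,
    center = c(0, 0), sds = c(1, 1), train_idx = 1L, test_idx = 1L,
    degenerate = FALSE, n_classes = 12L), class = "svm_decoder")
  # single classifier: every behavior except the winner has 0 votes, and
  # all zero-vote behaviors tie; the documented rule picks the winner of
  # the vote count, then the lowest id among ties
  pred <- predict_behavior(model, matrix(c(1, 0, -1, 0), 2, 2,
                                         byrow = TRUE))
  expect_equal(pred, c(4L, 7L))
  expect_error(predict_behavior(model, matrix(0, 1, 3)), "dimensionality")
})

test_that("the reconstruction error equals the hand-computed toy value", {
  D <- matrix(0, 12, 12)
  D[1, 2] <- D[2, 1] <- 1.5
  D[1, 3] <- D[3, 1] <- 4
  obs <- c(0L, 0L, 1L, 2L, 0L)
  pred <- c(0L, 1L, 1L, 0L, 2L)
  # frame errors: 0, 1.5, 0, 4, 4 -> mean 1.9
  err <- mean(D[cbind(obs + 1L, pred + 1L)])
  expect_equal(err, 1.9)
  # SMC closed form for a constant prediction
  pred_const <- rep(0L, 5)
  smc_b0 <- mean((pred_const == 0L) == (obs == 0L))
  expect_equal(smc_b0, 3 / 5)
})

test_that("subset decoding enforces the eligibility thresholds", {
  s <- separable_session()
  expect_true(subset_decode(s$raster, s$labels, 1:39,
                            min_neurons = 40)$discarded)
  r20 <- subset_decode(s$raster, s$labels, rep(TRUE, 9), min_neurons = 20)
  expect_true(r20$discarded) # 9 cells under the silent-analysis floor
  ok <- subset_decode(s$raster, s$labels, 1:9, min_neurons = 9,
                      cost_grid = 1, seed = 86)
  expect_false(isTRUE(ok$discarded))
  expect_gte(ok$accuracy, 0.9)
})

test_that("the time-lag null preserves label marginals and sits at chance", {
  s <- separable_session(n_per_class = 150)
  feats <- preprocess_activity(s$raster)
  n <- length(s$labels$labels)
  # lag construction preserves occupancy exactly
  flipped <- rev(s$labels$labels)
  lag <- 777
  shifted <- flipped[((seq_len(n) - 1L + lag) %% n) + 1L]
  expect_equal(as.integer(table(shifted)),
               as.integer(table(s$labels$labels)))

  nul <- time_lag_null(feats, s$labels, n_lags = 3, margin_s = 5,
                       cost = 1, seed = 87)
  mod <- train_decoder(feats, s$labels, cost_grid = 1, seed = 87)
  rep <- evaluate_decoding(mod, feats, s$labels)
  # tuned population beats its null by a wide margin
  expect_gt(rep$accuracy, nul$accuracy_mean + 3 * max(nul$accuracy_sd, 0.02))
  expect_lt(nul$accuracy_mean, 0.6)
})

test_that("longitudinal decoding on identical sessions matches within-session accuracy", {
  s <- separable_session(n_per_class = 100)
  reg <- cell_registry(data.frame(cell_a = 1:9, cell_b = 1:9))
  rep_long <- longitudinal_decode(s$raster, s$labels, s$raster, s$labels,
                                  reg, min_registered = 5, cost_grid = 1,
                                  seed = 88)
  expect_false(isTRUE(rep_long$discarded))
  expect_gte(rep_long$accuracy, 0.9) # evaluated on (the same) session B
  expect_true(longitudinal_decode(
    s$raster, s$labels, s$raster, s$labels,
    cell_registry(data.frame(cell_a = 1:4, cell_b = 1:4)),
    min_registered = 40)$discarded)
})

test_that("remapped sessions decode at chance across days", {
  tun <- tuning_spec(80, frac_active = 0.6, frac_silent = 0,
                     episode_gain_sd = 0, tuning_width = 0, seed = 89)
  sp <- generate_session_pair(tun, overlap_fraction = 1,
                              remap_fraction = 1, seed = 90,
                              duration_s = 420)
  la <- align_labels(sp$labels_a, 20); lb <- align_labels(sp$labels_b, 20)
  rep_long <- longitudinal_decode(sp$raster_a, la, sp$raster_b, lb,
                                  sp$registry, cost_grid = 1, seed = 91)
  # fully remapped tuning: accuracy near the occupancy base rate
  base <- max(table(lb$labels) / length(lb$labels))
  expect_lt(rep_long$accuracy, base + 0.15)
})

test_that("pair accuracy relates to behavioral distance with graded confusability", {
  lab40 <- generate_behavior_sequence(duration_s = 600, seed = 92)
  fs <- generate_feature_series(lab40, seed = 93)
  D <- behavioral_distance_matrix(fs, lab40)
  tun <- tuning_spec(120, frac_active = 0.4, frac_silent = 0,
                     episode_gain_sd = 0.2, tuning_width = 3, seed = 94)
  g <- generate_event_raster(lab40, tun, seed = 95)
  feats <- preprocess_activity(g$raster)
  mod <- train_decoder(feats, g$truth$true_labels, cost_grid = 1, seed = 96)
  rep <- evaluate_decoding(mod, feats, g$truth$true_labels, D)
  pv <- pair_accuracy_vs_distance(rep, D)
  expect_gt(pv$rho, 0) # dissimilar behaviors separate better
  expect_equal(nrow(pv$per_pair), 66)
})
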