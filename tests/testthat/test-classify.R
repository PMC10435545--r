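test_that("behavior information matches hand evaluations", {
  lab <- behavior_labels(rep(c(0L, 1L), each = 500), 20)
  # constant rate: 0 bits
  expect_equal(behavior_information(rep(2, 1000), lab)$bi, 0)
  # p = (1/2, 1/2), rates (2f, 0): 1 bit
  expect_equal(behavior_information(c(rep(1, 500), rep(0, 500)), lab)$bi, 1)
  # never-active cell: flagged undefined
  expect_true(is.na(behavior_information(rep(0, 1000), lab)$bi))
})

test_that("behavior information equals an independent oracle on random cases", {
  set.seed(50)
  for (i in 1:100) {
    n <- sample(200:400, 1)
    k <- sample(2:12, 1)
    lab_vec <- sample(0:(k - 1), n, replace = TRUE)
    ev <- rpois(n, runif(1, 0.05, 1.5)) * runif(n, 0.5, 2)
    lab <- behavior_labels(lab_vec, 20)
    expect_equal(behavior_information(ev, lab)$bi,
                 naive_behavior_information(ev, lab_vec, 20),
                 tolerance = 1e-10)
  }
})

test_that("binarized mutual information over mean rate approximates BI at low rates", {
  # the identity is exact only in the rare-event limit; check the limit
  set.seed(51)
  n <- 200000
  lab_vec <- sample(0:3, n, replace = TRUE)
  p_ev <- c(0.0004, 0.0002, 0.0001, 0.0003)[lab_vec + 1]
  ev <- as.numeric(runif(n) < p_ev)
  lab <- behavior_labels(lab_vec, 20)
  bi <- behavior_information(ev, lab)$bi
  pb <- table(lab_vec) / n
  mi <- 0
  fbar <- mean(ev)
  for (b in 0:3) {
    fb <- mean(ev[lab_vec == b])
    for (x in 0:1) {
      pj <- pb[b + 1] * (if (x == 1) fb else 1 - fb)
      px <- if (x == 1) fbar else 1 - fbar
      if (pj > 0) mi <- mi + pj * log2(pj / (pb[b + 1] * px))
    }
  }
  expect_equal(bi, as.numeric(mi / fbar), tolerance = 0.01)
})

test_that("the 4-sigma shuffle criterion detects planted tuning", {
  lab40 <- generate_behavior_sequence(duration_s = 900, seed = 52)
  tun <- tuning_spec(24, frac_active = 0.5, frac_silent = 0,
                     episode_gain_sd = 0.25, seed = 53)
  g <- generate_event_raster(lab40, tun, seed = 54)
  lab <- g$truth$true_labels
  res <- classify_cells_active(g$raster, lab, n_shuffles = 500, seed = 55)
  planted <- tun$class_of == "active"
  expect_gte(mean(res$is_active[planted]), 0.9)
  expect_lte(mean(res$is_active[!planted]), 0.1)
  # monotonicity: a stricter threshold never enlarges the active set
  strict <- res$sigma_level > 8
  expect_true(all(!strict | res$is_active))
  # an infinite threshold flags nothing
  res_inf <- classify_behavior_active(g$raster$events[1, ], lab,
                                      n_shuffles = 100,
                                      sigma_threshold = Inf, seed = 56)
  expect_false(res_inf$is_active)
})

test_that("per-behavior shuffle detection is specific to the tuned behavior", {
  lab40 <- generate_behavior_sequence(duration_s = 900, seed = 57)
  tun <- tuning_spec(6, frac_active = 1, frac_silent = 0,
                     tuning_width = 0, episode_gain_sd = 0, seed = 58)
  g <- generate_event_raster(lab40, tun, seed = 59)
  lab <- g$truth$true_labels
  cell <- 1
  pref <- tun$preferred[cell]
  r_pref <- classify_active_per_behavior(g$raster$events[cell, ], lab, pref,
                                         n_shuffles = 300, seed = 60)
  expect_true(r_pref$is_active)
  other <- setdiff(0:11, pref)[1]
  r_other <- classify_active_per_behavior(g$raster$events[cell, ], lab,
                                          other, n_shuffles = 300,
                                          seed = 61)
  expect_false(isTRUE(r_other$is_active))
  # occupancy below the floor is excluded, not flagged
  lab_short <- behavior_labels(c(rep(0L, 1000), rep(1L, 20)), 20)
  r_short <- classify_active_per_behavior(rpois(1020, 0.3), lab_short, 1,
                                          n_shuffles = 50, seed = 62)
  expect_true(is.na(r_short$is_active))
})

test_that("activation occurrence counts active episodes", {
  lab <- behavior_labels(rep(rep(c(0L, 1L), 25), each = 20), 20)
  ep0 <- lab$episodes[lab$episodes$behavior == 0, ]
  expect_equal(nrow(ep0), 25)
  ev <- rep(0, length(lab$labels))
  expect_equal(activation_occurrence(ev, lab, 0), 0)
  ev[lab$labels == 0] <- 1
  expect_equal(activation_occurrence(ev, lab, 0), 1)
  # exactly one of the episodes active
  ev2 <- rep(0, length(lab$labels))
  ev2[ep0$start[3]] <- 0.7
  expect_equal(activation_occurrence(ev2, lab, 0), 1 / 25)
  expect_error(activation_occurrence(ev, lab, 5), "no episodes")
})

test_that("silent/inactive thresholds are strict", {
  expect_true(classify_behavior_silent(0))
  expect_true(classify_behavior_silent(0.02))   # 1 of 50 episodes
  expect_false(classify_behavior_silent(0.025)) # boundary excluded
  expect_false(classify_behavior_silent(0.03))

  lab <- behavior_labels(rep(0L, 400), 20) # 20 s
  # 2 events in 20 s = 0.1 Hz exactly: not inactive (strict <)
  ev <- matrix(0, 3, 400)
  ev[1, 1:2] <- 1   # 0.1 Hz exactly
  ev[2, 1] <- 1     # 0.05 Hz
  inact <- classify_behavior_inactive(event_raster(ev, 20, "dSPN"), lab)
  expect_false(inact[1, 1])
  expect_true(inact[2, 1])
  expect_true(inact[3, 1])
  # monotonicity in the occurrence threshold
  occs <- runif(100)
  expect_true(all(classify_behavior_silent(occs, 0.01) <=
                    classify_behavior_silent(occs, 0.2)))
})

test_that("shuffle-based silent detection recovers planted silent cells", {
  lab40 <- generate_behavior_sequence(duration_s = 1200, seed = 63)
  tun <- tuning_spec(20, frac_active = 0, frac_silent = 0.5,
                     silent_radius = 0, seed = 64)
  g <- generate_event_raster(lab40, tun, seed = 65)
  lab <- g$truth$true_labels
  silent <- which(tun$class_of == "silent")
  flags <- vapply(silent, function(i)
    classify_silent_by_shuffle(g$raster$events[i, ], lab,
                               tun$preferred[i], n_shuffles = 300,
                               seed = 70 + i)$is_silent, logical(1))
  expect_gte(mean(flags), 0.95)
  # untuned cells rarely flagged
  untuned <- which(tun$class_of == "untuned")
  false_flags <- vapply(untuned, function(i)
    classify_silent_by_shuffle(g$raster$events[i, ], lab, 0,
                               n_shuffles = 300, seed = 90 + i)$is_silent,
    logical(1))
  expect_lte(mean(false_flags), 0.1)
  # an all-zero cell is silent for every behavior
  zero <- rep(0, length(lab$labels))
  expect_true(classify_silent_by_shuffle(zero, lab, 3, 50)$is_silent)
})

test_that("the analytic silent-flag probability matches simulation", {
  set.seed(66)
  durations <- rexp(60, 1 / 2.5)
  rate <- 0.02
  p_ana <- silent_flag_probability(durations, rate, 0.025)
  sims <- replicate(2000, {
    active <- runif(60) < (1 - exp(-rate * durations))
    mean(active) < 0.025
  })
  expect_equal(mean(sims), p_ana, tolerance = 0.15)
  # occurrence < 0.025 of 60 episodes means at most 1 active episode
  expect_equal(silent_flag_probability(durations, 0, 0.025), 1)
  expect_lt(silent_flag_probability(durations, 1, 0.025), 1e-6)
})

test_that("Jaccard stability counts shared attributes over the union", {
  reg <- cell_registry(data.frame(cell_a = 1:3, cell_b = 1:3))
  a <- matrix(c(TRUE, TRUE, FALSE), 3, 1)
  b <- matrix(c(TRUE, FALSE, TRUE), 3, 1)
  expect_equal(jaccard_stability(a, b, reg), 1 / 3) # {1,2} vs {1,3}
  expect_equal(jaccard_stability(a, a, reg), 1)
  expect_true(is.na(jaccard_stability(a & FALSE, b & FALSE, reg)))
  disj <- matrix(c(FALSE, FALSE, TRUE), 3, 1)
  expect_equal(jaccard_stability(a, disj, reg), 0)
})

test_that("registry controls shuffle pairs and find closest neighbors", {
  set.seed(67)
  reg <- cell_registry(data.frame(cell_a = 1:10, cell_b = 1:10),
                       matrix(runif(40), 20, 2), matrix(runif(40), 20, 2))
  sh <- registry_controls(reg, "shuffle_pairs", seed = 68)
  expect_equal(sort(sh$pairs$cell_b), 1:10)
  expect_true(all(sh$pairs$cell_b != reg$pairs$cell_b)) # no fixed point
  sh2 <- registry_controls(reg, "shuffle_pairs", seed = 68)
  expect_identical(sh$pairs, sh2$pairs)

  # two cells only: closest neighbor swaps them
  reg2 <- cell_registry(data.frame(cell_a = 1:2, cell_b = 1:2),
                        matrix(runif(4), 2, 2),
                        rbind(c(0, 0), c(1, 1)))
  cn <- registry_controls(reg2, "closest_neighbor")
  expect_equal(cn$pairs$cell_b, c(2, 1))
  expect_error(registry_controls(
    cell_registry(data.frame(cell_a = 1, cell_b = 1), NULL,
                  matrix(0, 1, 2)), "closest_neighbor"), "at least 2")
})

test_that("registry controls degrade cross-session similarity", {
  tun <- tuning_spec(150, frac_active = 0.4, frac_silent = 0,
                     episode_gain_sd = 0.2, seed = 69)
  sp <- generate_session_pair(tun, overlap_fraction = 0.6,
                              remap_fraction = 0, seed = 70,
                              duration_s = 420)
  la <- align_labels(sp$labels_a, 20); lb <- align_labels(sp$labels_b, 20)
  p <- sp$registry$pairs
  sims <- function(reg) {
    v <- vapply(0:11, function(b) {
      ma <- activation_map(sp$raster_a, la, b)
      mb <- activation_map(sp$raster_b, lb, b)
      if (!ma$valid || !mb$valid) return(NA_real_)
      activation_similarity(ma$x[reg$pairs$cell_a], mb$x[reg$pairs$cell_b],
                            require_valid = FALSE)
    }, numeric(1))
    mean(v, na.rm = TRUE)
  }
  true_sim <- sims(sp$registry)
  ctrl_sim <- sims(registry_controls(sp$registry, "shuffle_pairs",
                                     seed = 71))
  expect_gt(true_sim, ctrl_sim)
})
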