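#' Boxcar-convolved activity features for decoding
#'
#' Convolves each neuron's deconvolved event train with a centered square
#' window (default 500 ms, i.e. 10 frames at 20 frames/s), the standard
#' preprocessing before SVM decoding. Window edges use the mean of the
#' available frames, preserving length.
#'
#' @param raster An [event_raster()].
#' @param window_ms Window length in milliseconds (default 500; must be
#'   at least one frame).
#' @return Numeric matrix, frames x neurons.
#' @export
preprocess_activity <- function(raster, window_ms = 500) {
  stopifnot(inherits(raster, "event_raster"))
  k <- round(raster$rate * window_ms / 1000)
  if (k < 1) stop("window shorter than one frame")
  n <- ncol(raster$events)
  back <- floor(k / 2); fwd <- k - back - 1L
  i <- seq_len(n)
  lo <- pmax(i - back, 1L); hi <- pmin(i + fwd, n)
  len <- hi - lo + 1L
  apply(raster$events, 1, function(x) {
    cs <- cumsum(c(0, x))
    (cs[hi + 1L] - cs[lo]) / len
  })
}

# subsample at most `cap` elements per class, preserving order
.cap_per_class <- function(idx, lab, cap) {
  keep <- unlist(lapply(split(idx, lab), function(v)
    if (length(v) > cap) sort(sample(v, cap)) else v))
  sort(unname(keep))
}

# fit one binary linear SVM and extract a fast linear decision rule
.fit_pair_svm <- function(x, y01, cost) {
  y <- factor(y01)
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- crossprod(fit$SV, fit$coefs)[, 1]
  dec <- as.numeric(x %*% w) - fit$rho
  # calibrate the decision sign against the model's own fitted classes
  pos_lab <- names(which.max(table(as.character(fit$fitted)[dec > 0])))
  if (is.null(pos_lab) || length(pos_lab) == 0 || is.na(pos_lab))
    pos_lab <- levels(y)[1]
  neg_lab <- setdiff(levels(y), pos_lab)
  if (length(neg_lab) == 0) neg_lab <- pos_lab
  list(w = w, rho = fit$rho, pos = as.integer(pos_lab),
       neg = as.integer(neg_lab))
}

# k-fold CV accuracy of a linear SVM at one cost
.cv_accuracy <- function(x, y01, cost, n_folds) {
  n <- length(y01)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  acc <- 0
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(y01[tr])) < 2) next
    m <- .fit_pair_svm(x[tr, , drop = FALSE], y01[tr], cost)
    dec <- as.numeric(x[!tr, , drop = FALSE] %*% m$w) - m$rho
    pred <- ifelse(dec > 0, m$pos, m$neg)
    acc <- acc + sum(pred == y01[!tr])
  }
  acc / n
}

#' Train a one-vs-one multiclass SVM behavior decoder
#'
#' Fits one binary linear SVM per unordered behavior pair (66 classifiers
#' for the full 12-behavior catalog) on the convolved activity features.
#' The data are split into a training and a test set (default 80%/20%;
#' contiguous block by default, to limit temporal leakage through the
#' 500 ms convolution window); the SVM cost is selected by k-fold
#' cross-validation on the training set over `cost_grid`. Features are
#' z-scored per neuron on the training frames. Pairs with a behavior
#' absent from the training split are flagged degenerate and cast no
#' vote.
#'
#' @param features Frames x neurons activity matrix (see
#'   [preprocess_activity()]).
#' @param labels [behavior_labels()] at the same frame rate/length.
#' @param split_fraction Training fraction (default 0.8).
#' @param n_folds Cross-validation folds (default 5).
#' @param cost_grid Candidate SVM costs (default `10^(-2:2)`); a single
#'   value skips the cross-validation.
#' @param seed RNG seed (controls the split and all subsampling).
#' @param block_split Use a contiguous test block (default TRUE) rather
#'   than a random frame split.
#' @param max_class_frames Cap on training frames per class per binary
#'   classifier (default 400); the cross-validation uses at most
#'   `max_cv_frames` per class (default 150).
#' @param max_cv_frames Per-class cap during cross-validation.
#' @return Object of class `svm_decoder`.
#' @export
train_decoder <- function(features, labels, split_fraction = 0.8,
                          n_folds = 5, cost_grid = 10^(-2:2), seed = NULL,
                          block_split = TRUE, max_class_frames = 400,
                          max_cv_frames = 150) {
  stopifnot(is.matrix(features), inherits(labels, "behavior_labels"),
            nrow(features) == length(labels$labels),
            split_fraction > 0, split_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  lab <- labels$labels
  labeled <- which(!is.na(lab))
  if (length(unique(lab[labeled])) < 2) stop("need at least 2 behaviors")
  n_test <- max(1L, round((1 - split_fraction) * length(labeled)))
  if (block_split) {
    start <- sample.int(length(labeled) - n_test + 1L, 1)
    test_idx <- labeled[start:(start + n_test - 1L)]
  } else {
    test_idx <- sort(sample(labeled, n_test))
  }
  train_idx <- setdiff(labeled, test_idx)

  center <- colMeans(features[train_idx, , drop = FALSE])
  sds <- apply(features[train_idx, , drop = FALSE], 2, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  xt <- scale(features[train_idx, , drop = FALSE], center, sds)
  yt <- lab[train_idx]

  present <- sort(unique(yt))
  pairs <- utils::combn(0:11, 2)
  models <- vector("list", ncol(pairs))
  costs <- rep(NA_real_, ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    bi <- pairs[1, p]; bj <- pairs[2, p]
    if (!(bi %in% present) || !(bj %in% present)) next # degenerate
    rows <- which(yt %in% c(bi, bj))
    rows <- .cap_per_class(rows, yt[rows], max_class_frames)
    x <- xt[rows, , drop = FALSE]
    y01 <- yt[rows]
    cost <- cost_grid[1]
    if (length(cost_grid) > 1) {
      cv_rows <- .cap_per_class(seq_along(y01), y01, max_cv_frames)
      cv_acc <- vapply(cost_grid, function(cc)
        .cv_accuracy(x[cv_rows, , drop = FALSE], y01[cv_rows], cc,
                     n_folds), numeric(1))
      cost <- cost_grid[which.max(cv_acc)]
    }
    models[[p]] <- .fit_pair_svm(x, y01, cost)
    costs[p] <- cost
  }
  structure(list(models = models, pairs = pairs, costs = costs,
                 center = center, sds = sds,
                 train_idx = train_idx, test_idx = test_idx,
                 degenerate = vapply(models, is.null, logical(1)),
                 n_classes = 12L),
            class = "svm_decoder")
}

#' @export
print.svm_decoder <- function(x, ...) {
  cat(sprintf(
    "svm_decoder: %d/%d pairwise linear classifiers (%d train / %d test frames)\n",
    sum(!x$degenerate), ncol(x$pairs), length(x$train_idx),
    length(x$test_idx)))
  invisible(x)
}

#' Predict behavior by majority vote of the pairwise classifiers
#'
#' Each non-degenerate binary classifier votes for one behavior of its
#' pair; the behavior with the most votes wins (ties broken toward the
#' lower behavior id).
#'
#' @param model An `svm_decoder`.
#' @param features Frames x neurons matrix (same neurons as training).
#' @return Integer vector of predicted behavior ids.
#' @export
predict_behavior <- function(model, features) {
  stopifnot(inherits(model, "svm_decoder"))
  if (ncol(features) != length(model$center))
    stop("feature dimensionality does not match the decoder")
  x <- scale(features, model$center, model$sds)
  n <- nrow(x)
  votes <- matrix(0L, n, model$n_classes)
  for (p in seq_len(ncol(model$pairs))) {
    m <- model$models[[p]]
    if (is.null(m)) next
    dec <- as.numeric(x %*% m$w) - m$rho
    winner <- ifelse(dec > 0, m$pos, m$neg)
    votes[cbind(seq_len(n), winner + 1L)] <-
      votes[cbind(seq_len(n), winner + 1L)] + 1L
  }
  max.col(votes, ties.method = "first") - 1L
}

#' Evaluate a behavior decoder
#'
#' Computes, on the given frames (default: the decoder's held-out test
#' block): the decoding accuracy (fraction of frames with the correct
#' behavior), the behavior reconstruction error (mean behavioral distance
#' between predicted and observed behavior; 0 for correct frames), the
#' per-pair binary accuracies, and the per-behavior one-vs-rest simple
#' matching coefficients (TP + TN)/N.
#'
#' @param model An `svm_decoder`.
#' @param features Frames x neurons matrix (full session).
#' @param labels [behavior_labels()] for those frames.
#' @param distances 12 x 12 behavioral distance matrix (see
#'   [behavioral_distance_matrix()]); required for the reconstruction
#'   error (`NA` entries propagate).
#' @param frames Frame indices to evaluate (default `model$test_idx`).
#' @return Object of class `decoding_report`: `accuracy`, `error`,
#'   `per_pair` (data.frame), `smc` (length-12 vector), `predicted`,
#'   `observed`, `frames`.
#' @export
evaluate_decoding <- function(model, features, labels, distances = NULL,
                              frames = NULL) {
  stopifnot(inherits(model, "svm_decoder"))
  if (is.null(frames)) frames <- model$test_idx
  obs <- labels$labels[frames]
  ok <- !is.na(obs)
  frames <- frames[ok]; obs <- obs[ok]
  pred <- predict_behavior(model, features[frames, , drop = FALSE])
  accuracy <- mean(pred == obs)
  error <- if (!is.null(distances))
    mean(distances[cbind(obs + 1L, pred + 1L)]) else NA_real_

  x <- scale(features[frames, , drop = FALSE], model$center, model$sds)
  per_pair <- data.frame(behavior_i = model$pairs[1, ],
                         behavior_j = model$pairs[2, ],
                         accuracy = NA_real_, n = 0L)
  for (p in seq_len(ncol(model$pairs))) {
    m <- model$models[[p]]
    if (is.null(m)) next
    sel <- obs %in% model$pairs[, p]
    if (!any(sel)) next
    dec <- as.numeric(x[sel, , drop = FALSE] %*% m$w) - m$rho
    bpred <- ifelse(dec > 0, m$pos, m$neg)
    per_pair$accuracy[p] <- mean(bpred == obs[sel])
    per_pair$n[p] <- sum(sel)
  }
  smc <- vapply(0:11, function(b) mean((pred == b) == (obs == b)),
                numeric(1))
  structure(list(accuracy = accuracy, error = error, per_pair = per_pair,
                 smc = smc, predicted = pred, observed = obs,
                 frames = frames),
            class = "decoding_report")
}

#' @export
print.decoding_report <- function(x, ...) {
  cat(sprintf("decoding_report: accuracy %.3f, reconstruction error %.3f (%d frames)\n",
              x$accuracy, x$error, length(x$frames)))
  invisible(x)
}

#' Time-lagged chance level for behavior decoding
#'
#' Estimates the chance decoding performance: the behavior time series is
#' flipped (first element becomes the last) and cyclically shifted by a
#' random lag (at least `margin_s` away from zero), destroying the
#' behavior-activity relation while preserving both time series'
#' autocorrelations and label marginals. For each of `n_lags` lags a new
#' decoder is trained on the lagged labels (same split, fixed cost) and
#' evaluated against the *original* labels on the original test frames;
#' the report averages over lags.
#'
#' @param features Frames x neurons matrix.
#' @param labels Original [behavior_labels()].
#' @param distances Behavioral distance matrix for the error metric.
#' @param n_lags Number of random lags (default 10).
#' @param margin_s Minimum |lag| in seconds (default 30).
#' @param cost SVM cost used for the null decoders (default 1; pass the
#'   cost selected for the reference decoder).
#' @param split_fraction,block_split,seed As in [train_decoder()]; use
#'   the same seed as the reference decoder so the split matches.
#' @param max_class_frames Per-class training cap.
#' @return List with `accuracy_mean`, `accuracy_sd`, `error_mean`,
#'   `error_sd`, and `per_lag` (data.frame).
#' @export
time_lag_null <- function(features, labels, distances = NULL, n_lags = 10,
                          margin_s = 30, cost = 1, split_fraction = 0.8,
                          block_split = TRUE, seed = NULL,
                          max_class_frames = 400) {
  stopifnot(inherits(labels, "behavior_labels"))
  n <- length(labels$labels)
  margin <- round(margin_s * labels$frame_rate)
  if (n <= 2 * margin) stop("session shorter than twice the lag margin")
  if (!is.null(seed)) set.seed(seed)
  lags <- sample(margin:(n - margin), n_lags, replace = TRUE)
  flipped <- rev(labels$labels)
  res <- lapply(lags, function(lag) {
    shifted <- flipped[((seq_len(n) - 1L + lag) %% n) + 1L]
    lag_labels <- behavior_labels(shifted, labels$frame_rate)
    mod <- train_decoder(features, lag_labels,
                         split_fraction = split_fraction,
                         cost_grid = cost, seed = seed,
                         block_split = block_split,
                         max_class_frames = max_class_frames)
    rep <- evaluate_decoding(mod, features, labels, distances,
                             frames = mod$test_idx)
    data.frame(lag = lag, accuracy = rep$accuracy, error = rep$error)
  })
  per_lag <- do.call(rbind, res)
  list(accuracy_mean = mean(per_lag$accuracy),
       accuracy_sd = stats::sd(per_lag$accuracy),
       error_mean = mean(per_lag$error),
       error_sd = stats::sd(per_lag$error),
       per_lag = per_lag)
}

#' Decode behavior from a neuron subset
#'
#' Trains and evaluates a decoder restricted to a subset of neurons
#' (e.g. behavior-active or behavior-silent cells). Analyses with fewer
#' than `min_neurons` in the subset are discarded (returned as a marker,
#' not an error), following the session-eligibility rule of 40 neurons
#' for active-subset and 20 for silent-subset analyses.
#'
#' @param raster An [event_raster()].
#' @param labels [behavior_labels()] at the raster rate.
#' @param subset Logical or integer neuron selector.
#' @param min_neurons Eligibility threshold (discard when the subset has
#'   strictly fewer neurons).
#' @param distances Behavioral distance matrix.
#' @param window_ms Convolution window (default 500).
#' @param ... Passed to [train_decoder()].
#' @return A `decoding_report`, or `list(discarded = TRUE, n_neurons =)`
#'   when under threshold.
#' @export
subset_decode <- function(raster, labels, subset, min_neurons = 40,
                          distances = NULL, window_ms = 500, ...) {
  idx <- if (is.logical(subset)) which(subset) else as.integer(subset)
  if (length(idx) < min_neurons)
    return(list(discarded = TRUE, n_neurons = length(idx)))
  sub <- raster
  sub$events <- raster$events[idx, , drop = FALSE]
  feats <- preprocess_activity(sub, window_ms)
  mod <- train_decoder(feats, labels, ...)
  rep <- evaluate_decoding(mod, feats, labels, distances)
  rep$n_neurons <- length(idx)
  rep$model <- mod
  rep
}

#' Longitudinal decoding across registered sessions
#'
#' Trains the one-vs-one decoder on session A restricted to the cells
#' registered in both sessions, and evaluates it on session B's
#' corresponding cells (columns ordered by the registry). Each session is
#' z-scored by its own per-neuron statistics. Discarded when fewer than
#' `min_registered` pairs are available.
#'
#' @param raster_a,raster_b [event_raster()] objects.
#' @param labels_a,labels_b [behavior_labels()] at the raster rate.
#' @param registry A [cell_registry()].
#' @param min_registered Eligibility threshold (default 40).
#' @param distances Behavioral distance matrix for the error.
#' @param window_ms Convolution window (default 500).
#' @param ... Passed to [train_decoder()] (session A training).
#' @return A `decoding_report` on session B frames, or a discarded
#'   marker.
#' @export
longitudinal_decode <- function(raster_a, labels_a, raster_b, labels_b,
                                registry, min_registered = 40,
                                distances = NULL, window_ms = 500, ...) {
  stopifnot(inherits(registry, "cell_registry"))
  p <- registry$pairs
  if (nrow(p) < min_registered)
    return(list(discarded = TRUE, n_registered = nrow(p)))
  ra <- raster_a; ra$events <- raster_a$events[p$cell_a, , drop = FALSE]
  rb <- raster_b; rb$events <- raster_b$events[p$cell_b, , drop = FALSE]
  fa <- preprocess_activity(ra, window_ms)
  fb <- preprocess_activity(rb, window_ms)
  mod <- train_decoder(fa, labels_a, ...)
  # session B is standardized by its own statistics (session-level gain
  # changes should not masquerade as tuning changes)
  center_b <- colMeans(fb)
  sds_b <- apply(fb, 2, stats::sd)
  sds_b[sds_b == 0 | !is.finite(sds_b)] <- 1
  fb_std <- scale(fb, center_b, sds_b)
  mod_b <- mod
  mod_b$center <- rep(0, ncol(fb)); mod_b$sds <- rep(1, ncol(fb))
  rep <- evaluate_decoding(mod_b, fb_std, labels_b, distances,
                           frames = which(!is.na(labels_b$labels)))
  rep$n_registered <- nrow(p)
  rep$model <- mod
  rep
}

#' Per-pair decoding accuracy versus behavioral distance
#'
#' Relates each binary classifier's accuracy to the behavioral distance
#' of its pair; dissimilar behaviors are expected to separate better.
#'
#' @param report A `decoding_report`.
#' @param distances 12 x 12 behavioral distance matrix.
#' @return List with `per_pair` (data.frame adding `distance`) and `rho`
#'   (Spearman rank correlation; `NA` when degenerate, e.g. all
#'   accuracies equal).
#' @export
pair_accuracy_vs_distance <- function(report, distances) {
  stopifnot(inherits(report, "decoding_report"))
  pp <- report$per_pair
  pp$distance <- distances[cbind(pp$behavior_i + 1L, pp$behavior_j + 1L)]
  ok <- !is.na(pp$accuracy) & !is.na(pp$distance)
  rho <- if (sum(ok) >= 3 && stats::sd(pp$accuracy[ok]) > 0 &&
             stats::sd(pp$distance[ok]) > 0)
    stats::cor(pp$accuracy[ok], pp$distance[ok], method = "spearman")
  else NA_real_
  list(per_pair = pp, rho = rho)
}
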