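#' Confusion matrix over the 12-behavior catalog
#'
#' @param reference,predicted Integer behavior ids (0-11), equal length;
#'   pairs with a missing entry are dropped.
#' @param catalog A [behavior_catalog()].
#' @return 12 x 12 integer matrix (reference rows, predicted columns).
#' @export
confusion_matrix <- function(reference, predicted,
                             catalog = behavior_catalog()) {
  stopifnot(length(reference) == length(predicted))
  ok <- !is.na(reference) & !is.na(predicted)
  k <- length(catalog$ids)
  m <- matrix(0L, k, k, dimnames = list(catalog$names, catalog$names))
  t <- table(factor(reference[ok], levels = catalog$ids),
             factor(predicted[ok], levels = catalog$ids))
  m[] <- as.integer(t)
  m
}

#' Per-class accuracy, precision, recall and F1
#'
#' One-vs-rest metrics per behavior class: accuracy (TP + TN)/N,
#' precision TP/(TP + FP), recall TP/(TP + FN), and
#' F1 = 2 * precision * recall / (precision + recall).
#' Undefined ratios (0/0) are reported as `NA`, not as 0.
#'
#' @param cm Confusion matrix (reference rows x predicted columns).
#' @param class_id Optional single class id (0-based row/column index);
#'   default: all classes.
#' @return data.frame with columns `class`, `accuracy`, `precision`,
#'   `recall`, `f1` (one row per class), or a single-row data.frame when
#'   `class_id` is given.
#' @export
per_class_metrics <- function(cm, class_id = NULL) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  ids <- if (is.null(class_id)) seq_len(nrow(cm)) else class_id + 1L
  out <- lapply(ids, function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- n - tp - fp - fn
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall)
    else NA_real_
    data.frame(class = i - 1L, accuracy = (tp + tn) / n,
               precision = precision, recall = recall, f1 = f1)
  })
  do.call(rbind, out)
}

#' Macro-averaged classification metrics
#'
#' Unweighted arithmetic mean of the per-class metrics, skipping classes
#' whose metric is undefined.
#'
#' @param metrics Output of [per_class_metrics()].
#' @return Named numeric vector (`accuracy`, `precision`, `recall`, `f1`).
#' @export
macro_average <- function(metrics) {
  cols <- c("accuracy", "precision", "recall", "f1")
  if (all(is.na(metrics[cols]))) stop("no class with a defined metric")
  vapply(cols, function(c) mean(metrics[[c]], na.rm = TRUE), numeric(1))
}

#' Majority classification of annotated items
#'
#' For each item, the class receiving the most votes is retained if its
#' vote share is at least 50%; items below 50% or with a tie between two
#' modal classes are discarded (`NA`).
#'
#' @param annotations data.frame with columns `item` and `vote`
#'   (additional columns such as `annotator` and `pass` are ignored here;
#'   every row counts as one vote).
#' @return Named vector: majority class per item (`NA` = discarded), in
#'   order of first appearance.
#' @export
majority_classification <- function(annotations) {
  stopifnot(all(c("item", "vote") %in% names(annotations)))
  items <- unique(annotations$item)
  out <- stats::setNames(rep(NA, length(items)), as.character(items))
  mode(out) <- mode(annotations$vote)
  for (it in items) {
    votes <- annotations$vote[annotations$item == it]
    votes <- votes[!is.na(votes)]
    if (!length(votes)) next
    counts <- sort(table(votes), decreasing = TRUE)
    if (counts[1] / length(votes) < 0.5) next
    if (length(counts) > 1 && counts[2] == counts[1]) next # tie: discard
    out[as.character(it)] <- names(counts)[1]
  }
  if (is.numeric(annotations$vote)) {
    num <- as.numeric(out)
    names(num) <- names(out)
    out <- num
  }
  out
}

#' Simple matching agreement between two annotation passes
#'
#' Fraction of items on which the two label vectors agree (items missing
#' in either are dropped). Used for intra-annotator consistency and
#' annotator-vs-reference comparisons.
#'
#' @param a,b Label vectors of equal length.
#' @return Agreement fraction in `[0, 1]`.
#' @export
annotation_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no jointly scored items")
  mean(a[ok] == b[ok])
}

#' Permutation-based two-sided t-test
#'
#' Two-sample test on the pooled-variance t statistic, with the p-value
#' estimated as the proportion of random relabellings whose |t| is at
#' least the observed |t|. The observed statistic is counted in both the
#' numerator and the denominator, so the reported p-value is never
#' exactly 0.
#'
#' @param group_a,group_b Numeric samples (each of length >= 2).
#' @param n_perm Number of random permutations (default 10000).
#' @param seed RNG seed.
#' @return List with `p_value`, `t_observed`, `n_perm`.
#' @export
permutation_t_test <- function(group_a, group_b, n_perm = 10000,
                               seed = NULL) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2, n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  pooled <- c(group_a, group_b)
  n_a <- length(group_a)
  t_obs <- .pooled_t(group_a, group_b)
  t_perm <- cpp_perm_t_abs(pooled, n_a, as.integer(n_perm))
  exceed <- sum(t_perm >= abs(t_obs) - 1e-12)
  list(p_value = (1 + exceed) / (n_perm + 1), t_observed = t_obs,
       n_perm = n_perm)
}

.pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  se <- sqrt(ss / (na + nb - 2) * (1 / na + 1 / nb))
  d <- mean(a) - mean(b)
  if (se <= 0) return(if (abs(d) <= 0) 0 else Inf)
  d / se
}
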