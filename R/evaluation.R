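#' Classification accuracy
#'
#' Proportion of predictions matching the truth.
#'
#' @param predicted,truth Equal-length vectors of class labels.
#' @return A proportion in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) == 0L) {
    abort("`predicted` and `truth` must be equal-length, non-empty.")
  }
  mean(as.character(predicted) == as.character(truth))
}

#' Hard labels from a probability matrix
#'
#' Maximum-posterior rule; posterior ties break toward the lowest class
#' index (the first column).
#'
#' @param proba Instance x class probability matrix with class-level
#'   column names.
#' @return Character vector of class labels.
#' @export
predict_labels <- function(proba) {
  colnames(proba)[apply(proba, 1L, which.max)]
}

#' Two-class area under the ROC curve
#'
#' Mann-Whitney rank formulation: the probability that a random positive
#' instance receives a higher score than a random negative one, with ties
#' counting one half.
#'
#' @param scores Numeric scores for the positive class.
#' @param labels Logical (or coercible) vector, `TRUE` = positive. Both
#'   classes must be present.
#' @return AUC in `[0, 1]`.
#' @examples
#' binary_auc(c(0.9, 0.4, 0.6), c(TRUE, FALSE, TRUE))  # 1
#' @export
binary_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    abort("both classes must be present to compute an AUC.")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Multi-class AUC (Hand-Till M measure)
#'
#' Averages pairwise two-class AUCs over all unordered class pairs:
#' `M = 2/(J(J-1)) * sum_{i<j} [A(i|j) + A(j|i)] / 2`, where `A(i|j)` is
#' [binary_auc()] of the class-`i` probability column restricted to
#' instances of classes `i` and `j` with class `i` as positive. Reduces to
#' [binary_auc()] when `J = 2`.
#'
#' @param proba Instance x class probability matrix with class-level
#'   column names.
#' @param labels Class labels, each one of the column names; every class
#'   named by a column must occur.
#' @return AUC in `[0, 1]`.
#' @export
hand_till_auc <- function(proba, labels) {
  lev <- colnames(proba)
  labels <- as.character(labels)
  if (length(labels) != nrow(proba)) abort("label / probability size mismatch.")
  missing <- setdiff(lev, labels)
  if (length(missing)) {
    abort(paste0("class(es) absent from labels: ", paste(missing, collapse = ", ")))
  }
  J <- length(lev)
  if (J < 2L) abort("need at least 2 classes.")
  total <- 0
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      sel <- labels %in% c(lev[i], lev[j])
      a_ij <- binary_auc(proba[sel, i], labels[sel] == lev[i])
      a_ji <- binary_auc(proba[sel, j], labels[sel] == lev[j])
      total <- total + (a_ij + a_ji) / 2
    }
  }
  2 * total / (J * (J - 1))
}

#' Robustness of a classifier across train and test folds
#'
#' Test accuracy as a percentage of training accuracy — an overfitting
#' indicator. Can legitimately exceed 100.
#'
#' @param test_accuracy,train_accuracy Accuracies in `[0, 1]` (or
#'   percentages, as long as both use the same scale); training accuracy
#'   must be positive.
#' @return A percentage.
#' @examples
#' robustness(0.6, 0.8)  # 75
#' @export
robustness <- function(test_accuracy, train_accuracy) {
  if (any(train_accuracy <= 0)) abort("training accuracy must be positive.")
  100 * test_accuracy / train_accuracy
}

#' Chance-corrected similarity of two selected-variable sets
#'
#' Kuncheva-style consistency index extended to sets of unequal size:
#' `(r - k_i k_j / n) / (min(k_i, k_j) - max(0, k_i + k_j - n))` where `r`
#' is the overlap, `k_i`, `k_j` the set sizes and `n` the total number of
#' variables; `k_i k_j / n` is the hypergeometric expectation of `r` under
#' random selection. Bounded in `[-1, 1]`. The undefined cases — either set
#' empty, or both sets containing every variable — return 0 by convention.
#'
#' @param set_i,set_j Vectors of selected variable identifiers.
#' @param n_vars Total number of variables both selections drew from.
#' @return Similarity in `[-1, 1]`.
#' @examples
#' set_similarity(c("a", "b"), c("a", "b"), 10)  # 0.8
#' @export
set_similarity <- function(set_i, set_j, n_vars) {
  k_i <- length(unique(set_i))
  k_j <- length(unique(set_j))
  if (k_i > n_vars || k_j > n_vars) abort("set larger than `n_vars`.")
  if (k_i == 0L || k_j == 0L) return(0)
  if (k_i == n_vars && k_j == n_vars) return(0)
  r <- length(intersect(unique(set_i), unique(set_j)))
  num <- r - k_i * k_j / n_vars
  den <- min(k_i, k_j) - max(0, k_i + k_j - n_vars)
  # den = 0 iff one set contains every variable; the overlap is then forced
  # (num = 0 too) and carries no information: same 0 convention
  if (den == 0) return(0)
  num / den
}

#' Selection stability across cross-validation folds
#'
#' Within each replicate, averages [set_similarity()] over all
#' `F(F-1)/2` pairs of training folds' selected-variable sets (45 pairs for
#' 10 folds); the overall stability is the mean over replicates.
#'
#' @param fold_sets A list of replicates, each a list of `F >= 2`
#'   selected-variable sets (character vectors).
#' @param n_vars Total variable count.
#' @return A list with `overall` and per-replicate `by_replicate`.
#' @export
stability <- function(fold_sets, n_vars) {
  if (!length(fold_sets)) abort("no replicates.")
  per_rep <- vapply(fold_sets, function(sets) {
    f <- length(sets)
    if (f < 2L) abort("each replicate needs at least 2 folds.")
    pairs <- utils::combn(f, 2L)
    mean(apply(pairs, 2L, function(p) {
      set_similarity(sets[[p[1L]]], sets[[p[2L]]], n_vars)
    }))
  }, numeric(1))
  list(overall = mean(per_rep), by_replicate = per_rep)
}

#' Interval-complexity statistics of a set of discretizations
#'
#' The three per-dataset complexity summaries: the fraction of predictors
#' discretized to a single interval (and hence filtered out), the mean
#' interval count among predictors with more than one interval (`NA` if
#' none), and the mean interval count over all predictors.
#'
#' @param models List of `discretization` objects.
#' @return A tibble with columns `fraction_trivial`,
#'   `mean_intervals_selected`, `mean_intervals`.
#' @examples
#' # W values (1, 1, 2, 3) -> (0.5, 2.5, 1.75)
#' @export
interval_stats <- function(models) {
  if (!length(models)) abort("no models.")
  W <- vapply(models, function(m) m$n_intervals, integer(1))
  tibble::tibble(
    fraction_trivial = mean(W == 1L),
    mean_intervals_selected = if (any(W > 1L)) mean(W[W > 1L]) else NA_real_,
    mean_intervals = mean(W)
  )
}

#' Wilcoxon paired-samples signed-rank test
#'
#' Tests whether the population medians of two paired samples differ. Zero
#' differences are discarded; absolute differences are ranked with
#' mid-ranks for ties; the `Z` statistic uses the normal approximation with
#' tie-corrected variance, and the p-value is two-sided.
#'
#' @param a,b Equal-length paired numeric vectors; at least 5 non-zero
#'   differences are required for the approximation to be meaningful.
#' @return A tibble with `statistic` (signed-rank sum `W+` of `a - b`),
#'   `z`, `p_value`, and `n_nonzero`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) abort("all paired differences are zero.")
  r <- rank(abs(d), ties.method = "average")
  w_plus <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  tie_sizes <- table(r)
  sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
    sum(tie_sizes^3 - tie_sizes) / 48
  z <- (w_plus - mu) / sqrt(sigma2)
  tibble::tibble(
    statistic = w_plus,
    z = z,
    p_value = 2 * pnorm(-abs(z)),
    n_nonzero = m
  )
}
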