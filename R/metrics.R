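#' F1 score from confusion counts
#'
#' `F1 = TP / (TP + 0.5 * (FP + FN))`, the harmonic mean of precision and
#' recall. The positive class throughout the package is the e3e4 risk
#' group. The degenerate case with no positives anywhere (TP = FP = FN =
#' 0) is defined as 0 with a warning.
#'
#' @param tp,fp,fn,tn Non-negative confusion counts (`tn` unused by F1 but
#'   accepted for a uniform signature).
#' @return F1 in `[0, 1]`.
#' @export
#' @examples
#' f1_score(tp = 3, fp = 1, fn = 2) # 3 / 4.5
f1_score <- function(tp, fp, fn, tn = 0) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  denom <- tp + 0.5 * (fp + fn)
  if (denom == 0) {
    warning("no positive instances in truth or prediction; F1 defined as 0")
    return(0)
  }
  tp / denom
}

#' Classification accuracy from confusion counts
#'
#' The fraction of correctly classified participants of either genotype.
#'
#' @inheritParams f1_score
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_score <- function(tp, fp, fn, tn) {
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix")
  (tp + tn) / total
}

confusion_counts <- function(truth, pred, positive = "e34") {
  tibble::tibble(
    tp = sum(truth == positive & pred == positive),
    fp = sum(truth != positive & pred == positive),
    fn = sum(truth == positive & pred != positive),
    tn = sum(truth != positive & pred != positive)
  )
}

# weighted-average F1: per-class F1 weighted by class prevalence
f1_weighted <- function(tp, fp, fn, tn) {
  f1_pos <- if (tp + 0.5 * (fp + fn) == 0) 0 else tp / (tp + 0.5 * (fp + fn))
  f1_neg <- if (tn + 0.5 * (fn + fp) == 0) 0 else tn / (tn + 0.5 * (fn + fp))
  n_pos <- tp + fn
  n_neg <- tn + fp
  if (n_pos + n_neg == 0) stop("empty confusion matrix")
  (n_pos * f1_pos + n_neg * f1_neg) / (n_pos + n_neg)
}

#' Stratified k-fold assignment
#'
#' Partitions indices into `k` folds that preserve the class proportions:
#' within each class, fold counts differ by at most one, and the extra
#' members of each class are dealt to the folds with the smallest running
#' totals so overall fold sizes are as even as possible. With the study's
#' 32/21 split and `k = 5` this yields fold sizes 11, 11, 11, 10, 10 with
#' 6-7 non-carriers and 4-5 carriers each. Deterministic given `seed`.
#'
#' @param labels Vector of class labels, one per participant.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the within-class shuffles.
#' @return Integer vector of fold ids in `1..k`, aligned with `labels`.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < k)) {
    stop("each class needs at least k = ", k, " members for stratified folds")
  }
  # per-class fold quotas: base floor(n/k) everywhere, remainders dealt to
  # the folds with the smallest running totals (largest classes first)
  quota <- matrix(0L, nrow = length(classes), ncol = k,
                  dimnames = list(classes, NULL))
  fold_tot <- rep(0L, k)
  for (cl in classes[order(-counts[classes])]) {
    n <- counts[[cl]]
    base <- n %/% k
    quota[cl, ] <- base
    extra <- n - base * k
    if (extra > 0) {
      receive <- order(fold_tot, seq_len(k))[seq_len(extra)]
      quota[cl, receive] <- quota[cl, receive] + 1L
    }
    fold_tot <- fold_tot + quota[cl, ]
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in classes) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep(seq_len(k), times = quota[cl, ])
  }
  fold
}

#' Empirical chance level by label permutation
#'
#' Recomputes a cross-validation statistic on copies of the table with the
#' genotype labels randomly permuted, giving the empirical null
#' distribution of the statistic (the package's chance reference, used in
#' place of any nominal constant).
#'
#' @param table Feature table for one trial (see [cv_classify()]).
#' @param statistic Function `table, seed -> numeric scalar`; typically a
#'   wrapper around [cv_classify()] returning the mean F1.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Numeric vector of `n_perm` null statistic values.
#' @export
permutation_null <- function(table, statistic, n_perm = 50, seed = 1L) {
  vapply(seq_len(n_perm), function(b) {
    perm_seed <- seed * 1000L + b
    set.seed(perm_seed)
    tab <- table
    tab$group <- sample(tab$group)
    statistic(tab, perm_seed)
  }, numeric(1))
}
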