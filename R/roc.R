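# Nonparametric ROC machinery. Classification convention throughout:
# score >= threshold -> malignant (positive).

#' Empirical ROC curve with trapezoidal AUC
#'
#' Operating points are computed at every distinct observed score under
#' the classify-at->= convention, plus the (0, 0) endpoint; the AUC is the
#' trapezoidal integral, which equals the Mann-Whitney pair-counting
#' statistic with ties counted one half.
#'
#' @param scores Numeric classifier scores (higher = more malignant).
#' @param labels Benign/malignant labels.
#' @return An object of class `roc_curve`: `fpr`, `tpr`, `thresholds`
#'   (decreasing; `Inf` for the (0,0) point), `auc`.
#' @export
empirical_roc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  if (length(unique(y)) < 2L)
    stop("empirical_roc: both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc),
            class = "roc_curve")
}

# DeLong structural components: V10 (per positive), V01 (per negative).
delong_components <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  psi <- (outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")) * 1
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong confidence interval for an AUC
#'
#' Nonparametric AUC variance from the DeLong structural components with a
#' normal-approximation interval truncated to [0, 1]. Degenerate cases
#' (perfect separation) yield a zero-width interval at the boundary and
#' are flagged.
#'
#' @param scores,labels As in [empirical_roc].
#' @param level Confidence level (default 0.95).
#' @return An object of class `delong_result`: `auc`, `variance`,
#'   `ci_low`, `ci_high`, `level`, `truncated`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    stop("delong_ci: both classes must be present")
  cmp <- delong_components(scores, y)
  m <- sum(y == 1); n <- sum(y == 0)
  v <- var(cmp$v10) / m + var(cmp$v01) / n
  z <- qnorm(1 - (1 - level) / 2)
  lo <- cmp$auc - z * sqrt(v)
  hi <- cmp$auc + z * sqrt(v)
  truncated <- lo < 0 || hi > 1
  structure(list(auc = cmp$auc, variance = v,
                 ci_low = max(0, lo), ci_high = min(1, hi),
                 level = level, truncated = truncated),
            class = "delong_result")
}

#' DeLong paired test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors measured on the same subjects,
#' using the covariance of their DeLong structural components.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Benign/malignant labels shared by both.
#' @return An object of class `delong_result` with `auc_a`, `auc_b`,
#'   `auc_diff`, `z`, `p_value`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  m <- sum(y == 1); n <- sum(y == 0)
  va <- var(ca$v10) / m + var(ca$v01) / n
  vb <- var(cb$v10) / m + var(cb$v01) / n
  cab <- cov(ca$v10, cb$v10) / m + cov(ca$v01, cb$v01) / n
  vd <- va + vb - 2 * cab
  d <- ca$auc - cb$auc
  if (vd <= .Machine$double.eps) {
    if (abs(d) > 0)
      warning("delong_paired_test: zero variance with non-zero difference")
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(vd)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = ca$auc, auc_b = cb$auc, auc_diff = d,
                 variance = vd, z = z, p_value = p),
            class = "delong_result")
}

# TPR of a ROC curve evaluated at arbitrary FPR values (step function:
# the highest TPR attained at fpr <= f).
roc_tpr_at <- function(curve, f) {
  vapply(f, function(fi) max(curve$tpr[curve$fpr <= fi + 1e-12]),
         numeric(1))
}

#' Do two ROC curves cross?
#'
#' Evaluates both curves' TPR on the union grid of their FPR values and
#' reports whether the sign of the difference changes. Curves that touch
#' without the difference changing sign (including one curve uniformly
#' dominating) do not cross. Used to dispatch the paired comparison: the
#' DeLong AUC test when curves do not cross, the Venkatraman-Begg shape
#' test when they do.
#'
#' @param curve_a,curve_b `roc_curve` objects on the same label set.
#' @param tol Differences within `tol` are treated as ties.
#' @return Logical flag.
#' @export
curves_cross <- function(curve_a, curve_b, tol = 1e-9) {
  grid <- sort(unique(c(curve_a$fpr, curve_b$fpr)))
  d <- roc_tpr_at(curve_a, grid) - roc_tpr_at(curve_b, grid)
  s <- sign(d)
  s <- s[abs(d) > tol]
  any(s > 0) && any(s < 0)
}

# E statistic of the Venkatraman-Begg shape comparison from within-modality
# ranks (each a permutation of 1..n): total absolute difference in
# classification errors over all rank cutpoints.
vb_e_stat <- function(rank_a, rank_b, y) {
  n <- length(y)
  ex <- vb_errors(rank_a, y, n)
  ey <- vb_errors(rank_b, y, n)
  sum(abs(ex - ey))
}

vb_errors <- function(r, y, n) {
  d_sorted <- y[order(r)]
  n_neg <- sum(y == 0)
  # error at cutpoint k (classify rank > k as positive):
  # missed positives with rank <= k plus false-positive negatives rank > k
  cum_pos <- cumsum(d_sorted)[seq_len(n - 1L)]
  cum_neg <- cumsum(1 - d_sorted)[seq_len(n - 1L)]
  cum_pos + (n_neg - cum_neg)
}

#' Venkatraman-Begg permutation test for paired ROC curves
#'
#' Rank-based comparison of the entire shapes of two ROC curves measured
#' on the same subjects, applicable when the curves cross. The statistic E
#' sums, over all rank cutpoints, the absolute difference in classification
#' errors between the two modalities. The null distribution is generated by
#' exchanging the two modalities' values within subject with probability
#' one half; ties are broken by a uniform jitter smaller than the minimal
#' score gap, redrawn and re-ranked on every permutation. The p-value is
#' the tail fraction of permuted E greater than or equal to the observed E.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Benign/malignant labels shared by both.
#' @param n_permutations Number of permutations (study setting: 2000).
#' @param seed Integer seed, recorded in the result.
#' @return An object of class `venkatraman_result`: `e_stat`, `p_value`,
#'   `n_permutations`, `seed`, `permuted_e`.
#' @export
venkatraman_begg_test <- function(scores_a, scores_b, labels,
                                  n_permutations = 2000L, seed = 1L) {
  y <- as_binary_labels(labels)
  n <- length(y)
  if (length(scores_a) != n || length(scores_b) != n)
    stop("venkatraman_begg_test: unpaired score lengths")
  stopifnot(n_permutations >= 1L)
  gaps <- diff(sort(unique(c(scores_a, scores_b))))
  eps <- if (length(gaps)) min(gaps) / 4 else 0.25
  with_seed(seed, {
    jitter_rank <- function(v) rank(v + runif(n, -eps, eps))
    ra <- if (anyDuplicated(scores_a)) jitter_rank(scores_a) else
      rank(scores_a)
    rb <- if (anyDuplicated(scores_b)) jitter_rank(scores_b) else
      rank(scores_b)
    e_obs <- vb_e_stat(ra, rb, y)
    perm_e <- numeric(n_permutations)
    for (i in seq_len(n_permutations)) {
      swap <- rbinom(n, 1L, 0.5) == 1L
      pa <- ifelse(swap, scores_b, scores_a)
      pb <- ifelse(swap, scores_a, scores_b)
      perm_e[i] <- vb_e_stat(jitter_rank(pa), jitter_rank(pb), y)
    }
    structure(list(e_stat = e_obs,
                   p_value = mean(perm_e >= e_obs),
                   n_permutations = as.integer(n_permutations),
                   seed = as.integer(seed), permuted_e = perm_e),
              class = "venkatraman_result")
  })
}

threshold_metrics <- function(scores, y, threshold) {
  pred <- as.integer(scores >= threshold)
  list(sensitivity = mean(pred[y == 1] == 1),
       specificity = mean(pred[y == 0] == 0))
}

#' Youden-index decision threshold
#'
#' Among the observed scores (classify-at->= convention), returns the
#' threshold maximising J = sensitivity + specificity - 1. Ties are broken
#' toward the lower threshold (higher sensitivity), consistent with the
#' greater cost placed on false negatives.
#'
#' @param scores,labels As in [empirical_roc].
#' @return An object of class `threshold_result`: `threshold`, `rule`,
#'   `sensitivity`, `specificity`, `j`.
#' @export
youden_threshold <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    stop("youden_threshold: both classes must be present")
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(t) mean(scores[y == 1] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores[y == 0] < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]   # candidates ascending: lowest wins
  structure(list(threshold = cand[best], rule = "youden",
                 sensitivity = sens[best], specificity = spec[best],
                 j = j[best]),
            class = "threshold_result")
}

#' Sensitivity-constrained decision threshold
#'
#' Among thresholds achieving at least `min_sens` sensitivity on the
#' selection data, returns the one maximising specificity (ties toward the
#' lower threshold). The rule encodes the asymmetric-cost stance: missing
#' a malignant nodule is costlier than a false positive. If no threshold
#' meets the constraint the minimal observed score is returned with a
#' warning.
#'
#' @param scores,labels As in [empirical_roc].
#' @param min_sens Minimum sensitivity (study setting: 0.95).
#' @return An object of class `threshold_result`.
#' @export
constrained_threshold <- function(scores, labels, min_sens = 0.95) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    stop("constrained_threshold: both classes must be present")
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(t) mean(scores[y == 1] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores[y == 0] < t), numeric(1))
  ok <- sens >= min_sens
  if (!any(ok)) {
    warning("constrained_threshold: no threshold reaches the minimum ",
            "sensitivity; returning the minimal observed score")
    best <- 1L
  } else {
    best <- which(ok)[which(spec[ok] >= max(spec[ok]) - 1e-12)[1]]
  }
  structure(list(threshold = cand[best], rule = "min_sensitivity",
                 sensitivity = sens[best], specificity = spec[best],
                 min_sens = min_sens),
            class = "threshold_result")
}

#' Average the four fold decision thresholds
#'
#' @param thresholds Numeric vector of four thresholds, or a list of
#'   `threshold_result`s.
#' @return Their arithmetic mean.
#' @export
average_thresholds <- function(thresholds) {
  if (is.list(thresholds))
    thresholds <- vapply(thresholds, function(t) t$threshold, numeric(1))
  stopifnot(length(thresholds) == 4L)
  mean(thresholds)
}

#' Convert probabilities to classes at a decision threshold
#'
#' A probability equal to or higher than the threshold is classified as
#' malignant.
#'
#' @param prob Numeric probabilities.
#' @param threshold Decision threshold.
#' @return Factor with levels benign/malignant.
#' @export
classify_malignant <- function(prob, threshold) {
  factor(ifelse(prob >= threshold, "malignant", "benign"),
         levels = c("benign", "malignant"))
}

#' Confusion-matrix summary metrics
#'
#' @param predictions Predicted classes (factor or character).
#' @param labels Reference classes.
#' @return A list with `sensitivity`, `specificity`, `accuracy` and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(predictions, labels) {
  pred <- as_binary_labels(predictions)
  y <- as_binary_labels(labels)
  stopifnot(length(pred) == length(y))
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(y), tp = tp, fp = fp, tn = tn,
       fn = fn)
}
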