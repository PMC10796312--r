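test_that("the empirical AUC matches hand-countable cases", {
  expect_equal(empirical_roc(c(0.9, 0.8, 0.2, 0.1),
                             c(1, 1, 0, 0))$auc, 1.0)
  # pair counting: 3 of 4 positive-negative pairs correctly ordered
  expect_equal(empirical_roc(c(0.9, 0.4, 0.8, 0.1),
                             c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(empirical_roc(rep(0.3, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(empirical_roc(1:4, rep(1, 4)), "both classes")
})

test_that("trapezoidal AUC equals Mann-Whitney pair counting on 500 draws", {
  set.seed(500)
  for (i in 1:500) {
    n <- sample(6:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- if (i %% 2 == 0) sample(seq(0, 1, 0.1), n, replace = TRUE)
      else rnorm(n)                      # with and without ties
    r <- empirical_roc(scores, y)
    expect_equal(r$auc, mw_auc(scores, y), tolerance = 1e-12)
    # curve endpoints and monotonicity
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(tail(r$fpr, 1), tail(r$tpr, 1)), c(1, 1))
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  }
})

test_that("DeLong intervals are internally consistent and truncate", {
  set.seed(21)
  y <- rep(c(0, 1), each = 25)
  s <- rnorm(50) + y
  d <- delong_ci(s, y)
  expect_equal(d$auc, empirical_roc(s, y)$auc)
  expect_true(d$ci_low <= d$auc && d$auc <= d$ci_high)
  expect_gte(d$variance, 0)

  perfect <- delong_ci(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$ci_high, 1.0)
})

test_that("a large exchangeable sample covers AUC one half", {
  set.seed(78)
  y <- rep(c(0, 1), each = 250)
  s <- rnorm(500)                        # scores carry no signal
  d <- delong_ci(s, y)
  expect_lte(d$ci_low, 0.5)
  expect_gte(d$ci_high, 0.5)
})

test_that("DeLong interval width shrinks with sample size", {
  width_at <- function(n) {
    set.seed(1000 + n)
    y <- rep(c(0, 1), each = n / 2)
    s <- rnorm(n) + 0.8 * y
    d <- delong_ci(s, y)
    d$ci_high - d$ci_low
  }
  w <- vapply(c(50, 200, 800), width_at, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("DeLong CI and paired test agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(7)
  y <- rep(c(0, 1), each = 30)
  a <- rnorm(60) + y * 1.2
  b <- rnorm(60) + y * 0.8
  pr <- pROC::roc(y, a, quiet = TRUE, direction = "<")
  ci <- pROC::ci.auc(pr, method = "delong")
  ours <- delong_ci(a, y)
  expect_equal(ours$ci_low, as.numeric(ci[1]), tolerance = 1e-10)
  expect_equal(ours$ci_high, as.numeric(ci[3]), tolerance = 1e-10)
  rt <- pROC::roc.test(pr, pROC::roc(y, b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  dp <- delong_paired_test(a, b, y)
  expect_equal(dp$z, unname(rt$statistic), tolerance = 1e-10)
  expect_equal(dp$p_value, rt$p.value, tolerance = 1e-10)
})

test_that("the paired DeLong test is antisymmetric with degenerate guard", {
  set.seed(9)
  y <- rep(c(0, 1), each = 20)
  a <- rnorm(40) + y
  b <- rnorm(40) + 0.5 * y
  ab <- delong_paired_test(a, b, y)
  ba <- delong_paired_test(b, a, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  same <- delong_paired_test(a, a, y)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
})

test_that("the paired DeLong test detects an informative scorer", {
  set.seed(31)
  hits <- replicate(100, {
    y <- rep(c(0, 1), each = 100)
    informative <- rnorm(200) + 1.5 * y
    noise <- rnorm(200)
    delong_paired_test(informative, noise, y)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("curve crossing detection dispatches correctly", {
  y <- rep(c(0, 1), each = 4)
  good <- c(1, 2, 3, 4, 5, 6, 7, 8)
  r_good <- empirical_roc(good, y)
  expect_false(curves_cross(r_good, r_good))
  weak <- c(1, 2, 3, 5, 4, 6, 7, 8)          # uniformly dominated
  expect_false(curves_cross(r_good, empirical_roc(weak, y)))
  # hand-built 4-point curves: scorer a is better at FPR 0 (TPR 0.5 vs 0)
  # while scorer b is better at FPR 0.5 (TPR 1 vs 0.5), so they cross
  y2 <- c(1, 1, 0, 0)
  ra <- empirical_roc(c(0.9, 0.2, 0.5, 0.4), y2)
  rb <- empirical_roc(c(0.8, 0.6, 0.85, 0.1), y2)
  expect_true(curves_cross(ra, rb))
})

test_that("the Venkatraman-Begg statistic behaves as a shape distance", {
  set.seed(15)
  y <- rep(c(0, 1), each = 15)
  a <- rnorm(30) + y
  same <- venkatraman_begg_test(a, a, y, n_permutations = 100, seed = 1)
  expect_equal(same$e_stat, 0)
  expect_equal(same$p_value, 1)
  b <- rnorm(30) + 0.5 * y
  ab <- venkatraman_begg_test(a, b, y, n_permutations = 200, seed = 2)
  ba <- venkatraman_begg_test(b, a, y, n_permutations = 200, seed = 2)
  expect_equal(ab$e_stat, ba$e_stat)         # wholesale exchange symmetry
  # rank-based: invariant to strictly monotone transforms
  tr <- venkatraman_begg_test(exp(a), b^3 + 2 * b, y,
                              n_permutations = 200, seed = 2)
  expect_equal(tr$e_stat, ab$e_stat)
  # seed-stable
  expect_equal(venkatraman_begg_test(a, b, y, 200, seed = 2)$p_value,
               ab$p_value)
  expect_error(venkatraman_begg_test(a, b[-1], y), "unpaired")
})

test_that("the Venkatraman-Begg E statistic matches the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(7)
  y <- rep(c(0, 1), each = 30)
  a <- rnorm(60) + y * 1.2
  b <- rnorm(60) + y * 0.8
  vt <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                       pROC::roc(y, b, quiet = TRUE, direction = "<"),
                       method = "venkatraman", paired = TRUE, boot.n = 400)
  ours <- venkatraman_begg_test(a, b, y, n_permutations = 2000, seed = 5)
  expect_equal(ours$e_stat, unname(vt$statistic))
  expect_lt(abs(ours$p_value - vt$p.value), 0.1)  # permutation noise
})

test_that("threshold rules match hand-computed and exhaustive oracles", {
  yt <- youden_threshold(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(yt$threshold, 0.8)
  expect_equal(yt$j, 1)
  set.seed(40)
  for (i in 1:100) {
    y <- c(0, 1, rbinom(28, 1, 0.5))
    s <- round(runif(30), 2)
    got <- youden_threshold(s, y)
    want <- oracle_youden(s, y)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$j, want$j)
    gotc <- constrained_threshold(s, y, min_sens = 0.95)
    wantc <- oracle_constrained(s, y, 0.95)
    expect_equal(gotc$threshold, wantc$threshold)
    expect_equal(gotc$specificity, wantc$spec)
    expect_gte(gotc$sensitivity, 0.95)
  }
})

test_that("the constrained rule reduces to max specificity at zero floor", {
  set.seed(41)
  y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  s <- runif(30)
  free <- constrained_threshold(s, y, min_sens = 0)
  # with no sensitivity floor the most specific cutpoint wins
  cand <- sort(unique(s))
  specs <- vapply(cand, function(t) mean(s[y == 0] < t), numeric(1))
  expect_equal(free$specificity, max(specs))
  # perfect separation: both rules pick the same threshold
  sp <- c(0.8, 0.9, 0.1, 0.2); yp <- c(1, 1, 0, 0)
  expect_equal(constrained_threshold(sp, yp)$threshold,
               youden_threshold(sp, yp)$threshold)
})

test_that("threshold averaging and classification follow the >= rule", {
  expect_equal(average_thresholds(c(0.4, 0.5, 0.6, 0.5)), 0.5)
  pred <- classify_malignant(c(0.5, 0.4999), 0.5)
  expect_equal(as.character(pred), c("malignant", "benign"))
})

test_that("confusion metrics reproduce the reconstructed test-set counts", {
  labels <- rep(c("malignant", "benign"), c(10, 13))
  preds <- c(rep("malignant", 8), rep("benign", 2),    # TP = 8, FN = 2
             rep("malignant", 4), rep("benign", 9))    # FP = 4, TN = 9
  cm <- confusion_metrics(preds, labels)
  expect_equal(cm$tp, 8); expect_equal(cm$fn, 2)
  expect_equal(cm$tn, 9); expect_equal(cm$fp, 4)
  expect_equal(round(100 * cm$sensitivity, 1), 80.0)
  expect_equal(round(100 * cm$specificity, 1), 69.2)
  expect_equal(round(100 * cm$accuracy, 1), 73.9)
})
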