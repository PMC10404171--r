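test_that("separable classes give a perfect cut between the score groups", {
  curve <- roc_curve(c(0, 0, 100, 100),
                     c("non_sensitizer", "non_sensitizer",
                       "sensitizer", "sensitizer"))
  cut <- optimal_cutoff(curve)
  expect_gt(cut$threshold, 0)
  expect_lt(cut$threshold, 100)
  expect_equal(cut$achieved_sensitivity, 1)
  expect_equal(cut$achieved_specificity, 1)
  expect_equal(cut$youden_j, 1)
  expect_equal(cut$achieved_balanced_accuracy, 1)
  expect_equal(cut$tie_interval, c(0, 100))
})

test_that("constant scores admit only the trivial thresholds", {
  curve <- roc_curve(rep(5, 6), rep(hazard_levels, 3))
  expect_equal(max(curve$youden_j), 0)
  expect_equal(nrow(curve), 2)  # below-min and above-max only
})

test_that("degenerate single-class input is rejected", {
  expect_error(roc_curve(1:4, rep("sensitizer", 4)), "degenerate")
  expect_error(roc_curve(1:3, c("sensitizer", "bad", "non_sensitizer")),
               "labels")
  expect_error(roc_curve(1:3, rep("sensitizer", 2)), "equal length")
})

test_that("roc_curve matches brute-force enumeration on random small inputs", {
  set.seed(73)
  for (rep in 1:30) {
    n <- sample(4:30, 1)
    scores <- round(runif(n, 0, 100), sample(c(0, 1), 1))
    labels <- sample(hazard_levels, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    curve <- roc_curve(scores, labels)
    cut <- optimal_cutoff(curve)
    oracle <- brute_force_best(scores, labels)
    expect_equal(cut$youden_j, oracle$j, tolerance = 1e-12)
    # the chosen cut-off realises one of the oracle's tied optima
    tpr <- mean(scores[labels == "sensitizer"] >= cut$threshold)
    fpr <- mean(scores[labels == "non_sensitizer"] >= cut$threshold)
    expect_true(any(abs(oracle$tpr - tpr) < 1e-12 &
                      abs(oracle$fpr - fpr) < 1e-12))
  }
})

test_that("thresholds within one inter-score gap induce identical confusion matrices", {
  set.seed(99)
  scores <- round(runif(25, 0, 100), 1)
  labels <- sample(hazard_levels, 25, replace = TRUE, prob = c(.6, .4))
  s <- sort(unique(scores))
  gaps <- cbind(s[-length(s)], s[-1])
  counts_at <- function(t) {
    brute_counts(ifelse(scores >= t, "sensitizer", "non_sensitizer"), labels)
  }
  for (g in sample(nrow(gaps), 8)) {
    lo <- gaps[g, 1]; hi <- gaps[g, 2]
    probes <- lo + (hi - lo) * c(0.01, 0.4, 0.99)
    base <- counts_at(probes[1])
    for (p in probes[-1]) expect_equal(counts_at(p), base)
  }
})

test_that("shuffled labels give near-zero optimal J", {
  set.seed(11)
  scores <- runif(400, 0, 100)
  labels <- sample(rep(hazard_levels, each = 200))
  cut <- optimal_cutoff(roc_curve(scores, labels))
  expect_lt(cut$youden_j, 0.2)  # small positive selection bias only
})

test_that("fixture cysteine cut-off is classification-equivalent to the published 13.935%", {
  ch <- pr_chemicals()
  cut <- optimal_cutoff(roc_curve(ch$pr_cys, ch$hazard))
  pred_ref <- ifelse(ch$pr_cys >= 13.935, "sensitizer", "non_sensitizer")
  pred_roc <- ifelse(ch$pr_cys >= cut$threshold, "sensitizer", "non_sensitizer")
  expect_equal(pred_roc, pred_ref)
  # published threshold sits inside the tie interval
  expect_gt(13.935, cut$tie_interval[1])
  expect_lte(13.935, cut$tie_interval[2])
  # and the maximised balanced accuracy can be no worse than at 13.935
  cm_ref <- confusion(pred_ref, ch$hazard)
  expect_gte(cut$achieved_balanced_accuracy, cm_ref$balanced_accuracy - 1e-12)
})

test_that("optimal cut-off agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  ch <- pr_chemicals()
  mine <- optimal_cutoff(roc_curve(ch$pr_cys, ch$hazard))
  ref <- pROC::roc(response = ch$hazard, predictor = ch$pr_cys,
                   levels = c("non_sensitizer", "sensitizer"),
                   direction = "<", quiet = TRUE)
  best <- pROC::coords(ref, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"))
  expect_equal(mine$achieved_sensitivity, best$sensitivity, tolerance = 1e-12)
  expect_equal(mine$achieved_specificity, best$specificity, tolerance = 1e-12)
})
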