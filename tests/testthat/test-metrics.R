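test_that("confusion matrix tallies true/predicted pairs", {
  m <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  expect_equal(unname(m), matrix(c(1L, 0L, 1L, 2L), 2, 2))
  expect_equal(sum(m), 4)
  y <- sample(0:3, 25, TRUE)
  expect_equal(unname(diag(confusion_matrix(y, y, 4))),
               as.integer(table(factor(y, 0:3))))
  expect_error(confusion_matrix(c(0, 5), c(0, 1), 2), "outside")
})

test_that("accuracy reduces to the binary closed form", {
  y <- c(rep(1, 10), rep(0, 10))
  p <- c(rep(1, 8), rep(0, 2), rep(1, 1), rep(0, 9))  # TP 8 FN 2 FP 1 TN 9
  expect_equal(accuracy(confusion_matrix(y, p, 2)), 17 / 20)
  expect_equal(accuracy(confusion_matrix(y, y, 2)), 1)
  expect_error(accuracy(matrix(0, 2, 2)), "empty")
  set.seed(60)
  yr <- sample(0:1, 4000, TRUE)
  pr <- sample(0:1, 4000, TRUE)
  expect_equal(accuracy(confusion_matrix(yr, pr, 2)), 0.5, tolerance = 0.05)
})

test_that("ROC construction handles separation, ties, and known fixtures", {
  perf <- roc_points(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_true(any(perf$points$x == 0 & perf$points$y == 1))
  expect_equal(perf$area, 1)

  tied <- roc_points(rep(0.3, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(tied$points$x, c(0, 1))
  expect_equal(tied$points$y, c(0, 1))
  expect_equal(tied$area, 0.5)

  fix <- roc_points(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(fix$area, 0.75)
  expect_equal(fix$area, oracle_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))

  expect_error(roc_points(runif(5), rep(1, 5)), "single class")
})

test_that("AUC equals the concordant-pair probability and is monotone-invariant", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(8:30, 1)
    scores <- round(runif(n), 2)               # rounding forces ties
    labels <- sample(0:1, n, TRUE)
    if (length(unique(labels)) < 2) next
    a <- roc_points(scores, labels)$area
    expect_equal(a, oracle_auc(scores, labels), tolerance = 1e-12)
    # strictly monotone transform leaves the area unchanged
    expect_equal(roc_points(exp(3 * scores), labels)$area, a)
    # reversing the score order complements the area (distinct scores)
    sd <- runif(n)
    if (length(unique(labels)) == 2) {
      expect_equal(roc_points(-sd, labels)$area,
                   1 - roc_points(sd, labels)$area, tolerance = 1e-12)
    }
  }
})

test_that("AUC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  for (i in 1:10) {
    scores <- rnorm(40)
    labels <- sample(0:1, 40, TRUE)
    if (length(unique(labels)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_points(scores, labels)$area, ref, tolerance = 1e-10)
  }
})

test_that("PR curves match a brute-force per-threshold recount", {
  perf <- pr_points(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  # precision 1 at every operating point down to recall 1
  upto <- seq_len(match(1, perf$points$x))
  expect_true(all(perf$points$y[upto] == 1))
  expect_equal(perf$area, 1)
  single <- pr_points(c(0.9, 0.5, 0.1), c(1, 0, 0))
  expect_equal(single$points$x[1], 1)
  expect_equal(single$points$y[1], 1)

  set.seed(63)
  scores <- runif(30); labels <- sample(0:1, 30, TRUE)
  curve <- pr_points(scores, labels)
  for (r in seq_len(nrow(curve$points))) {
    thr <- sort(unique(scores), decreasing = TRUE)[r]
    tp <- sum(labels == 1 & scores >= thr)
    fp <- sum(labels == 0 & scores >= thr)
    expect_equal(curve$points$y[r], tp / (tp + fp))
    expect_equal(curve$points$x[r], tp / sum(labels))
  }
  expect_error(pr_points(runif(4), rep(0, 4)), "positives")
})

test_that("one-vs-rest curves reduce to binary AUC and respect permutation", {
  set.seed(64)
  n <- 60
  labels <- sample(0:2, n, TRUE)
  p <- matrix(runif(3 * n), n, 3); p <- p / rowSums(p)
  ovr <- one_vs_rest(p, labels)
  expect_equal(ovr$auc[2],
               roc_points(p[, 2], as.integer(labels == 1))$area)
  perm <- c(3, 1, 2)
  ovr2 <- one_vs_rest(p[, perm], (match(labels + 1, perm) - 1))
  expect_equal(ovr2$auc, ovr$auc[perm])
  # perfect probabilities give unit areas everywhere
  ph <- matrix(0, n, 3); ph[cbind(1:n, labels + 1)] <- 1
  ovr3 <- one_vs_rest(0.98 * ph + 0.01, labels)
  expect_equal(ovr3$auc, rep(1, 3))
  expect_equal(ovr3$ap, rep(1, 3))
  # absent class is flagged and excluded from the macro average
  l2 <- sample(0:1, n, TRUE)
  ovr4 <- one_vs_rest(p, l2)
  expect_true(is.na(ovr4$auc[3]))
  expect_equal(ovr4$undefined, 2)
  expect_equal(ovr4$macro_auc, mean(ovr4$auc[1:2]))
})
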