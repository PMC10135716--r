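test_that("confusion counts match a brute-force tally on random inputs", {
  expect_error(confusion_counts(integer(0), numeric(0)), "empty")
  set.seed(51)
  for (trial in 1:200) {
    n <- sample(1:20, 1)
    y <- sample(0:1, n, replace = TRUE)
    p <- round(runif(n), 2)
    th <- sample(c(0, 0.25, 0.5, 0.75, 1), 1)
    expect_equal(confusion_counts(y, p, th), oracle_confusion(y, p, th))
  }
  # threshold 0 predicts everything positive
  cc0 <- confusion_counts(c(1, 0, 0), c(0.1, 0.2, 0.9), 0)
  expect_equal(cc0[["TN"]], 0L)
  expect_equal(cc0[["FN"]], 0L)
  # perfect separation
  ccp <- confusion_counts(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2), 0.5)
  expect_equal(ccp[["FP"]] + ccp[["FN"]], 0L)
})

test_that("classification metrics agree with brute-force formulas", {
  set.seed(52)
  for (trial in 1:300) {
    n <- sample(2:20, 1)
    y <- sample(0:1, n, replace = TRUE)
    p <- round(runif(n), 2)
    cc <- confusion_counts(y, p, 0.5)
    m <- classification_metrics(cc)
    o <- oracle_metrics(cc)
    expect_equal(m$precision, o$precision)
    expect_equal(m$recall, o$recall)
    expect_equal(m$f1, o$f1)
    expect_equal(m$mcc, o$mcc)
  }
  # balanced no-association case has MCC 0
  m0 <- classification_metrics(c(TP = 5, FP = 5, TN = 5, FN = 5))
  expect_equal(m0$mcc, 0)
  expect_equal(m0$kappa, 0)
  # perfect classifier
  m1 <- classification_metrics(c(TP = 4, FP = 0, TN = 16, FN = 0))
  expect_equal(m1$precision, 1)
  expect_equal(m1$recall, 1)
  expect_equal(m1$f1, 1)
  expect_equal(m1$mcc, 1)
  expect_equal(m1$kappa, 1)
  # degenerate denominators flag instead of erroring
  md <- classification_metrics(c(TP = 0, FP = 0, TN = 10, FN = 2))
  expect_true(md$degenerate)
  expect_equal(md$precision, 0)
})

test_that("MCC sign flips when only the labels are inverted", {
  set.seed(53)
  for (trial in 1:50) {
    n <- 20
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    p <- runif(n)
    m <- classification_metrics(confusion_counts(y, p, 0.5))$mcc
    m_flip <- classification_metrics(confusion_counts(1 - y, p, 0.5))$mcc
    expect_equal(m_flip, -m)
    # flipping labels and predictions together preserves MCC
    m_both <- classification_metrics(confusion_counts(1 - y, 1 - p, 0.5))$mcc
    expect_equal(m_both, m, tolerance = 1e-12)
  }
})

test_that("PR curve area equals average precision and its known properties", {
  # perfect ranking
  expect_equal(pr_curve(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_error(pr_curve(c(1, 1), c(0.5, 0.6)), "both classes")

  # worked 4-sample example against the hand oracle
  y4 <- c(1, 0, 1, 0)
  p4 <- c(0.9, 0.8, 0.7, 0.1)
  expect_equal(pr_curve(y4, p4)$auc, oracle_average_precision(y4, p4))

  set.seed(54)
  for (trial in 1:100) {
    n <- sample(4:25, 1)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 1)  # ties included
    expect_equal(pr_curve(y, p)$auc, oracle_average_precision(y, p))
  }

  # random scores at large n: area approaches the positive prevalence
  set.seed(55)
  n <- 20000
  y <- rep(0:1, each = n / 2)
  p <- runif(n)
  expect_equal(pr_curve(y, p)$auc, 0.5, tolerance = 0.02)

  # average precision is invariant to strictly monotone score transforms
  set.seed(56)
  y <- sample(0:1, 50, replace = TRUE)
  p <- runif(50)
  expect_equal(pr_curve(y, p)$auc, pr_curve(y, plogis(5 * p - 2))$auc)
})

test_that("the F1-MCC sweep covers the grid and matches pointwise metrics", {
  set.seed(57)
  y <- sample(0:1, 30, replace = TRUE)
  p <- runif(30)
  sw <- f1_mcc_curve(y, p, n_thresholds = 101)
  expect_equal(nrow(sw), 101L)
  expect_equal(sw$threshold[1], 0)
  expect_equal(sw$threshold[101], 1)
  at_half <- sw[abs(sw$threshold - 0.5) < 1e-9, ]
  ref <- classification_metrics(confusion_counts(y, p, 0.5))
  expect_equal(at_half$f1, ref$f1)
  expect_equal(at_half$mcc, ref$mcc)
  expect_equal(attr(sw, "best_point"), c(f1 = 1, mcc = 1))
  expect_equal(attr(sw, "worst_point"), c(f1 = 0, mcc = -1))

  # perfect classifier touches (1, 1)
  swp <- f1_mcc_curve(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_true(any(swp$f1 == 1 & swp$mcc == 1))
})

test_that("F1 from printed precision/recall and R-squared behave as defined", {
  expect_equal(f_score(0.91, 0.87), 2 * 0.91 * 0.87 / (0.91 + 0.87))
  expect_equal(r_squared(c(0, 0.5, 1), c(0, 0.5, 1)), 1)
  expect_equal(r_squared(c(0, 0.5, 1), rep(0.5, 3)), 0)
  expect_equal(r_squared(c(0, 0.5, 1), c(0.1, 0.5, 0.9)), 0.96)
  expect_error(r_squared(c(1, 1), c(1, 2)), "variance")
  expect_error(r_squared(1, 1), "2 samples")
})
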