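test_that("confusion metrics follow their defining ratios", {
  m <- confusion_metrics(9, 9, 1, 1)
  expect_equal(c(m$ca, m$se, m$sp), c(0.9, 0.9, 0.9))
  m2 <- confusion_metrics(10, 10, 0, 0)
  expect_equal(c(m2$ca, m2$se, m2$sp), c(1, 1, 1))
  set.seed(15)
  for (i in 1:200) {
    k <- sample(0:20, 4, replace = TRUE)
    if (sum(k) == 0) next
    m <- suppressWarnings(confusion_metrics(k[1], k[2], k[3], k[4]))
    expect_identical(m$ca, (k[1] + k[2]) / sum(k))
    if (k[1] + k[4] > 0) expect_identical(m$se, k[1] / (k[1] + k[4]))
    if (k[2] + k[3] > 0) expect_identical(m$sp, k[2] / (k[2] + k[3]))
  }
  expect_warning(confusion_metrics(0, 5, 2, 0), "undefined")
  expect_error(confusion_metrics(-1, 1, 1, 1), "non-negative")
})

test_that("ROC/AUC equals the normalized Mann-Whitney statistic", {
  expect_equal(roc_auc(c(3, 4, 5, 0, 1, 2),
                       rep(c("high", "low"), each = 3))$auc, 1)
  expect_equal(roc_auc(rep(1, 8), rep(c("high", "low"), 4))$auc, 0.5)
  set.seed(16)
  for (i in 1:500) {
    n1 <- sample(2:10, 1); n0 <- sample(2:10, 1)
    s <- c(sample(1:6, n1, replace = TRUE) + rnorm(n1, 0, 0.01) * rbinom(n1, 1, 0.5),
           sample(1:6, n0, replace = TRUE))
    lab <- c(rep("high", n1), rep("low", n0))
    expect_equal(roc_auc(s, lab)$auc, mw_auc_oracle(s, lab), tolerance = 1e-9)
  }
  expect_error(roc_auc(1:3, rep("high", 3)), "both classes")
})

test_that("perfectly separated features classify perfectly in every scheme", {
  set.seed(17)
  f <- c(rnorm(10, 5, 0.1), rnorm(10, 1, 0.1))
  lab <- rep(c("high", "low"), each = 10)
  r <- loocv_classify(f, lab, scheme = "intra_s1")
  expect_equal(c(r$ca, r$se, r$sp, r$auc), c(1, 1, 1, 1))
  f2 <- c(rnorm(10, 5, 0.1), rnorm(10, 1, 0.1))
  x <- cross_session_classify(f, lab, f2, lab)
  expect_equal(c(x$ca, x$se, x$sp, x$auc), c(1, 1, 1, 1))
})

test_that("LOOCV folds are leave-one-out and deterministic", {
  set.seed(18)
  f <- rnorm(14); lab <- rep(c("high", "low"), 7)
  r1 <- loocv_classify(f, lab)
  r2 <- loocv_classify(f, lab)
  expect_identical(r1$predictions, r2$predictions)
  expect_equal(nrow(r1$predictions), 14)
  expect_equal(sum(r1$counts), 14)
  expect_equal(r1$auc, mw_auc_oracle(r1$predictions$score,
                                     r1$predictions$label), tolerance = 1e-9)
  expect_error(loocv_classify(f[1:3], c("high", "low", "low")),
               "2 subjects per class")
})

test_that("permutation-null LOOCV accuracy shows no optimistic bias", {
  # under label permutation the feature is uninformative; leave-one-out with
  # near-balanced classes is pessimistically biased (the held-out subject's
  # class becomes the training minority), so chance behavior is an upper
  # envelope, not a two-sided target
  set.seed(19)
  x <- rnorm(20)
  lab <- c(rep("high", 11), rep("low", 9))
  cas <- replicate(200, loocv_classify(x, sample(lab))$ca)
  expect_lt(mean(cas), 0.5 + 2 * sd(cas) / sqrt(length(cas)))
})

test_that("fold-local standardization is load-bearing (leakage mutation test)", {
  set.seed(20)
  f <- rnorm(16, 10, 4); lab <- rep(c("high", "low"), 8)
  real <- loocv_classify(f, lab)
  # mutated pipeline: standardize once with the full-sample statistics
  fz <- (f - mean(f)) / sd(f)
  mutated_scores <- vapply(seq_along(fz), function(i) {
    tr <- data.frame(x = fz[-i], y = factor(lab[-i], levels = c("low", "high")))
    fit <- e1071::svm(y ~ x, data = tr, kernel = "linear", cost = 1, scale = FALSE)
    pr <- predict(fit, data.frame(x = fz[i]), decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    if (startsWith(colnames(dv)[1], "high")) dv[1] else -dv[1]
  }, numeric(1))
  expect_false(isTRUE(all.equal(real$predictions$score, mutated_scores)))
})

test_that("cross-session classification flags one-class test sets", {
  set.seed(21)
  f <- c(rnorm(5, 5), rnorm(5, 0)); lab <- rep(c("high", "low"), each = 5)
  w <- capture_warnings(
    r <- cross_session_classify(f, lab, rnorm(4, 5), rep("high", 4)))
  expect_true(any(grepl("undefined", w)))
  expect_true(is.nan(r$sp) || is.nan(r$auc))
  expect_true(is.finite(r$ca))
  expect_error(cross_session_classify(f, rep("high", 10), f, lab),
               "both classes")
})

test_that("SVR recovers a noiseless monotone relationship", {
  set.seed(22)
  x <- seq(-2, 2, length.out = 20)
  y <- 10 + 5 * x
  # a tight epsilon tube, since the default 0.1 (in standardized units)
  # deliberately leaves ~10% of the target spread unpenalized
  r <- loocv_svr(x, y, cost = 10, epsilon = 0.01)
  expect_lt(r$rmsep, 0.05 * sd(y))
  expect_gt(r$r, 0.99)
  # the reported RMSEP is exactly the pooled prediction error
  expect_equal(r$rmsep,
               sqrt(mean((r$predictions$predicted - r$predictions$actual)^2)))
  expect_error(loocv_svr(x, rep(1, 20)), "degenerate target")
  expect_error(loocv_svr(x[1:2], y[1:2]), "at least 3")
})
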