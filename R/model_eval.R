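#' Confusion-matrix metrics
#'
#' Classification accuracy, sensitivity and specificity from confusion
#' counts, with the high-performance group as the positive class:
#' `CA = (TP + TN) / total`, `SE = TP / (TP + FN)`, `SP = TN / (TN + FP)`.
#' A zero denominator yields `NaN` with a warning rather than an error.
#'
#' @param tp,tn,fp,fn non-negative confusion counts; their total must be
#'   positive.
#' @return list with `ca`, `se`, `sp`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("confusion counts sum to zero", call. = FALSE)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: no %s samples in the test set", what,
                      if (what == "sensitivity") "positive" else "negative"))
      NaN
    } else num / den
  }
  list(ca = (tp + tn) / total,
       se = ratio(tp, tp + fn, "sensitivity"),
       sp = ratio(tn, tn + fp, "specificity"))
}

#' ROC curve and area under it
#'
#' Sweeps a threshold over the unique decision scores (ties share one
#' threshold), plotting the true-positive rate against the false-positive
#' rate, and integrates the staircase with the trapezoidal rule. The
#' high-performance group is the positive class; larger scores indicate
#' "more positive".
#'
#' @param scores numeric decision values.
#' @param labels factor/character with levels `low`/`high` (high = positive).
#' @return list with `roc` (data frame `threshold, fpr, tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "high"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("undefined AUC: both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  k <- nrow(roc)
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-k]) / 2)
  list(roc = roc, auc = auc)
}

# orient e1071 decision values so larger = more "high"
.svm_scores <- function(fit, newdata) {
  pred <- stats::predict(fit, newdata, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  s <- as.numeric(dv[, 1L])
  list(label = as.character(pred), score = if (first == "high") s else -s)
}

.as_group_factor <- function(labels) {
  f <- factor(as.character(labels), levels = c("low", "high"))
  if (anyNA(f)) stop("labels must be 'low'/'high'", call. = FALSE)
  f
}

#' Leave-one-out SVM classification of high/low performers
#'
#' Trains a linear-kernel support vector machine on a single feature (one
#' value per subject), leaving each subject out in turn. Within every fold
#' the feature is standardized with the training fold's mean and standard
#' deviation only, so no statistic of the held-out subject leaks into its
#' own fold. Pooled held-out predictions give CA/SE/SP; the ROC and AUC are
#' built from the pooled held-out decision scores.
#'
#' @param feature numeric vector, one feature value per subject.
#' @param labels group labels (`low`/`high`), high = positive.
#' @param cost SVM cost parameter C (default 1).
#' @param scheme tag recorded in the report (e.g. `"intra_s1"`).
#' @return list of class `classification_report`: `scheme`, `ca`, `se`,
#'   `sp`, `auc`, `counts` (tp/tn/fp/fn), `predictions`
#'   (`subject, label, predicted, score`), `roc`.
#' @export
loocv_classify <- function(feature, labels, cost = 1, scheme = "intra") {
  y <- .as_group_factor(labels)
  n <- length(feature)
  if (n != length(y)) stop("feature/labels length mismatch", call. = FALSE)
  if (min(table(y)) < 2L)
    stop("need at least 2 subjects per class for leave-one-out folds", call. = FALSE)
  pred <- character(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    xtr <- feature[-i]; ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2L)
      stop("degenerate fold: a class is absent from a training fold", call. = FALSE)
    mu <- mean(xtr); sdev <- stats::sd(xtr)
    if (sdev == 0) stop("degenerate fold: zero feature variance", call. = FALSE)
    tr <- data.frame(x = (xtr - mu) / sdev, y = factor(ytr, levels = c("low", "high")))
    fit <- e1071::svm(y ~ x, data = tr, kernel = "linear", cost = cost,
                      scale = FALSE)
    out <- .svm_scores(fit, data.frame(x = (feature[i] - mu) / sdev))
    pred[i] <- out$label
    score[i] <- out$score
  }
  .classification_report(y, pred, score, scheme,
                         subjects = seq_len(n))
}

#' Cross-session SVM classification
#'
#' Fits one linear-kernel SVM on an entire training session (feature
#' standardized with training-session statistics) and evaluates it once on
#' the other session. If the test session contains only one class,
#' sensitivity or specificity is reported as `NaN` with a warning while CA
#' remains defined.
#'
#' @param train_feature,train_labels training-session feature and labels.
#' @param test_feature,test_labels test-session feature and labels.
#' @param cost SVM cost parameter C (default 1).
#' @param scheme tag recorded in the report.
#' @return a `classification_report` (see [loocv_classify()]).
#' @export
cross_session_classify <- function(train_feature, train_labels,
                                   test_feature, test_labels,
                                   cost = 1, scheme = "inter") {
  ytr <- .as_group_factor(train_labels)
  yte <- .as_group_factor(test_labels)
  if (length(train_feature) == 0L || length(test_feature) == 0L)
    stop("empty session", call. = FALSE)
  if (nlevels(droplevels(ytr)) < 2L)
    stop("training session must contain both classes", call. = FALSE)
  mu <- mean(train_feature); sdev <- stats::sd(train_feature)
  tr <- data.frame(x = (train_feature - mu) / sdev, y = ytr)
  fit <- e1071::svm(y ~ x, data = tr, kernel = "linear", cost = cost, scale = FALSE)
  out <- .svm_scores(fit, data.frame(x = (test_feature - mu) / sdev))
  .classification_report(yte, out$label, out$score, scheme,
                         subjects = seq_along(test_feature))
}

.classification_report <- function(y, pred, score, scheme, subjects) {
  tp <- sum(pred == "high" & y == "high")
  tn <- sum(pred == "low" & y == "low")
  fp <- sum(pred == "high" & y == "low")
  fn <- sum(pred == "low" & y == "high")
  metrics <- confusion_metrics(tp, tn, fp, fn)
  ra <- if (nlevels(droplevels(y)) == 2L) roc_auc(score, y)
        else { warning("AUC undefined: one class only in test set"); list(roc = NULL, auc = NaN) }
  structure(
    list(scheme = scheme, ca = metrics$ca, se = metrics$se, sp = metrics$sp,
         auc = ra$auc, counts = c(tp = tp, tn = tn, fp = fp, fn = fn),
         predictions = data.frame(subject = subjects, label = as.character(y),
                                  predicted = pred, score = score),
         roc = ra$roc),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report %s> CA %.3f  SE %.3f  SP %.3f  AUC %.3f (n = %d)\n",
              x$scheme, x$ca, x$se, x$sp, x$auc, nrow(x$predictions)))
  invisible(x)
}

#' Leave-one-out SVR prediction of SRT scores
#'
#' Predicts each subject's SRT score from the selected channel's spectral
#' entropy with an RBF-kernel support vector regression, leaving each subject
#' out in turn. Feature and target are standardized with training-fold
#' statistics only; predictions are mapped back to the original score scale.
#' Reports the root-mean-square error of prediction over the pooled held-out
#' predictions and the Pearson correlation between predicted and actual
#' scores.
#'
#' @param feature numeric feature vector (one value per subject).
#' @param target numeric SRT scores.
#' @param cost,epsilon SVR parameters (defaults 1 and 0.1).
#' @param gamma RBF width; default `NULL` uses the reciprocal of the
#'   training-fold feature variance after standardization (i.e. 1).
#' @param scope tag recorded in the report (e.g. `"merged"`).
#' @return list of class `regression_report`: `scope`, `rmsep`, `r`, `p`,
#'   `predictions` (`subject, actual, predicted`).
#' @export
loocv_svr <- function(feature, target, cost = 1, epsilon = 0.1, gamma = NULL,
                      scope = "merged") {
  n <- length(feature)
  if (n < 3L) stop("SVR leave-one-out needs at least 3 subjects", call. = FALSE)
  if (stats::sd(target) == 0)
    stop("degenerate target: zero SRT variance", call. = FALSE)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    xtr <- feature[-i]; ttr <- target[-i]
    mx <- mean(xtr); sx <- stats::sd(xtr)
    mt <- mean(ttr); st <- stats::sd(ttr)
    if (sx == 0) stop("degenerate fold: zero feature variance", call. = FALSE)
    xs <- (xtr - mx) / sx
    g <- if (is.null(gamma)) 1 / stats::var(xs) else gamma
    fit <- e1071::svm(x = matrix(xs, ncol = 1L), y = (ttr - mt) / st,
                      type = "eps-regression", kernel = "radial",
                      cost = cost, epsilon = epsilon, gamma = g, scale = FALSE)
    z <- stats::predict(fit, matrix((feature[i] - mx) / sx, ncol = 1L))
    pred[i] <- z * st + mt
  }
  rmsep <- sqrt(mean((pred - target)^2))
  ct <- stats::cor.test(pred, target, method = "pearson")
  structure(
    list(scope = scope, rmsep = rmsep, r = unname(ct$estimate), p = ct$p.value,
         predictions = data.frame(subject = seq_len(n), actual = target,
                                  predicted = pred)),
    class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report %s> RMSEP %.3f  r %.3f (p = %.3g, n = %d)\n",
              x$scope, x$rmsep, x$r, x$p, nrow(x$predictions)))
  invisible(x)
}
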