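#' Dichotomize a clinical variable into binary labels
#'
#' Survival rule: label 1 iff survival exceeds 12 months. Median rule
#' (immune signature scores): label 1 iff the score exceeds the cohort
#' median, 0 at or below it.
#'
#' @param values Numeric vector, one value per subject.
#' @param rule `"threshold-12-months"` or `"median"`.
#' @return Integer vector of 0/1 labels.
#' @export
dichotomize_labels <- function(values,
                               rule = c("threshold-12-months", "median")) {
  rule <- match.arg(rule)
  hg_assert(length(values) >= 2, "need at least 2 subjects")
  if (rule == "threshold-12-months") {
    as.integer(values > 12)
  } else {
    if (length(unique(values)) == 1) {
      hg_error("constant scores: median dichotomization degenerate",
               "habitatgraph_degenerate_labels")
    }
    as.integer(values > stats::median(values))
  }
}

# Column-wise median imputation; statistics always come from `train`.
impute_by_median <- function(train, test = train) {
  med <- apply(train, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0  # column entirely missing in the training fold
  fill <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- med[j]
    m
  }
  list(train = fill(train), test = fill(test))
}

# Upsample (with replacement) so both classes reach the majority count.
balance_classes <- function(idx, y) {
  counts <- table(y[idx])
  target <- max(counts)
  unlist(lapply(names(counts), function(cl) {
    members <- idx[y[idx] == cl]
    if (length(members) == target) members
    else c(members, sample(members, target - length(members), replace = TRUE))
  }), use.names = FALSE)
}

#' Cross-validated random-forest probabilities
#'
#' Stratified k-fold cross-validation of a random forest. Within each
#' training fold, missing features are imputed by the training-fold median
#' and class imbalance is removed by resampling the minority class to the
#' majority count (class-proportional sampling). Out-of-fold probabilities
#' of class 1 are returned for every subject. Deterministic given the seed.
#'
#' @param x Numeric matrix or data.frame of features (subjects x features).
#' @param y Binary labels (0/1), at least `k` subjects per class.
#' @param n_trees Trees per forest (default 10000).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List with `prob` (out-of-fold class-1 probabilities), `fold`
#'   (fold assignment per subject), `labels` and `seed`.
#' @export
crossvalidated_rf <- function(x, y, n_trees = 10000, k = 5, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  hg_assert(length(y) == nrow(x), "labels must match feature rows")
  hg_assert(all(y %in% 0:1), "labels must be 0/1")
  if (min(table(y)) < k) {
    hg_error(sprintf("need at least %d subjects per class for %d folds", k, k),
             "habitatgraph_stratification_error")
  }
  # drop features missing for every subject (carry no information)
  x <- x[, colSums(!is.na(x)) > 0, drop = FALSE]
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in 0:1) {
      members <- which(y == cl)
      fold[members] <- sample(rep(seq_len(k), length.out = length(members)))
    }
  })
  prob <- numeric(length(y))
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    imp <- impute_by_median(x[train_idx, , drop = FALSE],
                            x[test_idx, , drop = FALSE])
    withr::with_seed(seed + f, {
      bal <- balance_classes(seq_along(train_idx), y[train_idx])
      rf <- randomForest::randomForest(imp$train[bal, , drop = FALSE],
                                       factor(y[train_idx][bal], levels = 0:1),
                                       ntree = n_trees)
      prob[test_idx] <- predict(rf, imp$test, type = "prob")[, "1"]
    })
  }
  list(prob = prob, fold = fold, labels = y, seed = as.integer(seed))
}

#' ROC analysis, Youden-optimal cutoff and summary metrics
#'
#' Sweeps all unique probability thresholds, computes the ROC curve and
#' its trapezoidal AUC, picks the cutoff maximizing sensitivity +
#' specificity (smallest such threshold on ties), and reports accuracy
#' `ACC = (TP + TN) / (TP + FN + TN + FP)` at that cutoff together with
#' the mean absolute error between probabilities and labels. If features
#' are supplied, Gini importances from a forest refit on the full table
#' are included.
#'
#' @param prob Predicted class-1 probabilities.
#' @param labels Binary 0/1 labels (both classes present).
#' @param x Optional feature table for the importance refit.
#' @param n_trees Trees for the importance refit.
#' @param seed Seed for the importance refit.
#' @return Object of class `classifier_report`: `auc`, `tpr`, `tnr`,
#'   `acc`, `mae`, `cutoff`, `operating_point` (fpr, tpr), `roc`
#'   (data.frame of the full sweep) and optional `importance` (named,
#'   decreasing mean decrease in Gini).
#' @export
roc_report <- function(prob, labels, x = NULL, n_trees = 1000, seed = 1L) {
  labels <- as.integer(labels)
  hg_assert(length(prob) == length(labels), "prob/labels length mismatch")
  if (length(unique(labels)) < 2) {
    hg_error("ROC undefined: only one class present",
             "habitatgraph_undefined_roc")
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  # predict positive when prob > threshold; -Inf gives the (1,1) corner
  thr <- c(-Inf, sort(unique(prob)))
  tpr <- vapply(thr, function(c) sum(prob > c & labels == 1) / n1, 0)
  fpr <- vapply(thr, function(c) sum(prob > c & labels == 0) / n0, 0)
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (head(tpr[o], -1) + tpr[o][-1]) / 2)
  youden <- tpr + (1 - fpr)
  best <- which(youden == max(youden))
  best <- best[which.min(thr[best])]
  cutoff <- thr[best]
  tp <- sum(prob > cutoff & labels == 1)
  fn <- n1 - tp
  fp <- sum(prob > cutoff & labels == 0)
  tn <- n0 - fp
  rep <- list(auc = auc,
              tpr = tp / n1, tnr = tn / n0,
              acc = (tp + tn) / (tp + fn + tn + fp),
              mae = mean(abs(prob - labels)),
              cutoff = cutoff,
              operating_point = c(fpr = fp / n0, tpr = tp / n1),
              confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
              roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr))
  if (!is.null(x)) {
    x <- as.matrix(x)
    x <- x[, colSums(!is.na(x)) > 0, drop = FALSE]
    full <- impute_by_median(x)$train
    rep$importance <- withr::with_seed(seed, {
      rf <- randomForest::randomForest(full, factor(labels, levels = 0:1),
                                       ntree = n_trees, importance = TRUE)
      sort(rf$importance[, "MeanDecreaseGini"], decreasing = TRUE)
    })
  }
  structure(rep, class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report: AUC %.3f | TPR %.3f | TNR %.3f | ACC %.3f | MAE %.3f\n",
              x$auc, x$tpr, x$tnr, x$acc, x$mae))
  cat(sprintf("  Youden-optimal cutoff %.4f at operating point (FPR %.3f, TPR %.3f)\n",
              x$cutoff, x$operating_point["fpr"], x$operating_point["tpr"]))
  if (!is.null(x$importance)) {
    cat("  top features by Gini importance:",
        paste(names(head(x$importance, 5)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cross-validated evaluation of a feature table
#'
#' Convenience wrapper: [crossvalidated_rf()] followed by [roc_report()]
#' on the pooled out-of-fold probabilities.
#'
#' @inheritParams crossvalidated_rf
#' @return A `classifier_report` with the cross-validation `fold`
#'   assignments attached.
#' @export
evaluate_features <- function(x, y, n_trees = 10000, k = 5, seed = 1L) {
  cv <- crossvalidated_rf(x, y, n_trees = n_trees, k = k, seed = seed)
  rep <- roc_report(cv$prob, y, x = x, n_trees = min(n_trees, 1000),
                    seed = seed)
  rep$fold <- cv$fold
  rep$prob <- cv$prob
  rep$seed <- cv$seed
  rep
}
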