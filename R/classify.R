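# k-NN staging with cross-validated ROC/AUC evaluation.

#' Z-score standardization of a feature matrix
#'
#' Zero-variance features are dropped with a warning. When `center`/`scale`
#' are supplied (training-fold parameters) they are applied as-is.
#'
#' @param x numeric matrix (samples x features).
#' @param center,scale optional per-feature parameters; defaults are the
#'   column means and SDs of `x`.
#' @return standardized matrix with attributes `center` and `scale`.
#' @export
standardize_features <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) scale <- apply(x, 2, stats::sd)
  keep <- scale > 0
  if (!any(keep)) stopf("all features are degenerate (zero variance)")
  if (!all(keep))
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(colnames(x)[!keep], collapse = ", ")), call. = FALSE)
  out <- sweep(sweep(x[, keep, drop = FALSE], 2, center[keep]), 2,
               scale[keep], "/")
  attr(out, "center") <- center[keep]
  attr(out, "scale") <- scale[keep]
  out
}

#' k-nearest-neighbour prediction with per-class scores
#'
#' Euclidean distance; the predicted label is the majority class among the k
#' nearest training points, and the score of each class is the fraction of
#' the k neighbours belonging to it. Majority ties are broken by the
#' smallest mean neighbour distance among the tied classes, then by class
#' (factor level) order.
#'
#' @param train_x numeric matrix of training samples.
#' @param train_labels factor (or coercible) of training labels.
#' @param query_x matrix of query points (same columns as `train_x`).
#' @param k number of neighbours, `1 <= k <= nrow(train_x)`.
#' @return list with `labels` (factor) and `scores` (queries x classes
#'   matrix of neighbour fractions).
#' @export
knn_predict <- function(train_x, train_labels, query_x, k = 5L) {
  train_x <- as.matrix(train_x)
  query_x <- matrix(as.matrix(query_x), ncol = ncol(train_x))
  if (!nrow(train_x)) stopf("empty training set")
  if (!is_count(k) || k > nrow(train_x))
    stopf("k must be in [1, %d]", nrow(train_x))
  train_labels <- as.factor(train_labels)
  classes <- levels(train_labels)
  d2 <- outer(rowSums(query_x^2), rep(1, nrow(train_x))) +
    outer(rep(1, nrow(query_x)), rowSums(train_x^2)) -
    2 * tcrossprod(query_x, train_x)
  scores <- matrix(0, nrow(query_x), length(classes),
                   dimnames = list(NULL, classes))
  labels <- character(nrow(query_x))
  for (q in seq_len(nrow(query_x))) {
    nn <- order(d2[q, ])[seq_len(k)]
    votes <- table(factor(train_labels[nn], levels = classes))
    scores[q, ] <- as.numeric(votes) / k
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      mean_dist <- vapply(top, function(cl)
        mean(d2[q, nn[train_labels[nn] == cl]]), numeric(1))
      top <- top[order(mean_dist, match(top, classes))]
    }
    labels[q] <- top[1]
  }
  list(labels = factor(labels, levels = classes), scores = scores)
}

#' Per-class and macro metrics from a confusion matrix
#'
#' One-vs-rest collapse per class: sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP); accuracy is trace/total. Macro values are unweighted means
#' over classes; a class absent from the truth yields NA sensitivity and is
#' excluded from the macro mean.
#'
#' @param confusion square integer matrix, rows = true, columns = predicted.
#' @return list with `per_class` (data.frame), `accuracy`,
#'   `macro_sensitivity`, `macro_specificity`.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || any(confusion < 0))
    stopf("confusion must be a square non-negative matrix")
  total <- sum(confusion)
  per <- lapply(seq_len(nrow(confusion)), function(c) {
    tp <- confusion[c, c]
    fn <- sum(confusion[c, ]) - tp
    fp <- sum(confusion[, c]) - tp
    tn <- total - tp - fn - fp
    data.frame(class = rownames(confusion)[c] %||% as.character(c),
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
  per <- do.call(rbind, per)
  list(per_class = per,
       accuracy = sum(diag(confusion)) / total,
       macro_sensitivity = mean(per$sensitivity, na.rm = TRUE),
       macro_specificity = mean(per$specificity, na.rm = TRUE))
}

#' ROC curve and AUC from scores
#'
#' Builds the ROC curve of `scores` against binary `truth` by threshold
#' sweep over the unique score values (ties grouped), anchored at (0,0) and
#' (1,1); the AUC is the trapezoidal integral.
#'
#' @param scores numeric vector (higher = more positive).
#' @param truth logical or 0/1 vector.
#' @return a `roc_curve`: list with `points` (data.frame `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stopf("scores and truth differ in length")
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) stopf("ROC needs both positive and negative cases")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)    # end of each tie group
  tpr <- c(0, tp[last] / n_pos, 1)
  fpr <- c(0, fp[last] / n_neg, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Cross-validated k-NN staging of a feature table
#'
#' Out-of-fold predictions and per-class neighbour-fraction scores are
#' pooled into a confusion matrix, accuracy, macro-averaged one-vs-rest
#' sensitivity/specificity, and a micro-averaged one-vs-rest ROC (scores of
#' all classes pooled). Standardization parameters are estimated on each
#' training fold and applied to its test fold.
#'
#' @param x numeric matrix or data.frame of features (samples x features).
#' @param labels class labels.
#' @param k number of neighbours; default 5.
#' @param scheme `"loocv"` (default) or `"stratified"` m-fold.
#' @param folds number of folds for the stratified scheme.
#' @param seed integer seed for stratified fold assignment (unused by LOOCV,
#'   which is deterministic).
#' @param features optional character vector restricting the feature columns
#'   (e.g. `c("energy", "inverse_difference_moment", "skewness",
#'   "sum_variance")`).
#' @return a `classification_result`: `confusion`, `accuracy`, `per_class`,
#'   `macro_sensitivity`, `macro_specificity`, `roc` ([roc_curve()],
#'   micro-averaged), `scores`, `predicted`, `k`, `cv_scheme`.
#' @export
cross_validate <- function(x, labels, k = 5L,
                           scheme = c("loocv", "stratified"), folds = 5L,
                           seed = NULL, features = NULL) {
  scheme <- match.arg(scheme)
  x <- as.data.frame(x)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stopf("need at least 2 classes")
  if (any(!stats::complete.cases(x))) stopf("feature matrix contains missing values")
  n <- nrow(x)
  fold_id <- if (scheme == "loocv") seq_len(n) else {
    if (any(table(labels) < 2)) stopf("every class needs >= 2 members for stratified CV")
    id <- integer(n)
    if (!is.null(seed)) set.seed(as.integer(seed))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  }
  classes <- levels(labels)
  scores <- matrix(NA_real_, n, length(classes), dimnames = list(NULL, classes))
  predicted <- factor(rep(classes[1], n), levels = classes)
  for (f in unique(fold_id)) {
    test <- fold_id == f
    tr <- standardize_features(x[!test, , drop = FALSE])
    te <- standardize_features(x[test, , drop = FALSE],
                               center = attr(tr, "center"),
                               scale = attr(tr, "scale"))
    pred <- knn_predict(tr, labels[!test], te, k = k)
    predicted[test] <- pred$labels
    scores[test, ] <- pred$scores
  }
  confusion <- table(true = labels, predicted = predicted)
  metrics <- metrics_from_confusion(unclass(confusion))
  one_hot <- outer(as.character(labels), classes, `==`)
  roc <- roc_curve(as.vector(scores), as.vector(one_hot))
  structure(c(list(confusion = confusion), metrics,
              list(roc = roc, scores = scores, predicted = predicted,
                   k = as.integer(k), cv_scheme = scheme)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s, k = %d\n", x$cv_scheme, x$k))
  print(x$confusion)
  cat(sprintf("accuracy %.4f | macro sensitivity %.4f | macro specificity %.4f | AUC %.4f\n",
              x$accuracy, x$macro_sensitivity, x$macro_specificity, x$roc$auc))
  invisible(x)
}
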