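# Stage-two classifiers over the (gamma, epsilon, tau) NSRP feature
# vector: SVM (linear / polynomial / RBF kernels), K-nearest neighbours,
# an entropy-split decision tree (the classic C4.5 family), and a random
# forest, with stratified k-fold cross-validation and detection metrics.

.feature_cols <- c("gamma", "epsilon", "tau")

#' Classifier configuration
#'
#' @param kind one of `"SVM_LINEAR"`, `"SVM_POLY"`, `"SVM_RBF"`,
#'   `"KNN"`, `"DT"`, `"RF"`.
#' @param kernel_p kernel scale p for the RBF/poly kernels; default 1/3
#'   (one over the number of features).
#' @param poly_coef0_r polynomial kernel offset r, default 0.
#' @param poly_degree_u polynomial kernel degree u, default 3.
#' @param knn_k neighbours for KNN, default 5.
#' @param rf_trees trees for the random forest, default 100.
#' @param svm_C SVM cost, default 1.
#' @param standardize centre/scale features on the training split before
#'   SVM/KNN (default `TRUE`); the scaler is fit on training data only
#'   and bundled with the model. gamma, epsilon and tau live on scales an
#'   order of magnitude apart, so distance-based learners benefit.
#' @param seed integer seed making training deterministic.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(kind = "SVM_LINEAR", kernel_p = 1 / 3,
                              poly_coef0_r = 0, poly_degree_u = 3L,
                              knn_k = 5L, rf_trees = 100L, svm_C = 1.0,
                              standardize = TRUE, seed = 1L) {
  kind <- match.arg(kind, c("SVM_LINEAR", "SVM_POLY", "SVM_RBF",
                            "KNN", "DT", "RF"))
  stopifnot(kernel_p > 0, poly_degree_u >= 1L, knn_k >= 1L, rf_trees >= 1L,
            svm_C > 0)
  structure(list(kind = kind, kernel_p = kernel_p,
                 poly_coef0_r = poly_coef0_r,
                 poly_degree_u = as.integer(poly_degree_u),
                 knn_k = as.integer(knn_k), rf_trees = as.integer(rf_trees),
                 svm_C = svm_C, standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

.as_label <- function(x) factor(as.character(x), levels = c("ADL", "FALL"))

.check_samples <- function(samples) {
  if (!all(.feature_cols %in% names(samples)) || !"label" %in% names(samples))
    stop("samples need columns gamma, epsilon, tau, label")
  if (nrow(samples) < 2L) stop("need at least 2 samples")
  lab <- .as_label(samples$label)
  if (anyNA(lab)) stop("labels must be 'FALL' or 'ADL'")
  if (nlevels(droplevels(lab)) < 2L)
    stop("training requires both FALL and ADL samples")
  x <- as.matrix(samples[, .feature_cols])
  if (any(!is.finite(x))) stop("features must be finite")
  lab
}

#' Train a fall/ADL classifier
#'
#' @param samples data.frame with columns `gamma`, `epsilon`, `tau` and
#'   `label` (`"FALL"`/`"ADL"`).
#' @param cfg a [classifier_config()].
#' @return Object of class `fall_classifier` supporting [predict()] (and
#'   decision scores via [decision_score()]).
#' @export
fall_classifier <- function(samples, cfg = classifier_config()) {
  label <- .check_samples(samples)
  x <- as.matrix(samples[, .feature_cols])
  center <- rep(0, 3); scale <- rep(1, 3)
  if (cfg$standardize && cfg$kind != "DT" && cfg$kind != "RF") {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    scale[scale == 0] <- 1
    x <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  }
  set.seed(cfg$seed)
  fit <- switch(cfg$kind,
    SVM_LINEAR = e1071::svm(x, label, kernel = "linear", cost = cfg$svm_C,
                            scale = FALSE, probability = FALSE),
    SVM_POLY = e1071::svm(x, label, kernel = "polynomial",
                          gamma = cfg$kernel_p, coef0 = cfg$poly_coef0_r,
                          degree = cfg$poly_degree_u, cost = cfg$svm_C,
                          scale = FALSE),
    SVM_RBF = e1071::svm(x, label, kernel = "radial", gamma = cfg$kernel_p,
                         cost = cfg$svm_C, scale = FALSE),
    KNN = list(train_x = x, train_y = label),  # lazy learner
    DT = rpart::rpart(label ~ ., data = data.frame(x, label = label),
                      method = "class",
                      parms = list(split = "information"),
                      control = rpart::rpart.control(minsplit = 2L, cp = 0)),
    RF = randomForest::randomForest(x, label, ntree = cfg$rf_trees))
  structure(list(kind = cfg$kind, fit = fit, cfg = cfg,
                 center = center, scale = scale),
            class = "fall_classifier")
}

.prep_x <- function(model, newdata) {
  x <- as.matrix(newdata[, .feature_cols, drop = FALSE])
  sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
}

#' @export
predict.fall_classifier <- function(object, newdata, ...) {
  x <- .prep_x(object, newdata)
  out <- switch(object$kind,
    SVM_LINEAR = , SVM_POLY = , SVM_RBF = predict(object$fit, x),
    KNN = class::knn(object$fit$train_x, x, object$fit$train_y,
                     k = object$cfg$knn_k),
    DT = predict(object$fit, data.frame(x), type = "class"),
    RF = predict(object$fit, x))
  factor(as.character(out), levels = c("ADL", "FALL"))
}

#' Real-valued decision score for ROC analysis
#'
#' Larger scores mean "more fall-like". For SVMs this is the signed
#' distance to the separating hyperplane (oriented toward FALL); for
#' KNN, the fraction of neighbours voting FALL; for the tree and forest,
#' the predicted FALL probability / vote fraction.
#'
#' @param model a `fall_classifier`.
#' @param newdata data.frame with `gamma`, `epsilon`, `tau`.
#' @return Numeric vector of scores.
#' @export
decision_score <- function(model, newdata) {
  x <- .prep_x(model, newdata)
  switch(model$kind,
    SVM_LINEAR = , SVM_POLY = , SVM_RBF = {
      dv <- attr(predict(model$fit, x, decision.values = TRUE),
                 "decision.values")
      # e1071 orients decision values toward the first training class;
      # flip so positive always means FALL
      if (grepl("^FALL/", colnames(dv)[1L])) dv[, 1L] else -dv[, 1L]
    },
    KNN = {
      pr <- class::knn(model$fit$train_x, x, model$fit$train_y,
                       k = model$cfg$knn_k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "FALL", p, 1 - p)
    },
    DT = predict(model$fit, data.frame(x), type = "prob")[, "FALL"],
    RF = predict(model$fit, x, type = "prob")[, "FALL"])
}

#' @export
print.fall_classifier <- function(x, ...) {
  cat(sprintf("<fall_classifier> %s (standardize=%s)\n", x$kind,
              x$cfg$standardize))
  invisible(x)
}

.metrics_from_counts <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(accuracy = (tp + tn) / n, precision = precision, recall = recall,
       f1 = f1,
       confusion = matrix(c(tp, fn, fp, tn), nrow = 2L,
                          dimnames = list(actual = c("FALL", "ADL"),
                                          predicted = c("FALL", "ADL"))))
}

.metrics_from_labels <- function(truth, pred) {
  truth <- .as_label(truth); pred <- .as_label(pred)
  .metrics_from_counts(tp = sum(truth == "FALL" & pred == "FALL"),
                       fp = sum(truth == "ADL" & pred == "FALL"),
                       fn = sum(truth == "FALL" & pred == "ADL"),
                       tn = sum(truth == "ADL" & pred == "ADL"))
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by label and assigned from the config seed, so a
#' run is reproducible. Each fold's model is trained on the remaining
#' folds (including its own feature scaler) and scored on the held-out
#' fold; the report carries the per-fold metrics and their mean.
#'
#' @param samples labelled sample data.frame (see [fall_classifier()]).
#' @param cfg a [classifier_config()].
#' @param folds number of folds, default 3.
#' @return List of class `metrics_report`: `accuracy`, `precision`,
#'   `recall`, `f1` (fold means), `confusion` (summed over folds),
#'   `per_fold` (data.frame).
#' @export
cross_validate <- function(samples, cfg = classifier_config(), folds = 3L) {
  label <- .check_samples(samples)
  n <- nrow(samples)
  if (n < folds) stop("need at least as many samples as folds (n = ", n,
                      ", folds = ", folds, ")")
  set.seed(cfg$seed)
  fold_id <- integer(n)
  for (lv in levels(label)) {
    idx <- sample(which(label == lv))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  per <- vector("list", folds)
  conf <- matrix(0, 2L, 2L)
  for (k in seq_len(folds)) {
    tr <- samples[fold_id != k, , drop = FALSE]
    te <- samples[fold_id == k, , drop = FALSE]
    model <- fall_classifier(tr, cfg)
    m <- .metrics_from_labels(te$label, predict(model, te))
    conf <- conf + m$confusion
    per[[k]] <- data.frame(fold = k, accuracy = m$accuracy,
                           precision = m$precision, recall = m$recall,
                           f1 = m$f1)
  }
  per <- do.call(rbind, per)
  dimnames(conf) <- list(actual = c("FALL", "ADL"),
                         predicted = c("FALL", "ADL"))
  structure(list(accuracy = mean(per$accuracy),
                 precision = mean(per$precision, na.rm = TRUE),
                 recall = mean(per$recall, na.rm = TRUE),
                 f1 = mean(per$f1, na.rm = TRUE),
                 confusion = conf, per_fold = per),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Detection metrics from a per-action count table
#'
#' Collapses a table of per-action event counts (how many events of each
#' action were called non-fall vs fall) to a 2x2 confusion matrix with
#' FALL as the positive class, then computes accuracy, precision, recall
#' and F1. Because the positive-class convention changes precision and
#' recall, the non-fall-positive variants are reported alongside.
#'
#' @param counts data.frame with columns `action`, `predicted_nonfall`,
#'   `predicted_fall` (nonnegative integers).
#' @param fall_actions character vector naming which actions are true
#'   falls.
#' @return `metrics_report` with extra fields `precision_nonfall` and
#'   `recall_nonfall` (the same metrics with non-fall as positive class).
#' @export
confusion_metrics <- function(counts, fall_actions) {
  need <- c("action", "predicted_nonfall", "predicted_fall")
  if (!is.data.frame(counts) || !all(need %in% names(counts)) ||
      nrow(counts) == 0L)
    stop("counts must be a nonempty data.frame with columns ",
         paste(need, collapse = ", "))
  if (any(counts$predicted_nonfall < 0 | counts$predicted_fall < 0))
    stop("counts must be nonnegative")
  isfall <- counts$action %in% fall_actions
  tp <- sum(counts$predicted_fall[isfall])
  fn <- sum(counts$predicted_nonfall[isfall])
  fp <- sum(counts$predicted_fall[!isfall])
  tn <- sum(counts$predicted_nonfall[!isfall])
  m <- .metrics_from_counts(tp, fp, fn, tn)
  # same table with non-fall as the positive class
  m$precision_nonfall <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  m$recall_nonfall <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(m, class = "metrics_report")
}

#' ROC curve and AUC from decision scores
#'
#' Standard score-thresholding ROC with FALL as the positive class and
#' trapezoid-rule AUC; the score orientation is fixed (higher = more
#' fall-like), never auto-flipped, so anti-correlated scores legitimately
#' give AUC below 0.5.
#'
#' @param model a `fall_classifier` (must expose decision scores), or
#'   `NULL` when `scores` is given directly.
#' @param samples labelled sample data.frame.
#' @param scores optional numeric vector of precomputed scores.
#' @return List with `points` (data.frame of `fpr`, `tpr`, `threshold`)
#'   and `auc`.
#' @export
roc_curve <- function(model, samples, scores = NULL) {
  truth <- .as_label(samples$label)
  if (nlevels(droplevels(truth)) < 2L)
    stop("ROC needs both classes present")
  if (is.null(scores)) scores <- decision_score(model, samples)
  r <- pROC::roc(response = truth, predictor = as.numeric(scores),
                 levels = c("ADL", "FALL"), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities,
                    threshold = r$thresholds)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  list(points = pts, auc = as.numeric(pROC::auc(r)))
}

#' Save / load a trained classifier
#'
#' @param model a `fall_classifier`.
#' @param path file path.
#' @return `path` invisibly; `read_classifier` returns the model.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "fall_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "fall_classifier"))
    stop("'", path, "' does not contain a fall_classifier")
  model
}
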