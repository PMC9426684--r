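# Segmentation and classification losses and evaluation metrics:
# per-channel Dice, channel-weighted Dice loss, inverse-frequency class
# weights, class-weighted cross-entropy, confusion-matrix summaries and
# cross-validated ROC/AUC.

#' Channel weights for the weighted Dice loss
#'
#' @param beta length-4 non-negative weights for (background, myocardium,
#'   LV cavity, scar). The default `(0.15, 0.25, 0.25, 0.35)` assigns the most
#'   weight to the scar channel and the least to the background.
#' @param epsilon smoothing constant added to numerator and denominator of the
#'   Dice ratio so that an empty ground-truth channel matched by an empty
#'   prediction scores 1 (loss 0) instead of 0/0.
#' @return Object of class `dice_weights`.
#' @export
dice_weights <- function(beta = c(0.15, 0.25, 0.25, 0.35), epsilon = 1e-7) {
  if (length(beta) != 4 || any(beta < 0)) stopf("beta must be 4 non-negative weights")
  if (epsilon <= 0) stopf("epsilon must be > 0")
  structure(list(beta = beta, epsilon = epsilon), class = "dice_weights")
}

#' Dice similarity of one soft channel
#'
#' `DSC = (2 * sum(y * y_hat) + eps) / (sum(y) + sum(y_hat) + eps)`. On hard
#' binary masks this equals the set-overlap form `2|A n B| / (|A| + |B|)` as
#' `eps -> 0`; on soft predictions `y_hat` is the posterior probability map.
#'
#' @param y ground-truth channel (0/1 or probabilities), any numeric array.
#' @param y_hat predicted channel, same shape.
#' @param epsilon smoothing constant.
#' @return Dice score in `[0, 1]`.
#' @export
dice_per_channel <- function(y, y_hat, epsilon = 1e-7) {
  if (!identical(dim(y) %||% length(y), dim(y_hat) %||% length(y_hat))) {
    stopf("y and y_hat must have identical shapes")
  }
  (2 * sum(y * y_hat) + epsilon) / (sum(y) + sum(y_hat) + epsilon)
}

#' Channel-weighted Dice loss
#'
#' `L = sum_i beta_i * (1 - DSC_i)` over the four channels (background,
#' myocardium, LV cavity, scar). With the default weights `L` lies in
#' `[0, 1]`; in general `0 <= L <= sum(beta)`.
#'
#' @param y,y_hat arrays with 4 channels along the last dimension, or lists
#'   of 4 equal-shape arrays (ground truth one-hot; prediction probabilities).
#' @param w a [dice_weights()].
#' @return Non-negative loss.
#' @export
weighted_dice_loss <- function(y, y_hat, w = dice_weights()) {
  ych <- split_channels4(y)
  pch <- split_channels4(y_hat)
  loss <- 0
  for (i in 1:4) {
    loss <- loss + w$beta[i] * (1 - dice_per_channel(ych[[i]], pch[[i]], w$epsilon))
  }
  loss
}

# Accept a list of 4 arrays or an array whose last dimension has extent 4.
split_channels4 <- function(x) {
  if (is.list(x)) {
    if (length(x) != 4) stopf("expected 4 channels, got %d", length(x))
    return(x)
  }
  d <- dim(x)
  if (is.null(d) || d[length(d)] != 4) stopf("expected 4 channels along the last dimension")
  idx <- as.matrix(expand.grid(lapply(d[-length(d)], seq_len)))
  lapply(1:4, function(i) {
    arr <- array(x, dim = c(prod(d[-length(d)]), 4))[, i]
    array(arr, dim = d[-length(d)])
  })
}

#' Inverse-frequency class weights
#'
#' `lambda_i = (1 / k_i) * (N / C)` where `k_i` is the sample count of class
#' `i`, `N = sum(k)` and `C` the number of classes. Balanced counts give unit
#' weights; the minority class receives a weight above 1. Weights are stored
#' at full precision; `print()` displays 3 decimals.
#'
#' @param class_counts positive integer counts, one per class.
#' @param n_classes number of classes `C` (default `length(class_counts)`).
#' @return Object of class `class_weights` with fields `lambda`,
#'   `class_counts`, `total` and `n_classes`.
#' @examples
#' compute_class_weights(c(336, 170))  # 0.753, 1.488
#' @export
compute_class_weights <- function(class_counts, n_classes = length(class_counts)) {
  if (any(class_counts <= 0)) stopf("all class counts must be > 0")
  n_total <- sum(class_counts)
  lambda <- (1 / class_counts) * (n_total / n_classes)
  structure(list(lambda = lambda, class_counts = class_counts,
                 total = n_total, n_classes = n_classes),
            class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat(sprintf("class weights (N = %d, C = %d): %s\n", x$total, x$n_classes,
              paste(sprintf("lambda_%d = %.3f", seq_along(x$lambda) - 1, x$lambda),
                    collapse = ", ")))
  invisible(x)
}

#' Class-weighted cross-entropy
#'
#' Per-sample weighted negative log-likelihood for a binary task:
#' `E = -(1/N) * sum_n lambda_c(n) * log(y_hat_n[c(n)])` where `c(n)` is the
#' true class of sample `n`. With unit weights this reduces to the mean
#' cross-entropy. The sigmoid-head probability `p` of class 1 is expanded to
#' the pair `(1 - p, p)` so the one-hot inner product is well defined.
#' Probabilities are clipped to `[delta, 1 - delta]`, `delta = 1e-7`, to keep
#' the log finite.
#'
#' @param y true labels: either an `N x 2` one-hot matrix or a 0/1 vector.
#' @param y_hat predicted probabilities: `N x 2` matrix or a vector of
#'   class-1 probabilities.
#' @param w a `class_weights` object (or numeric length-2 `lambda`).
#' @return Mean weighted cross-entropy (>= 0).
#' @export
weighted_cross_entropy <- function(y, y_hat, w = compute_class_weights(c(1, 1))) {
  lambda <- if (inherits(w, "class_weights")) w$lambda else as.numeric(w)
  if (length(lambda) != 2) stopf("two class weights required")
  if (is.matrix(y)) {
    cls <- max.col(y) - 1L
  } else {
    cls <- as.integer(y)
  }
  if (!all(cls %in% c(0L, 1L))) stopf("labels must be binary")
  if (is.matrix(y_hat)) {
    p1 <- y_hat[, 2]
  } else {
    p1 <- as.numeric(y_hat)
  }
  if (any(p1 < 0 | p1 > 1)) stopf("probabilities must lie in [0, 1]")
  delta <- 1e-7
  p1 <- pmin(pmax(p1, delta), 1 - delta)
  p_true <- ifelse(cls == 1L, p1, 1 - p1)
  mean(lambda[cls + 1L] * (-log(p_true)))
}

#' Binary classification report
#'
#' Confusion matrix and derived metrics for binary labels: precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 (harmonic mean) and accuracy.
#' Metrics with a zero denominator are reported as 0 with the corresponding
#' flag listed in `zero_division`.
#'
#' @param y_true,y_pred equal-length 0/1 vectors.
#' @return List with `confusion` (2x2 matrix, truth in rows), `precision`,
#'   `recall`, `f1`, `accuracy` and `zero_division` (character vector of
#'   flagged metrics, empty when none).
#' @export
classification_report <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stopf("length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) stopf("labels must be binary (0/1)")
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  flags <- character(0)
  precision <- if (tp + fp == 0) { flags <- c(flags, "precision"); 0 } else tp / (tp + fp)
  recall <- if (tp + fn == 0) { flags <- c(flags, "recall"); 0 } else tp / (tp + fn)
  f1 <- if (precision + recall == 0) { flags <- c(flags, "f1"); 0 } else {
    2 * precision * recall / (precision + recall)
  }
  confusion <- matrix(c(tn, fn, fp, tp), 2, 2,
                      dimnames = list(truth = c("0", "1"), predicted = c("0", "1")))
  list(confusion = confusion, precision = precision, recall = recall,
       f1 = f1, accuracy = (tp + tn) / length(y_true), zero_division = flags)
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin over folds.
stratified_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Cross-validated ROC curves and AUC
#'
#' Stratified k-fold cross-validation: for each fold the model is fitted on
#' the remaining folds and scored on the held-out fold; a ROC curve and AUC
#' are computed per fold, and a mean curve (+/- 1 SD band) is obtained by
#' interpolating each fold's TPR onto a common FPR grid.
#'
#' @param features numeric matrix or data frame (rows = samples).
#' @param labels binary 0/1 vector, both classes present.
#' @param model_spec function `(X_train, y_train) -> function(X) -> scores`
#'   returning continuous decision scores (larger = class 1). See
#'   [svm_model_spec()] and [tree_model_spec()].
#' @param n_folds folds (default 10; reduced with a warning when a class has
#'   fewer samples than folds).
#' @param seed fold-assignment seed.
#' @param fpr_grid common false-positive-rate grid for curve averaging.
#' @return List with `fold_auc`, `mean_auc`, `sd_auc`, `fpr_grid`,
#'   `mean_tpr`, `sd_tpr`, `fold_curves` (list of data frames) and `n_folds`.
#' @export
cv_roc_auc <- function(features, labels, model_spec, n_folds = 10, seed = 0L,
                       fpr_grid = seq(0, 1, by = 0.01)) {
  X <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stopf("labels must contain both classes")
  min_class <- min(table(labels))
  if (min_class < n_folds) {
    warning(sprintf("reducing folds from %d to %d (smallest class size)",
                    n_folds, min_class))
    n_folds <- min_class
  }
  folds <- stratified_folds(labels, n_folds, seed)
  fold_auc <- numeric(n_folds)
  curves <- vector("list", n_folds)
  tpr_mat <- matrix(NA_real_, n_folds, length(fpr_grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    predictor <- model_spec(X[tr, , drop = FALSE], labels[tr])
    scores <- predictor(X[te, , drop = FALSE])
    roc <- pROC::roc(labels[te], scores, quiet = TRUE,
                     direction = "<", levels = c(0, 1))
    fold_auc[f] <- as.numeric(pROC::auc(roc))
    fpr <- rev(1 - roc$specificities)
    tpr <- rev(roc$sensitivities)
    curves[[f]] <- data.frame(fpr = fpr, tpr = tpr)
    tpr_mat[f, ] <- stats::approx(fpr, tpr, xout = fpr_grid, ties = max,
                                  yleft = 0, yright = 1)$y
  }
  list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
       sd_auc = stats::sd(fold_auc), fpr_grid = fpr_grid,
       mean_tpr = colMeans(tpr_mat), sd_tpr = apply(tpr_mat, 2, stats::sd),
       fold_curves = curves, n_folds = n_folds)
}
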