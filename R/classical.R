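# Classical learning on the engineered feature table: seeded splitting,
# z-score standardization fitted on the training partition, RBF-kernel SVM
# and decision-tree classifiers, and permutation feature importance.

#' Split sample indices into seeded partitions
#'
#' Floor-remainder rule: every non-training partition receives
#' `floor(fraction * n)` samples and the training partition the remainder,
#' after a seeded shuffle. With `labels` supplied the split is stratified:
#' partition sizes still follow the global floor rule, filled class by class
#' with largest-remainder rounding.
#'
#' @param n_samples total sample count.
#' @param fractions named or unnamed fractions summing to 1; the first
#'   entry is the training fraction (e.g. `c(0.7, 0.15, 0.15)` or
#'   `c(0.8, 0.2)`).
#' @param seed shuffle seed.
#' @param labels optional binary labels enabling stratification.
#' @return List of integer index vectors, one per partition, named
#'   `train` / `val` / `test` (or `train` / `test` for two fractions).
#' @examples
#' lengths(split_dataset(722, c(0.70, 0.15, 0.15)))  # 506 108 108
#' @export
split_dataset <- function(n_samples, fractions, seed = 0L, labels = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8) stopf("fractions must sum to 1")
  n_parts <- length(fractions)
  if (n_samples < n_parts) stopf("need at least one sample per partition")
  part_names <- if (n_parts == 2) c("train", "test") else
    if (n_parts == 3) c("train", "val", "test") else
      paste0("part", seq_len(n_parts))
  sizes <- integer(n_parts)
  sizes[-1] <- floor(fractions[-1] * n_samples)
  sizes[1] <- n_samples - sum(sizes[-1])
  if (any(sizes == 0)) warning("a partition is empty at this sample size")

  assign_blocks <- function(idx, sizes) {
    # deal consecutive shuffled blocks into the partitions
    out <- vector("list", length(sizes))
    pos <- 1L
    for (p in seq_along(sizes)) {
      out[[p]] <- idx[seq_len(sizes[p]) + pos - 1L]
      pos <- pos + sizes[p]
    }
    out
  }

  parts <- with_seed(seed, {
    if (is.null(labels)) {
      assign_blocks(sample.int(n_samples), sizes)
    } else {
      stopifnot(length(labels) == n_samples)
      parts <- rep(list(integer(0)), n_parts)
      remaining <- sizes
      classes <- sort(unique(labels))
      class_idx <- lapply(classes, function(cl) {
        ci <- which(labels == cl)
        ci[sample.int(length(ci))]
      })
      # per-class quotas by largest remainder against the remaining pool
      for (p in seq_len(n_parts)) {
        remaining <- vapply(class_idx, length, numeric(1))
        quota_real <- remaining * sizes[p] / sum(remaining)
        quota <- pmin(floor(quota_real), remaining)
        short <- sizes[p] - sum(quota)
        if (short > 0) {
          order_rem <- order(quota_real - quota, decreasing = TRUE)
          for (ci in order_rem) {
            if (short == 0) break
            add <- min(short, remaining[ci] - quota[ci])
            quota[ci] <- quota[ci] + add
            short <- short - add
          }
        }
        for (ci in seq_along(class_idx)) {
          if (quota[ci] == 0) next
          take <- seq_len(quota[ci])
          parts[[p]] <- c(parts[[p]], class_idx[[ci]][take])
          class_idx[[ci]] <- class_idx[[ci]][-take]
        }
      }
      lapply(parts, sort)
    }
  })
  stats::setNames(parts, part_names)
}

#' Fit a z-score standardizer on training features
#'
#' Stores per-feature mean and SD estimated on the training partition only;
#' [apply_standardizer()] transforms any partition with those statistics, so
#' no information leaks from held-out data. Constant features are flagged
#' and transformed to zero.
#'
#' @param train_features numeric matrix or data frame.
#' @return Object of class `standardizer` with `mean`, `sd` and
#'   `constant_features`.
#' @export
fit_standardizer <- function(train_features) {
  X <- as.matrix(train_features)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  constant <- colnames(X)[sdv == 0] %||% character(0)
  sdv[sdv == 0] <- 1  # constants map to 0 after centering
  structure(list(mean = mu, sd = sdv, constant_features = constant),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param standardizer a fitted [fit_standardizer()] object.
#' @param features matrix/data frame with the same columns.
#' @return Standardized numeric matrix.
#' @export
apply_standardizer <- function(standardizer, features) {
  if (!inherits(standardizer, "standardizer")) {
    stopf("fit_standardizer() must be called before apply_standardizer()")
  }
  X <- as.matrix(features)
  sweep(sweep(X, 2, standardizer$mean, "-"), 2, standardizer$sd, "/")
}

#' Train an RBF-kernel support vector machine
#'
#' Radial-basis-function SVM (libsvm via e1071) on standardized features.
#' Default hyperparameters: cost `C = 1` and `gamma = 1 / (d * var(X))`
#' (the variance-scaled heuristic). The fitted object exposes continuous
#' decision scores oriented so that larger means class 1, for ROC analysis.
#'
#' @param X standardized feature matrix.
#' @param y binary 0/1 labels, both classes present.
#' @param cost,gamma hyperparameters (`gamma = NULL` for the heuristic).
#' @param seed RNG seed (the fit itself is deterministic).
#' @return Object of class `scar_svm` with `model`, `predict(newX)` ->
#'   labels and `scores(newX)` -> decision values.
#' @export
train_svm_rbf <- function(X, y, cost = 1, gamma = NULL, seed = 0L) {
  X <- as.matrix(X); y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("labels must contain both classes")
  if (is.null(gamma)) {
    v <- stats::var(as.vector(X))
    gamma <- 1 / (ncol(X) * if (v > 0) v else 1)
  }
  fit <- with_seed(seed, e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                                    kernel = "radial", cost = cost,
                                    gamma = gamma, scale = FALSE))
  orient <- if (colnames(attr(stats::predict(fit, X[1, , drop = FALSE],
                                             decision.values = TRUE),
                              "decision.values"))[1] == "0/1") 1 else -1
  structure(list(model = fit, gamma = gamma, cost = cost,
                 predict = function(newX) {
                   as.integer(as.character(stats::predict(fit, as.matrix(newX))))
                 },
                 scores = function(newX) {
                   dv <- attr(stats::predict(fit, as.matrix(newX),
                                             decision.values = TRUE),
                              "decision.values")[, 1]
                   -orient * dv  # larger score = class 1
                 }),
            class = "scar_svm")
}

#' Train a decision-tree classifier
#'
#' CART decision tree (rpart) with the Gini index and unlimited depth
#' (`cp = 0`, `minsplit = 2` by default, overridable). Tree structure is
#' exposed through the fitted `rpart` object (`$model$frame`) for white-box
#' inspection. Trees are insensitive to monotone feature rescaling.
#'
#' @param X feature matrix (standardization is unnecessary for trees).
#' @param y binary 0/1 labels.
#' @param control an [rpart::rpart.control()] list.
#' @param seed RNG seed (surrogate-split tie-breaks).
#' @return Object of class `scar_tree` with `model`, `predict(newX)` and
#'   `scores(newX)` (class-1 probability).
#' @export
train_decision_tree <- function(X, y,
                                control = rpart::rpart.control(cp = 0, minsplit = 2,
                                                               xval = 0),
                                seed = 0L) {
  X <- as.data.frame(X); y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("labels must contain both classes")
  df <- cbind(.y = factor(y, levels = c(0, 1)), X)
  fit <- with_seed(seed, rpart::rpart(.y ~ ., data = df, method = "class",
                                      parms = list(split = "gini"),
                                      control = control))
  structure(list(model = fit,
                 predict = function(newX) {
                   as.integer(as.character(
                     stats::predict(fit, as.data.frame(newX), type = "class")))
                 },
                 scores = function(newX) {
                   stats::predict(fit, as.data.frame(newX), type = "prob")[, "1"]
                 }),
            class = "scar_tree")
}

#' Model specifications for cross-validated ROC analysis
#'
#' Adapters turning the package classifiers into the
#' `(X_train, y_train) -> function(X) -> scores` form consumed by
#' [cv_roc_auc()].
#'
#' @param cost,gamma,control,seed forwarded to the underlying trainer.
#' @return A model-spec function.
#' @rdname model_specs
#' @export
svm_model_spec <- function(cost = 1, gamma = NULL, seed = 0L) {
  function(X_train, y_train) {
    m <- train_svm_rbf(X_train, y_train, cost = cost, gamma = gamma, seed = seed)
    m$scores
  }
}

#' @rdname model_specs
#' @export
tree_model_spec <- function(control = rpart::rpart.control(cp = 0, minsplit = 2,
                                                           xval = 0),
                            seed = 0L) {
  function(X_train, y_train) {
    m <- train_decision_tree(X_train, y_train, control = control, seed = seed)
    m$scores
  }
}

#' Permutation feature importance
#'
#' Importance of a feature = mean decrease in predictive accuracy on the
#' evaluation partition when that feature's column is shuffled, over
#' `n_repeats` seeded shuffles (accuracy is the importance metric).
#'
#' @param model a fitted `scar_svm` / `scar_tree` (anything with
#'   `$predict`).
#' @param X_eval,y_eval evaluation partition.
#' @param n_repeats shuffles per feature (default 10).
#' @param seed shuffle seed.
#' @return Object of class `importance_report`: data frame `importance`
#'   (feature, mean_importance, sd_importance), matrix `repeats`
#'   (n_repeats x features) and `baseline_accuracy`.
#' @export
permutation_importance <- function(model, X_eval, y_eval, n_repeats = 10L,
                                   seed = 0L) {
  X <- as.matrix(X_eval); y <- as.integer(y_eval)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  baseline <- mean(model$predict(X) == y)
  reps <- matrix(NA_real_, n_repeats, ncol(X),
                 dimnames = list(NULL, colnames(X)))
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      for (j in seq_len(ncol(X))) {
        Xp <- X
        Xp[, j] <- Xp[sample.int(nrow(X)), j]
        reps[r, j] <- baseline - mean(model$predict(Xp) == y)
      }
    }
  })
  imp <- data.frame(feature = colnames(X),
                    mean_importance = colMeans(reps),
                    sd_importance = apply(reps, 2, stats::sd),
                    row.names = NULL)
  structure(list(importance = imp[order(-imp$mean_importance), ],
                 repeats = reps, baseline_accuracy = baseline,
                 n_repeats = n_repeats),
            class = "importance_report")
}
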