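test_that("Dice of hard masks matches the set-overlap definition", {
  a <- matrix(0, 6, 6); a[2:3, 2] <- 1
  b <- matrix(0, 6, 6); b[2, 2] <- 1
  expect_equal(dice_per_channel(a, b), 2 * 1 / (2 + 1), tolerance = 1e-6)

  full <- matrix(1, 5, 5)
  expect_equal(dice_per_channel(full, full), 1, tolerance = 1e-6)
  disjoint <- matrix(0, 5, 5); disjoint[1, 1] <- 1
  other <- matrix(0, 5, 5); other[5, 5] <- 1
  expect_lt(dice_per_channel(disjoint, other), 1e-6)
  expect_error(dice_per_channel(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("soft Dice equals the set-cardinality oracle on random hard masks", {
  set.seed(21)
  for (i in 1:25) {
    a <- matrix(rbinom(64, 1, runif(1, 0.2, 0.8)), 8, 8)
    b <- matrix(rbinom(64, 1, runif(1, 0.2, 0.8)), 8, 8)
    if (sum(a) + sum(b) == 0) next
    oracle <- 2 * sum(a & b) / (sum(a) + sum(b))
    expect_equal(dice_per_channel(a, b, epsilon = 1e-12), oracle,
                 tolerance = 1e-9)
  }
})

test_that("weighted Dice loss honours its worked values and bounds", {
  w <- dice_weights()
  expect_equal(w$beta, c(0.15, 0.25, 0.25, 0.35))
  expect_equal(sum(w$beta), 1)

  lab <- matrix(sample(0:3, 64, TRUE), 8, 8)
  y <- array(0, c(8, 8, 4))
  for (c in 1:4) y[, , c] <- (lab == c - 1) * 1
  expect_lt(weighted_dice_loss(y, y, w), 1e-6)

  # total mismatch on four non-empty channels: every l_i = 1
  lab2 <- (lab + 1) %% 4
  y2 <- array(0, c(8, 8, 4))
  for (c in 1:4) y2[, , c] <- (lab2 == c - 1) * 1
  expect_equal(weighted_dice_loss(y, y2, w), 1, tolerance = 1e-5)

  # bounds 0 <= L <= sum(beta) on arbitrary soft inputs
  set.seed(22)
  for (i in 1:20) {
    p <- array(runif(8 * 8 * 4), c(8, 8, 4))
    p <- p / array(rep(apply(p, c(1, 2), sum), 4), c(8, 8, 4))
    L <- weighted_dice_loss(y, p, w)
    expect_gte(L, 0); expect_lte(L, sum(w$beta) + 1e-12)
  }
  expect_error(weighted_dice_loss(y[, , 1:3], y[, , 1:3]), "4 channels")
})

test_that("an empty ground-truth channel matched by an empty prediction costs nothing", {
  y <- array(0, c(4, 4, 4)); y[, , 1] <- 1      # background only, no scar
  expect_lt(weighted_dice_loss(y, y), 1e-6)
})

test_that("inverse-frequency class weights reproduce the worked example", {
  w <- compute_class_weights(c(336, 170))
  expect_identical(w$total, 506)
  expect_equal(round(w$lambda, 3), c(0.753, 1.488))
  expect_equal(compute_class_weights(c(100, 100))$lambda, c(1, 1))
  expect_equal(compute_class_weights(c(150, 50))$lambda, c(2 / 3, 2),
               tolerance = 1e-12)
  expect_error(compute_class_weights(c(10, 0)), "> 0")
})

test_that("weighted cross-entropy matches hand computation and reductions", {
  # perfectly confident correct predictions
  expect_lt(weighted_cross_entropy(c(1, 0, 1), c(1, 0, 1)), 2e-7)

  # unit weights reduce to the mean cross-entropy
  set.seed(23)
  yv <- rbinom(40, 1, 0.5); pv <- runif(40, 0.05, 0.95)
  plain <- mean(-log(ifelse(yv == 1, pv, 1 - pv)))
  expect_equal(weighted_cross_entropy(yv, pv, c(1, 1)), plain,
               tolerance = 1e-12)

  # hand substitution: N = 2, classes (1, 0), p_true = (0.9, 0.8), lambda (0.5, 2)
  v <- weighted_cross_entropy(c(1, 0), c(0.9, 0.2), c(0.5, 2))
  expect_equal(v, -(1 / 2) * (2 * log(0.9) + 0.5 * log(0.8)), tolerance = 1e-9)
  expect_equal(round(v, 4), 0.1611)
  expect_error(weighted_cross_entropy(c(1, 0), c(1.2, 0.5)), "\\[0, 1\\]")
})

test_that("weighted cross-entropy equals a per-sample loop oracle", {
  set.seed(24)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    yv <- rbinom(n, 1, 0.4)
    pv <- runif(n)
    lam <- runif(2, 0.2, 3)
    acc <- 0
    for (i in seq_len(n)) {
      p_true <- if (yv[i] == 1) pv[i] else 1 - pv[i]
      p_true <- min(max(p_true, 1e-7), 1 - 1e-7)
      acc <- acc + lam[yv[i] + 1] * (-log(p_true))
    }
    expect_equal(weighted_cross_entropy(yv, pv, lam), acc / n,
                 tolerance = 1e-10)
  }
})

test_that("classification report computes the confusion-derived metrics", {
  r <- classification_report(c(0, 0, 0, 1), c(0, 0, 1, 1))
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 1)
  expect_equal(r$f1, 2 / 3, tolerance = 1e-9)
  expect_equal(r$accuracy, 0.75)
  expect_identical(unname(r$confusion["1", "1"]), 1L)

  perfect <- classification_report(c(0, 1, 1), c(0, 1, 1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$confusion["0", "1"]), 0L)

  allneg <- classification_report(c(0, 1, 1), c(0, 0, 0))
  expect_equal(allneg$precision, 0)
  expect_true("precision" %in% allneg$zero_division)
  expect_error(classification_report(c(0, 2), c(0, 1)), "binary")
})

test_that("F1 survives duplication and accuracy survives permutation", {
  set.seed(25)
  y <- rbinom(30, 1, 0.5); p <- rbinom(30, 1, 0.5)
  base <- classification_report(y, p)
  dup <- classification_report(c(y, y), c(p, p))
  expect_equal(dup$f1, base$f1)
  ord <- sample(30)
  expect_equal(classification_report(y[ord], p[ord])$accuracy, base$accuracy)
})

test_that("cross-validated ROC separates separable data and nulls out permuted labels", {
  set.seed(26)
  n <- 400
  labels <- rep(c(0, 1), each = n / 2)
  X <- cbind(rnorm(n, mean = 8 * labels), rnorm(n))
  spec <- svm_model_spec(seed = 1)
  cv <- cv_roc_auc(X, labels, spec, n_folds = 10, seed = 2)
  expect_length(cv$fold_auc, 10)
  expect_gt(cv$mean_auc, 0.99)

  perm <- sample(labels)
  cv0 <- cv_roc_auc(X, perm, spec, n_folds = 10, seed = 3)
  expect_lt(abs(cv0$mean_auc - 0.5), 0.1)
  expect_error(cv_roc_auc(X, rep(1, n), spec), "both classes")
})
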