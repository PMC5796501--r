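# Labels, classifiers, cross-validation, metrics.

test_that("binary labels follow the >= threshold rule", {
  roster <- data.frame(subject_id = letters[1:4], ahi = c(4.9, 5.0, 14.99, 30))
  expect_equal(as.character(make_binary_labels(roster, 5)), c("0", "1", "1", "1"))
  # reported group-mean AHI values at threshold 15
  r2 <- data.frame(subject_id = 1:4, ahi = c(1.3, 9.1, 22.1, 57.5))
  expect_equal(as.character(make_binary_labels(r2, 15)), c("0", "0", "1", "1"))
  expect_error(make_binary_labels(r2, 0), "> 0")
})

test_that("all classifier kinds separate wide-margin data and emit probabilities", {
  set.seed(10)
  n <- 60
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(stats::rnorm(n * 3), n, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  X[y == "b", 1] <- X[y == "b", 1] + 12
  for (kind in c("logistic", "svm", "mlp")) {
    m <- train_classifier(classifier_spec(kind), X, y, seed = 3)
    expect_equal(mean(predict(m, X) == y), 1, info = kind)
    pr <- predict(m, X, type = "prob")
    expect_lt(max(abs(rowSums(pr) - 1)), 1e-6)
  }
  expect_error(train_classifier(classifier_spec("svm"), cbind(c(1, NA)), y[1:2]),
               "non-finite|classes")
})

test_that("probability rows sum to one for random multiclass subjects", {
  set.seed(12)
  y <- factor(rep(c("w", "x", "y", "z"), each = 25))
  X <- matrix(stats::rnorm(100 * 6), 100, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  for (kind in c("logistic", "svm", "mlp")) {
    m <- train_classifier(classifier_spec(kind), X, y, seed = 5)
    pr <- predict(m, X, type = "prob")
    expect_equal(dim(pr), c(100L, 4L))
    expect_lt(max(abs(rowSums(pr) - 1)), 1e-6)
  }
})

test_that("linear SVM recovers a planted separator", {
  set.seed(6)
  X <- matrix(stats::rnorm(200 * 2), 200, 2)
  y <- ifelse(2 * X[, 1] - 3 * X[, 2] > 0, 1, -1)
  keep <- abs(2 * X[, 1] - 3 * X[, 2]) > 0.5   # margin
  fit <- sdbscreen:::.svm_linear_fit(X[keep, ], y[keep])
  expect_gt(fit$w[1], 0)
  expect_lt(fit$w[2], 0)
  expect_gt(abs(fit$w[2] / fit$w[1]) / (3 / 2), 0.8)
})

test_that("MLP training is deterministic given a seed", {
  set.seed(1)
  y <- factor(rep(c("a", "b"), each = 20))
  X <- matrix(stats::rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
  m1 <- train_classifier(classifier_spec("mlp", epochs = 30L), X, y, seed = 42)
  m2 <- train_classifier(classifier_spec("mlp", epochs = 30L), X, y, seed = 42)
  expect_identical(predict(m1, X, type = "prob"), predict(m2, X, type = "prob"))
})

test_that("cross-validation: separable data, fold geometry, duplication", {
  set.seed(8)
  y <- factor(rep(c("n", "mi", "mo", "s"), each = 20))
  X <- matrix(stats::rnorm(80 * 4), 80, 4, dimnames = list(NULL, paste0("f", 1:4)))
  X[, 1] <- X[, 1] + as.integer(y) * 15
  rep1 <- crossval_evaluate(X, y, classifier_spec("logistic"), seed = 2)
  expect_equal(rep1$accuracy, 1)
  expect_true(all(rep1$confusion[row(rep1$confusion) != col(rep1$confusion)] == 0))

  # fold disjointness and 9:1 sizing (+-1 per class) across seeds
  for (sd in 1:5) {
    rep2 <- crossval_evaluate(X, y, classifier_spec("logistic"), seed = sd)
    expect_length(rep2$folds, 80L)
    sizes <- table(rep2$folds)
    expect_true(all(abs(sizes - 8) <= 1))
    per_class <- table(rep2$folds, y)
    expect_true(all(per_class == 2))   # stratified: 2 of each class per fold
  }

  # duplicating every subject under fixed folds leaves accuracy unchanged
  fold <- sdbscreen:::.stratified_folds(y, 10L, 3L)
  base <- crossval_evaluate(X, y, classifier_spec("logistic"),
                            fold_assignment = fold, seed = 3)
  dup <- crossval_evaluate(rbind(X, X), unlist(list(y, y)),
                           classifier_spec("logistic"),
                           fold_assignment = c(fold, fold), seed = 3)
  expect_equal(dup$accuracy, base$accuracy)

  few <- c(1:3, 21:23, 41:43, 61:63)   # 3 subjects per class < 10 folds
  expect_error(crossval_evaluate(X[few, ], y[few],
                                 classifier_spec("logistic")), "smallest class")
})

test_that("permuted labels drop cross-validated accuracy to chance", {
  set.seed(30)
  y <- factor(rep(c("a", "b", "c", "d"), each = 10))
  X <- matrix(stats::rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("f", 1:8)))
  accs <- vapply(1:6, function(sd) {
    yp <- sample(y)
    crossval_evaluate(X, yp, classifier_spec("logistic"), seed = sd)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.12)
})

test_that("compute_metrics matches hand arithmetic", {
  # perfect predictions
  cm <- diag(c(3, 4, 5))
  rownames(cm) <- colnames(cm) <- c("a", "b", "c")
  perfect <- compute_metrics(cm)
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$sensitivity == 1))
  expect_true(all(perfect$per_class$specificity == 1))

  # hand-computed binary confusion
  cm2 <- matrix(c(3, 1, 2, 4), 2, byrow = TRUE,
                dimnames = list(c("0", "1"), c("0", "1")))
  m2 <- compute_metrics(cm2)
  expect_equal(m2$accuracy, 0.7)
  expect_equal(m2$per_class$sensitivity[2], 4 / 6)
  expect_equal(m2$per_class$specificity[2], 3 / 4)

  # AUC: perfect = 1, anti-perfect = 0
  lab <- factor(c("0", "0", "1", "1"))
  sc_good <- cbind("0" = c(.9, .8, .1, .2), "1" = c(.1, .2, .9, .8))
  sc_bad <- sc_good[, c(2, 1)]; colnames(sc_bad) <- c("0", "1")
  cm3 <- matrix(c(2, 0, 0, 2), 2, dimnames = list(c("0", "1"), c("0", "1")))
  expect_equal(compute_metrics(cm3, sc_good, lab)$per_class$auc, c(1, 1))
  expect_equal(compute_metrics(cm3, sc_bad, lab)$per_class$auc, c(0, 0))

  # class with zero positives reports NA, not 0
  cm4 <- matrix(c(5, 0, 0, 0), 2, dimnames = list(c("0", "1"), c("0", "1")))
  expect_true(is.na(compute_metrics(cm4)$per_class$sensitivity[2]))
})
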