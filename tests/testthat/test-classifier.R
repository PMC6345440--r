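# Dataset splitting, training, prediction, and evaluation statistics.

test_that("stratified split reproduces the 70/15/15 arithmetic", {
  labels <- rep(tissue_classes(), each = 100L)
  sp <- split_dataset(labels, seed = 1L)
  expect_equal(lengths(sp)[c("train", "validation", "test")],
               c(train = 630L, validation = 135L, test = 135L))
  for (cl in tissue_classes()) {
    expect_equal(sum(labels[sp$train] == cl), 70L)
    expect_equal(sum(labels[sp$test] == cl), 15L)
  }
  expect_equal(sort(unlist(sp)), seq_along(labels), ignore_attr = TRUE)
  expect_identical(sp, split_dataset(labels, seed = 1L))
  expect_error(split_dataset(labels, split = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(split_dataset(c("ADI", "ADI", "BACK"), seed = 1L),
               "at least 3")
})

test_that("training rejects degenerate inputs", {
  expect_error(train_tissue_classifier(list(), character(0)), "empty")
  p <- generate_patch("LYM", texture_params(seed = 1L))
  expect_error(train_tissue_classifier(list(p, p), c("LYM", "LYM")),
               "degenerate label space")
})

test_that("training improves on the untrained network and is logged", {
  fx <- fixture_model()
  log <- fx$model$log
  expect_equal(log$epoch[1], 0L)
  expect_gte(log$val_accuracy[nrow(log)], log$val_accuracy[1])
  expect_lt(log$loss[nrow(log)], log$loss[1])
})

test_that("softmax activations obey the probability contract", {
  fx <- fixture_model()
  patch <- generate_patch("BACK", texture_params(seed = 999L))
  a <- predict(fx$model, patch)
  expect_length(a, 9L)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(sum(a), 1, tolerance = 1e-6)
  expect_equal(names(which.max(a)), "BACK")
  expect_identical(a, predict(fx$model, patch))
  expect_error(predict(fx$model, matrix(1, 3, 3)), "corrupt image")
})

test_that("held-out accuracy on synthetic textures is high", {
  fx <- fixture_model()
  ev <- evaluate_classifier(fx$model, fx$data$patches[fx$split$test],
                            fx$data$labels[fx$split$test])
  expect_gte(ev$accuracy, 0.90)
  expect_equal(sum(ev$confusion), length(fx$split$test))
})

test_that("flip augmentation leaves predictions essentially invariant", {
  fx <- fixture_model()
  idx <- fx$split$test
  agree <- vapply(idx[seq_len(min(30, length(idx)))], function(i) {
    x <- fx$data$patches[[i]]
    xf <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
    which.max(predict(fx$model, x)) == which.max(predict(fx$model, xf))
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("confusion counting matches a brute-force oracle", {
  truth <- c("A", "A", "B")
  pred <- c("A", "B", "B")
  cm <- confusion_matrix(truth, pred, classes = c("A", "B"))
  expect_equal(attr(cm, "accuracy"), 2 / 3)
  expect_equal(as.vector(cm), c(1L, 0L, 1L, 1L))

  set.seed(31)
  classes <- tissue_classes()
  tr <- sample(classes, 500, replace = TRUE)
  pr <- sample(classes, 500, replace = TRUE)
  cm2 <- confusion_matrix(tr, pr)
  brute <- matrix(0L, 9, 9, dimnames = list(classes, classes))
  for (i in seq_along(tr)) {
    brute[tr[i], pr[i]] <- brute[tr[i], pr[i]] + 1L
  }
  expect_equal(unclass(cm2), brute, ignore_attr = TRUE)
  expect_equal(rowSums(cm2), table(factor(tr, classes)) + 0,
               ignore_attr = TRUE)
  expect_error(confusion_matrix(c("A", NA), c("A", "A"), c("A", "B")),
               "unlabeled")
})

test_that("uniform-random prediction gives chance-level accuracy", {
  set.seed(77)
  n <- 9000L
  truth <- rep(tissue_classes(), each = n / 9L)
  pred <- sample(tissue_classes(), n, replace = TRUE)
  acc <- attr(confusion_matrix(truth, pred), "accuracy")
  expect_gte(acc, 0.09)
  expect_lte(acc, 0.13)
})

test_that("k-fold ROC statistics behave at the oracle and null extremes", {
  fx <- fixture_model()
  ds <- fx$data
  res <- kfold_roc_stats(fx$model, ds$patches, ds$labels, k = 5L, seed = 1L)
  expect_true(all(res$per_class$auc_median > 0.95))
  expect_true(all(res$per_class$auc_q05 <= res$per_class$auc_median))
  expect_true(all(res$per_class$auc_q95 >= res$per_class$auc_median))
  expect_true(all(unlist(res$per_class[-1]) >= 0, na.rm = TRUE))
  expect_true(all(unlist(res$per_class[-1]) <= 1, na.rm = TRUE))

  # labels shuffled: activations carry no information, AUC near 1/2
  set.seed(5)
  shuffled <- sample(ds$labels)
  res0 <- kfold_roc_stats(fx$model, ds$patches, shuffled, k = 3L, seed = 2L)
  expect_true(all(res0$per_class$auc_median > 0.3 &
                    res0$per_class$auc_median < 0.7))

  expect_error(kfold_roc_stats(fx$model, ds$patches, ds$labels, k = 1L),
               "at least 2")
  expect_error(kfold_roc_stats(fx$model, ds$patches, ds$labels, k = 100L),
               "at least k")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:5) {
    sc <- stats::rnorm(60)
    lb <- stats::rbinom(60, 1, 0.4)
    if (length(unique(lb)) < 2) next
    ours <- deepstroma:::auc_rank(sc, lb)
    ref <- as.numeric(suppressMessages(pROC::auc(lb, sc,
                                                 direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("classifiers round-trip through save/load", {
  fx <- fixture_model()
  path <- tempfile(fileext = ".rds")
  save_classifier(fx$model, path)
  m2 <- load_classifier(path)
  patch <- generate_patch("MUS", texture_params(seed = 303L))
  expect_identical(predict(fx$model, patch), predict(m2, patch))
  expect_true(file.exists(paste0(path, ".json")))
  unlink(c(path, paste0(path, ".json")))
})
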