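test_that("confusion counting is exact, order-invariant and validates labels", {
  act <- rep(c("mild", "moderate", "severe", "normal"), c(3, 2, 2, 3))
  cm <- confusion(act, act)
  expect_equal(unname(diag(cm$counts)), c(3, 2, 2, 3))
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0)
  expect_equal(unname(cm$fn_diagonal), rep(0L, 4))
  perm <- sample(seq_along(act))
  expect_identical(confusion(act[perm], act[perm])$counts, cm$counts)
  expect_error(confusion(c("mild", "odd"), c("mild", "mild")),
               class = "kerato3d_config_error")
  # the two TP conventions diverge exactly on off-diagonal keratoconus cells
  cm2 <- confusion(c("moderate", "moderate", "moderate"),
                   c("moderate", "severe", "normal"))
  expect_equal(unname(cm2$tp_diagonal["moderate"]), 1)
  expect_equal(unname(cm2$tp_row_nonnormal["moderate"]), 2)
})

test_that("metric formulas are literal, with textbook variants alongside", {
  m <- class_metrics(TP = 254, TN = 96, FP = 4, FN = 4)
  expect_equal(m$sensitivity, 100 * 254 / 258)
  expect_equal(m$specificity, 96)
  expect_equal(m$accuracy, 100 * 350 / 358)
  expect_equal(m$sensitivity_recall, 100 * 254 / 258)
  expect_equal(m$specificity_tnr, 96)
  perfect <- class_metrics(TP = 5, TN = 7, FP = 0, FN = 0)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(100, 100, 100))
  expect_equal(class_metrics(TP = 0, TN = 1, FP = 3, FN = 1)$sensitivity, 0)
  expect_error(class_metrics(TP = 0, TN = 0, FP = 0, FN = 0),
               class = "kerato3d_undefined_metric")
})

test_that("stratified k-fold covers every case once with balanced folds", {
  labels <- rep(c("a", "b"), c(23, 37))
  fold <- kfold_split(labels, 5, seed = 2)
  expect_equal(length(fold), 60)
  expect_true(all(table(fold) %in% c(12, 12)))
  for (cl in c("a", "b"))
    expect_lte(diff(range(table(factor(fold[labels == cl], levels = 1:5)))), 1)
  expect_identical(kfold_split(labels, 5, seed = 2), fold)
  expect_error(kfold_split(labels, 30, seed = 1), class = "kerato3d_config_error")
  # leave-one-out on a single class: n singleton folds
  loo <- kfold_split(rep("x", 7), 7, seed = 1)
  expect_equal(sort(loo), 1:7)
})

test_that("k-fold accuracy equals plain accuracy for a training-independent classifier", {
  set.seed(8)
  x <- runif(40)
  labels <- ifelse(x > 0.6, "mild", "normal")
  labels[c(3, 11)] <- "mild"  # inject disagreement with the fixed rule
  rule <- function(z) ifelse(z > 0.6, "mild", "normal")
  res <- kfold_evaluate(x, labels, k = 5, seed = 4,
                        fit = function(xt, lt) NULL,
                        predict_fn = function(f, xt) rule(xt))
  plain <- 100 * mean(rule(x) == labels)
  expect_equal(res$mean_accuracy, plain, tolerance = 1e-9)
  expect_equal(sum(res$per_fold$n_test), 40)
})

test_that("the Pearson formula matches its covariance oracle and affine invariance", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  oracle <- sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sd(x) * sd(y))
  expect_equal(pearson_r(x, y), oracle, tolerance = 1e-12)
  expect_equal(pearson_r(x, y), cor(x, y), tolerance = 1e-12)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -2 * x + 5), -1)
  set.seed(6)
  a <- rnorm(50); b <- a + rnorm(50)
  expect_equal(pearson_r(3 * a + 1, b), pearson_r(a, b), tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), class = "kerato3d_undefined_metric")
  expect_error(pearson_r(1:2, 1:2), class = "kerato3d_config_error")
})

test_that("Bland-Altman limits behave as 1.96-SD limits of agreement", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(ba0$mean_diff, ba0$lower_limit, ba0$upper_limit), c(0, 0, 0))
  bac <- bland_altman(c(4, 5, 6), c(1, 2, 3))
  expect_equal(c(bac$mean_diff, bac$sd_diff), c(3, 0))
  expect_equal(c(bac$lower_limit, bac$upper_limit), c(3, 3))
  set.seed(14)
  a <- rnorm(500, 50, 5); b <- a + rnorm(500, 0.5, 1)
  ba <- bland_altman(b, a)
  inside <- mean(ba$table$diff >= ba$lower_limit & ba$table$diff <= ba$upper_limit)
  expect_gte(inside, 0.93)
  expect_equal(nrow(ba$table), 500)
  expect_error(bland_altman(1:5, 1:4), class = "kerato3d_config_error")
})
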