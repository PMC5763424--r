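metric_value <- function(m, name) m$value[m$metric == name]

test_that("confusion metrics match direct arithmetic", {
  perfect <- classification_metrics(list(tp = 1, fp = 0, tn = 1, fn = 0))
  expect_equal(perfect$value, rep(1, 4))
  expect_true(all(perfect$defined))

  m <- classification_metrics(list(tp = 50, fp = 10, tn = 30, fn = 10))
  expect_equal(metric_value(m, "acc"), 0.8)
  expect_equal(metric_value(m, "precision"), 50 / 60)
  expect_equal(metric_value(m, "recall"), 50 / 60)
  expect_equal(metric_value(m, "specificity"), 0.75)
})

test_that("zero denominators are flagged undefined, never silent NaN", {
  m <- classification_metrics(list(tp = 0, fp = 0, tn = 1, fn = 1))
  expect_equal(metric_value(m, "acc"), 0.5)
  expect_true(is.na(metric_value(m, "precision")))
  expect_false(m$defined[m$metric == "precision"])
  expect_match(m$reason[m$metric == "precision"], "TP\\+FP")
  expect_equal(metric_value(m, "recall"), 0)
  expect_equal(metric_value(m, "specificity"), 1)
  expect_false(any(is.nan(m$value)))
  expect_error(classification_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)),
               class = "mirboost_input_error")
})

test_that("confusion counts tally the four cells", {
  cc <- confusion_counts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(cc, list(tp = 2L, fp = 1L, tn = 1L, fn = 1L))
})

test_that("folds partition the data with near-equal sizes", {
  f10 <- vfold_split(rep(0:1, 5), v = 10, seed = 1)
  expect_setequal(f10, 1:10)  # ten singletons
  f12 <- vfold_split(rep(0:1, 6), v = 10, seed = 1)
  sizes <- tabulate(f12, 10)
  expect_equal(sort(sizes, decreasing = TRUE), c(2, 2, rep(1, 8)))
  expect_error(vfold_split(1:5, v = 10), class = "mirboost_input_error")
  expect_error(vfold_split(1:5, v = 1), class = "mirboost_input_error")
})

test_that("splits are stratified and reproducible", {
  labels <- rep(c(0, 1), c(80, 40))
  f <- vfold_split(labels, v = 10, seed = 42)
  expect_identical(f, vfold_split(labels, v = 10, seed = 42))
  for (k in 1:10) {
    expect_equal(sum(labels[f == k] == 1), 4)
    expect_equal(sum(labels[f == k] == 0), 8)
  }
  # every record tested exactly once
  expect_equal(sort(unlist(lapply(1:10, function(k) which(f == k)))),
               seq_along(labels))
})

test_that("feature scaling is fit on the training portion only", {
  toy <- toy_gaussians(n_per = 25)
  fit <- train_weak(toy$x, ifelse(toy$y == 1, 1, -1),
                    config = small_config(2), seed = 1)
  expect_equal(fit$center, colMeans(toy$x))
  expect_equal(fit$scale, apply(toy$x, 2, sd))
  # learners inside a CV fold therefore never see held-out rows
})

test_that("cross-validation averages the stored fold metrics", {
  toy <- toy_gaussians(n_per = 30)
  cv <- cross_validate(toy$x, toy$y, v = 4, rounds = 2,
                       config = small_config(2), seed = 12)
  expect_identical(nrow(cv$folds), 4L)
  expect_equal(cv$summary$acc, mean(cv$folds$acc, na.rm = TRUE))
  expect_equal(cv$summary$recall, mean(cv$folds$recall, na.rm = TRUE))
  expect_equal(sum(cv$folds$n_test), nrow(toy$x))
  # separable clouds: the sanity inversion - training error near zero but
  # held-out accuracy still high, and everything in [0, 1]
  expect_true(all(cv$folds$acc >= 0 & cv$folds$acc <= 1))
  expect_gt(cv$summary$acc, 0.8)
  gl <- glance(cv)
  expect_identical(gl$v, 4)
  td <- tidy(cv)
  expect_identical(nrow(td), 16L)
})

test_that("a memorizing model is perfect when train equals test", {
  toy <- toy_gaussians(n_per = 15)
  fit <- adaboost_fit(toy$x, toy$y, rounds = 3, config = small_config(2),
                      seed = 2)
  expect_equal(mean(predict(fit, toy$x)$.pred == as.character(toy$y)), 1)
})

test_that("hand-worked two-fold example with a constant classifier", {
  # folds {1,2} and {3,4}; truth 1,0 in each fold; classifier always says 1
  truth <- c(1, 0, 1, 0)
  pred <- rep(1, 4)
  per_fold <- lapply(list(1:2, 3:4), function(idx)
    classification_metrics(confusion_counts(truth[idx], pred[idx])))
  accs <- vapply(per_fold, function(m) metric_value(m, "acc"), 0)
  expect_equal(accs, c(0.5, 0.5))
  specs <- vapply(per_fold, function(m) metric_value(m, "specificity"), 0)
  expect_equal(specs, c(0, 0))
  recalls <- vapply(per_fold, function(m) metric_value(m, "recall"), 0)
  expect_equal(mean(recalls), 1)
})

test_that("per-species accuracy reports class, pooled and macro rows", {
  truth <- c("a", "a", "b", "b", "b", "c")
  est <- c("a", "b", "b", "b", "a", "c")
  acc <- species_accuracy(truth, est)
  expect_equal(acc$accuracy[acc$class == "a"], 0.5)
  expect_equal(acc$accuracy[acc$class == "b"], 2 / 3)
  expect_equal(acc$accuracy[acc$class == "c"], 1)
  expect_equal(acc$accuracy[acc$class == "total"], 4 / 6)
  expect_equal(acc$accuracy[acc$class == "macro_mean"], mean(c(0.5, 2 / 3, 1)))
})

test_that("the metric-curve plot builds", {
  toy <- toy_gaussians(n_per = 20)
  cv <- cross_validate(toy$x, toy$y, v = 3, rounds = 2,
                       config = small_config(2), seed = 3)
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(length(built$data), 0)
})
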