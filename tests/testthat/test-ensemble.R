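boost_toy <- function(rounds = 4, seed = 21) {
  toy <- toy_gaussians(n_per = 25)
  fit <- adaboost_fit(toy$x, toy$y, rounds = rounds,
                      config = small_config(2), seed = seed)
  list(fit = fit, toy = toy)
}

test_that("sample weights stay on the simplex after every round", {
  res <- boost_toy()
  for (w in res$fit$weight_trace) {
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("stored alphas follow the clamped error formula", {
  res <- boost_toy()
  expect_equal(res$fit$alphas, adaboost_alpha(res$fit$errors))
  expect_true(all(res$fit$alphas > 0))
})

test_that("a perfect weak learner gets a finite capped alpha and is reproduced", {
  # four points, trivially separable in one dimension
  x <- matrix(c(-2, -1, 1, 2, 0, 0, 0, 0), ncol = 2)
  fit <- adaboost_fit(x, c(0, 0, 1, 1), rounds = 1,
                      config = small_config(2), seed = 4)
  expect_true(is.finite(fit$alphas[1]))
  expect_lte(fit$alphas[1], adaboost_alpha(0))
  pred <- predict(fit, x)
  expect_identical(pred$.pred, c("0", "0", "1", "1"))
})

test_that("boosting does not do worse than its first weak learner on training data", {
  res <- boost_toy(rounds = 6)
  ym <- ifelse(res$toy$y == 1, 1, -1)
  h1 <- ifelse(nn_forward(res$fit$learners[[1]], res$toy$x) > 0, 1, -1)
  err_first <- mean(h1 != ym)
  pred <- predict(res$fit, res$toy$x)
  err_ens <- mean(pred$.pred != as.character(res$toy$y))
  expect_lte(err_ens, err_first)
})

test_that("the ensemble score is the brute-force weighted vote", {
  res <- boost_toy(rounds = 5)
  x <- res$toy$x
  manual <- rep(0, nrow(x))
  for (t in seq_along(res$fit$learners)) {
    h <- ifelse(nn_forward(res$fit$learners[[t]], x) > 0, 1, -1)
    manual <- manual + res$fit$alphas[t] * h
  }
  expect_equal(predict(res$fit, x)$.score, manual)
})

test_that("single-learner ensembles and score ties behave as specified", {
  single <- manual_ensemble(list(constant_weak(2)), alphas = 1)
  p <- predict(single, matrix(rnorm(10), 5))
  expect_identical(p$.pred, rep("1", 5))
  # two equal-alpha learners voting in opposite directions: score 0 -> negative
  tied <- manual_ensemble(list(constant_weak(2), constant_weak(-2)),
                          alphas = c(0.7, 0.7))
  pt <- predict(tied, matrix(rnorm(10), 5))
  expect_equal(pt$.score, rep(0, 5))
  expect_identical(pt$.pred, rep("0", 5))
  # untrained ensemble rejected
  empty <- manual_ensemble(list(constant_weak(1)), alphas = 1)
  empty$learners <- list()
  expect_error(predict(empty, matrix(0, 1, 2)), class = "mirboost_input_error")
})

test_that("fitting is deterministic and survives a JSON round trip", {
  res1 <- boost_toy(seed = 77)
  res2 <- boost_toy(seed = 77)
  expect_identical(res1$fit$alphas, res2$fit$alphas)
  expect_identical(predict(res1$fit, res1$toy$x), predict(res2$fit, res2$toy$x))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(res1$fit, path)
  back <- read_model(path)
  expect_equal(predict(back, res1$toy$x), predict(res1$fit, res1$toy$x))
  expect_identical(back$class_map, res1$fit$class_map)
})

mc_gaussians <- function(n_per = 20, seed = 55) {
  withr::with_seed(seed, {
    centers <- list(c(0, 0), c(4, 0), c(0, 4))
    x <- do.call(rbind, lapply(centers, function(cc)
      cbind(rnorm(n_per) + cc[1], rnorm(n_per) + cc[2])))
    list(x = x, y = rep(c("a", "b", "c"), each = n_per))
  })
}

test_that("one-vs-rest bank recovers well-separated classes above chance", {
  d <- mc_gaussians()
  fit <- multiclass_fit(d$x, d$y, rounds = 3, config = small_config(2),
                        seed = 9)
  pred <- predict(fit, d$x)
  acc <- species_accuracy(d$y, pred$.pred)
  per_class <- acc[acc$class %in% c("a", "b", "c"), ]
  expect_true(all(per_class$accuracy > 1 / 3))
})

test_that("multi-class argmax equals a brute-force max over stored scores", {
  d <- mc_gaussians(n_per = 12)
  fit <- multiclass_fit(d$x, d$y, rounds = 2, config = small_config(2),
                        seed = 10)
  pred <- predict(fit, d$x)
  scores <- as.matrix(pred[, paste0(".score_", fit$classes)])
  manual <- apply(scores, 1, function(r) fit$classes[which.max(r)])
  expect_identical(pred$.pred, unname(manual))
})

test_that("two-class species labels reduce to the binary decision", {
  toy <- toy_gaussians(n_per = 20)
  y <- ifelse(toy$y == 1, "real", "pseudo")
  mc <- multiclass_fit(toy$x, y, rounds = 3, config = small_config(2), seed = 6)
  bin <- adaboost_fit(toy$x, toy$y, rounds = 3, config = small_config(2), seed = 6)
  pred_mc <- predict(mc, toy$x)$.pred
  pred_bin <- ifelse(predict(bin, toy$x)$.pred == "1", "real", "pseudo")
  # both paths solve the same separable problem
  expect_gt(mean(pred_mc == y), 0.9)
  expect_gt(mean(pred_mc == pred_bin), 0.9)
  expect_error(multiclass_fit(toy$x, rep("a", nrow(toy$x))),
               class = "mirboost_input_error")
})

test_that("tidy and glance summarize rounds and ensembles", {
  res <- boost_toy(rounds = 3)
  td <- tidy(res$fit)
  expect_identical(nrow(td), res$fit$n_rounds)
  expect_named(td, c("round", "error", "alpha", "weak_mse", "weak_epochs"))
  gl <- glance(res$fit)
  expect_identical(gl$n_hidden, 3L)
  expect_equal(gl$total_alpha, sum(res$fit$alphas))
})
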