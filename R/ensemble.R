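EPSILON_CLAMP <- 1e-10

#' Classifier weight from a weighted error
#'
#' The discrete-AdaBoost weight `alpha = 0.5 * log((1 - eps) / eps)`, with
#' `eps` clamped to `[1e-10, 1 - 1e-10]` so a perfect (or perfectly wrong)
#' weak learner still gets a finite weight.
#'
#' @param epsilon Weighted 0/1 error(s) of a weak learner, in `[0, 1]`.
#' @return Numeric vector of classifier weights.
#' @examples
#' adaboost_alpha(c(0.1, 0.25, 0.49))
#' @export
adaboost_alpha <- function(epsilon) {
  stopifnot(all(epsilon >= 0 & epsilon <= 1))
  eps <- pmin(pmax(epsilon, EPSILON_CLAMP), 1 - EPSILON_CLAMP)
  0.5 * log((1 - eps) / eps)
}

resolve_xy <- function(x) {
  # accept either a raw numeric matrix or a hairpin_features() tibble
  if (is.data.frame(x)) feature_matrix(x) else {
    x <- as.matrix(x); storage.mode(x) <- "double"; x
  }
}

encode_binary <- function(y) {
  lv <- sort(unique(as.character(y)))
  if (length(lv) > 2) {
    rlang::abort("binary boosting needs at most two classes",
                 class = "mirboost_input_error")
  }
  if (all(lv %in% c("0", "1"))) lv <- c("0", "1")  # pseudo = 0, real = 1
  ym <- ifelse(as.character(y) == lv[length(lv)], 1, -1)
  list(ym = ym, class_map = c(negative = lv[1],
                              positive = lv[length(lv)]))
}

#' Fit a BP-AdaBoost binary classifier
#'
#' Discrete AdaBoost over backpropagation network weak learners. Sample
#' weights start uniform at `1/N`. Each round draws a weighted bootstrap of
#' the training data, trains a fresh [train_weak()] network on it, thresholds
#' its score at zero to get `{-1, +1}` hypotheses, and measures the weighted
#' error `eps_t` on the full training set. The classifier weight is
#' `alpha_t = 0.5 * log((1 - eps_t) / eps_t)` with `eps_t` clamped to
#' `[1e-10, 1 - 1e-10]`; sample weights are updated by
#' `w_i <- w_i * exp(-alpha_t * y_i * h_t(x_i))` and renormalized, so correct
#' samples lose weight and errors gain it. A round with `eps_t >= 0.5` is
#' reinitialized once with fresh randomness; if it still fails, boosting
#' stops early with the learners collected so far.
#'
#' @param x Feature matrix or [hairpin_features()] tibble.
#' @param y Binary labels (0 = pseudo, 1 = real; any two-level coding works).
#' @param rounds Number of boosting rounds (weak learners) to attempt.
#' @param config A [network_config()]; `NULL` derives the default 98-12-1
#'   architecture from `ncol(x)`.
#' @param seed Integer seed controlling every stochastic step (bootstraps and
#'   weight initializations).
#' @return A `bp_adaboost` object with elements `learners`, `alphas`,
#'   `errors`, `class_map`, `threshold`, `config`, `seed`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60 * 4), 60)
#' y <- as.integer(x[, 1] + x[, 2] > 0)
#' fit <- adaboost_fit(x, y, rounds = 3, config = network_config(4, 3), seed = 7)
#' glance(fit)
#' @export
adaboost_fit <- function(x, y, rounds = 10, config = NULL, seed = 1) {
  x <- resolve_xy(x)
  if (length(y) != nrow(x)) {
    rlang::abort("length(y) must equal nrow(x)", class = "mirboost_input_error")
  }
  if (length(unique(y)) < 2) {
    rlang::abort("training data must contain both classes",
                 class = "mirboost_input_error")
  }
  stopifnot(rounds >= 1)
  if (is.null(config)) config <- network_config(n_inputs = ncol(x))
  enc <- encode_binary(y)
  ym <- enc$ym
  n <- nrow(x)

  fit_rounds <- function() {
    w <- rep(1 / n, n)
    learners <- list(); alphas <- numeric(0); errors <- numeric(0)
    weight_trace <- list()
    for (t in seq_len(rounds)) {
      attempt <- 0L
      repeat {
        attempt <- attempt + 1L
        idx <- sample.int(n, n, replace = TRUE, prob = w)
        learner <- train_weak(x[idx, , drop = FALSE], ym[idx], config = config)
        h <- ifelse(nn_forward(learner, x) > 0, 1, -1)
        eps <- sum(w[h != ym])
        if (eps < 0.5 || attempt >= 2L) break
      }
      if (eps >= 0.5) {
        if (!length(learners)) {
          rlang::abort(sprintf(
            "boosting failed at round %d: no weak learner beat chance", t),
            class = "mirboost_fit_error")
        }
        break  # early stop, keep the rounds collected so far
      }
      alpha <- adaboost_alpha(eps)
      w <- w * exp(-alpha * ym * h)
      w <- w / sum(w)
      learners[[t]] <- learner
      alphas[t] <- alpha
      errors[t] <- eps
      weight_trace[[t]] <- w
    }
    list(learners = learners, alphas = alphas, errors = errors,
         weight_trace = weight_trace)
  }
  res <- withr::with_seed(seed, fit_rounds())

  structure(list(learners = res$learners,
                 alphas = res$alphas,
                 errors = res$errors,
                 weight_trace = res$weight_trace,
                 n_rounds = length(res$learners),
                 class_map = enc$class_map,
                 threshold = 0,
                 config = res$learners[[1]]$config,
                 n_train = n,
                 seed = as.integer(seed),
                 version = as.character(utils::packageVersion("mirboost"))),
            class = "bp_adaboost")
}

ensemble_score <- function(object, x) {
  x <- resolve_xy(x)
  h <- vapply(object$learners,
              function(l) ifelse(nn_forward(l, x) > 0, 1, -1),
              numeric(nrow(x)))
  if (is.null(dim(h))) h <- matrix(h, nrow = nrow(x))
  drop(h %*% object$alphas)
}

#' Predict with a BP-AdaBoost classifier
#'
#' The ensemble score is the alpha-weighted vote
#' `sum_t alpha_t * sign(f_t(x))`; the positive label is assigned when the
#' score exceeds the threshold (0), and a tie at the threshold falls to the
#' negative class.
#'
#' @param object A `bp_adaboost` fit.
#' @param new_data Feature matrix or tibble.
#' @param ... Unused.
#' @return A tibble with `.score` and `.pred` (labels in the original
#'   coding).
#' @export
predict.bp_adaboost <- function(object, new_data, ...) {
  if (!length(object$learners)) {
    rlang::abort("untrained ensemble", class = "mirboost_input_error")
  }
  score <- ensemble_score(object, new_data)
  lab <- ifelse(score > object$threshold,
                object$class_map[["positive"]], object$class_map[["negative"]])
  tibble::tibble(.score = score, .pred = lab)
}

#' @export
print.bp_adaboost <- function(x, ...) {
  cat(sprintf("<bp_adaboost> %d weak learners (%d-%d-1), alphas in [%.3f, %.3f]\n",
              x$n_rounds, x$config$n_inputs, x$config$n_hidden,
              min(x$alphas), max(x$alphas)))
  cat(sprintf("  classes: %s (negative) vs %s (positive); seed %d\n",
              x$class_map[["negative"]], x$class_map[["positive"]], x$seed))
  invisible(x)
}

#' Tidy a BP-AdaBoost fit
#'
#' @param x A `bp_adaboost` object.
#' @param ... Unused.
#' @return One row per boosting round: weighted error, classifier weight
#'   `alpha`, and the weak learner's final training MSE and epochs.
#' @method tidy bp_adaboost
#' @export
tidy.bp_adaboost <- function(x, ...) {
  tibble::tibble(
    round = seq_len(x$n_rounds),
    error = x$errors,
    alpha = x$alphas,
    weak_mse = purrr::map_dbl(x$learners, ~ .x$diagnostics$mse),
    weak_epochs = purrr::map_int(x$learners, ~ as.integer(.x$diagnostics$epochs_run))
  )
}

#' Glance at a BP-AdaBoost fit
#' @param x A `bp_adaboost` object.
#' @param ... Unused.
#' @return One-row tibble of ensemble-level summaries.
#' @method glance bp_adaboost
#' @export
glance.bp_adaboost <- function(x, ...) {
  tibble::tibble(
    n_rounds = x$n_rounds,
    n_train = x$n_train,
    mean_error = mean(x$errors),
    total_alpha = sum(x$alphas),
    n_inputs = x$config$n_inputs,
    n_hidden = x$config$n_hidden
  )
}

#' Fit a one-vs-rest multi-class BP-AdaBoost bank
#'
#' Trains one binary [adaboost_fit()] per class (that class vs the rest).
#' Prediction takes the class with the largest normalized vote margin
#' `sum_t alpha_t h_t(x) / sum_t alpha_t`; ties go to the earliest class in
#' the sorted label ordering. A class absent from the training labels is
#' reported as unpredictable.
#'
#' @param x Feature matrix or tibble.
#' @param y Class labels (e.g. species names), at least two distinct.
#' @param rounds,config,seed As in [adaboost_fit()].
#' @return A `bp_adaboost_mc` object (list of per-class ensembles plus the
#'   label ordering).
#' @export
multiclass_fit <- function(x, y, rounds = 10, config = NULL, seed = 1) {
  x <- resolve_xy(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    rlang::abort("need at least two classes", class = "mirboost_input_error")
  }
  class_seeds <- withr::with_seed(seed,
                                  sample.int(.Machine$integer.max - 1,
                                             length(classes)))
  bank <- purrr::map2(classes, class_seeds, function(cl, s) {
    adaboost_fit(x, as.integer(y == cl), rounds = rounds,
                 config = config, seed = s)
  })
  names(bank) <- classes
  structure(list(classes = classes, bank = bank, seed = as.integer(seed),
                 version = as.character(utils::packageVersion("mirboost"))),
            class = "bp_adaboost_mc")
}

multiclass_scores <- function(object, new_data) {
  x <- resolve_xy(new_data)
  s <- vapply(object$bank, function(fit) {
    ensemble_score(fit, x) / sum(fit$alphas)
  }, numeric(nrow(x)))
  if (is.null(dim(s))) s <- matrix(s, nrow = nrow(x))
  colnames(s) <- object$classes
  s
}

#' Predict species with a multi-class BP-AdaBoost bank
#'
#' @param object A `bp_adaboost_mc` fit.
#' @param new_data Feature matrix or tibble.
#' @param ... Unused.
#' @return A tibble with `.pred` and one `.score_<class>` column per class.
#' @export
predict.bp_adaboost_mc <- function(object, new_data, ...) {
  s <- multiclass_scores(object, new_data)
  # max.col with ties.method = "first" => lowest index in sorted class order
  pred <- object$classes[max.col(s, ties.method = "first")]
  out <- tibble::as_tibble(s, .name_repair = ~ paste0(".score_", .x))
  dplyr::bind_cols(tibble::tibble(.pred = pred), out)
}

#' @export
print.bp_adaboost_mc <- function(x, ...) {
  cat(sprintf("<bp_adaboost_mc> one-vs-rest bank over %d classes: %s\n",
              length(x$classes), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' @method glance bp_adaboost_mc
#' @export
glance.bp_adaboost_mc <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes),
                 n_rounds = x$bank[[1]]$n_rounds,
                 n_train = x$bank[[1]]$n_train)
}
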