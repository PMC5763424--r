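#' Confusion counts of binary predictions
#'
#' @param truth True labels.
#' @param estimate Predicted labels (same coding).
#' @param positive The positive-class label (default `"1"`, the real
#'   pre-miRNA class).
#' @return Named list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, estimate, positive = "1") {
  truth <- as.character(truth); estimate <- as.character(estimate)
  if (length(truth) != length(estimate) || !length(truth)) {
    rlang::abort("truth and estimate must be equal-length, non-empty",
                 class = "mirboost_input_error")
  }
  positive <- as.character(positive)
  list(tp = sum(truth == positive & estimate == positive),
       fp = sum(truth != positive & estimate == positive),
       tn = sum(truth != positive & estimate != positive),
       fn = sum(truth == positive & estimate != positive))
}

#' Confusion-matrix metrics
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and specificity `TN/(TN+FP)`. A metric whose denominator is
#' zero is reported as explicitly undefined (`value = NA`, `defined = FALSE`,
#' with a reason) rather than silently propagating `NaN`.
#'
#' @param counts Named list or vector with `tp`, `fp`, `tn`, `fn` (as from
#'   [confusion_counts()]).
#' @return A tibble with columns `metric`, `value`, `defined`, `reason`.
#' @examples
#' classification_metrics(list(tp = 50, fp = 10, tn = 30, fn = 10))
#' @export
classification_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  vals <- c(tp, fp, tn, fn)
  if (any(is.na(vals)) || any(vals < 0)) {
    rlang::abort("counts must be non-negative tp/fp/tn/fn",
                 class = "mirboost_input_error")
  }
  total <- tp + fp + tn + fn
  if (total == 0) {
    rlang::abort("no evaluated samples (all counts zero)",
                 class = "mirboost_input_error")
  }
  ratio <- function(num, den, den_desc) {
    if (den == 0) {
      list(value = NA_real_, defined = FALSE,
           reason = sprintf("denominator %s is zero", den_desc))
    } else {
      list(value = num / den, defined = TRUE, reason = NA_character_)
    }
  }
  rows <- list(
    acc = ratio(tp + tn, total, "TP+FP+TN+FN"),
    precision = ratio(tp, tp + fp, "TP+FP"),
    recall = ratio(tp, tp + fn, "TP+FN"),
    specificity = ratio(tn, tn + fp, "TN+FP")
  )
  tibble::tibble(
    metric = names(rows),
    value = unname(purrr::map_dbl(rows, "value")),
    defined = unname(purrr::map_lgl(rows, "defined")),
    reason = unname(purrr::map_chr(rows, "reason"))
  )
}

#' Assign records to V cross-validation folds
#'
#' Random, optionally stratified assignment into `v` folds whose sizes
#' differ by at most one (within each stratum when stratified).
#'
#' @param labels Label vector (one entry per record); used for
#'   stratification and to determine the number of records.
#' @param v Number of folds.
#' @param seed Integer seed; the same seed always reproduces the split.
#' @param stratify Balance class proportions across folds (default `TRUE`).
#' @return Integer vector of fold ids in `1..v`.
#' @export
vfold_split <- function(labels, v = 10, seed = 1, stratify = TRUE) {
  n <- length(labels)
  if (v < 2) rlang::abort("v must be at least 2", class = "mirboost_input_error")
  if (v > n) {
    rlang::abort(sprintf("v = %d exceeds the %d records", v, n),
                 class = "mirboost_input_error")
  }
  withr::with_seed(seed, {
    folds <- integer(n)
    groups <- if (stratify) split(seq_len(n), as.character(labels)) else list(seq_len(n))
    offset <- 0L
    for (idx in groups) {
      # rotate fold numbering between strata so fold sizes stay balanced
      ids <- ((offset + seq_along(idx) - 1L) %% v) + 1L
      folds[idx[sample.int(length(idx))]] <- ids
      offset <- offset + length(idx)
    }
    folds
  })
}

#' Cross-validate the BP-AdaBoost classifier
#'
#' Runs the V-fold protocol: records are split into `v` folds (stratified by
#' label by default), each fold in turn is held out while an
#' [adaboost_fit()] ensemble is trained on the remaining `v - 1` folds, and
#' confusion-matrix metrics are computed on the held-out fold. Per-column
#' feature standardization happens inside each fold's training call, so no
#' information leaks from the test fold. The report carries the per-fold
#' metric curves and their arithmetic mean.
#'
#' @param features Feature tibble ([hairpin_features()]) or numeric matrix.
#' @param labels Binary labels, one per row.
#' @param v Number of folds.
#' @param rounds Boosting rounds per fold.
#' @param config Optional [network_config()].
#' @param seed Integer seed controlling the split and every fold's training.
#' @param stratify Stratify the folds by label.
#' @return A `mirboost_cv` object: `$folds` (per-fold counts and metrics),
#'   `$summary` (mean of each metric over folds where it is defined),
#'   `$pooled` (metrics of the summed confusion counts), `$skipped`.
#' @export
cross_validate <- function(features, labels, v = 10, rounds = 10,
                           config = NULL, seed = 1, stratify = TRUE) {
  x <- resolve_xy(features)
  if (length(labels) != nrow(x)) {
    rlang::abort("one label per feature row required",
                 class = "mirboost_input_error")
  }
  folds <- vfold_split(labels, v = v, seed = seed, stratify = stratify)
  fold_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1, v))
  per_fold <- list()
  skipped <- integer(0)
  for (k in seq_len(v)) {
    tr <- folds != k
    if (length(unique(labels[tr])) < 2) {
      message(sprintf("fold %d skipped: single-class training partition", k))
      skipped <- c(skipped, k)
      next
    }
    fit <- adaboost_fit(x[tr, , drop = FALSE], labels[tr], rounds = rounds,
                        config = config, seed = fold_seeds[k])
    pred <- predict(fit, x[!tr, , drop = FALSE])
    cc <- confusion_counts(labels[!tr], pred$.pred,
                           positive = fit$class_map[["positive"]])
    m <- classification_metrics(cc)
    per_fold[[length(per_fold) + 1L]] <- tibble::tibble(
      fold = k, n_test = sum(!tr),
      tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
      acc = m$value[m$metric == "acc"],
      precision = m$value[m$metric == "precision"],
      recall = m$value[m$metric == "recall"],
      specificity = m$value[m$metric == "specificity"]
    )
  }
  if (!length(per_fold)) {
    rlang::abort("every fold was skipped", class = "mirboost_fit_error")
  }
  folds_tbl <- dplyr::bind_rows(per_fold)
  metric_cols <- c("acc", "precision", "recall", "specificity")
  summary_tbl <- dplyr::summarise(
    folds_tbl,
    dplyr::across(dplyr::all_of(metric_cols), ~ mean(.x, na.rm = TRUE))
  )
  pooled <- classification_metrics(list(tp = sum(folds_tbl$tp),
                                        fp = sum(folds_tbl$fp),
                                        tn = sum(folds_tbl$tn),
                                        fn = sum(folds_tbl$fn)))
  structure(list(folds = folds_tbl, summary = summary_tbl, pooled = pooled,
                 v = v, rounds = rounds, seed = as.integer(seed),
                 skipped = skipped,
                 version = as.character(utils::packageVersion("mirboost"))),
            class = "mirboost_cv")
}

#' @export
print.mirboost_cv <- function(x, ...) {
  cat(sprintf("<mirboost_cv> %d folds, %d boosting rounds, seed %d\n",
              x$v, x$rounds, x$seed))
  cat(sprintf("  mean: ACC %.4f  precision %.4f  recall %.4f  specificity %.4f\n",
              x$summary$acc, x$summary$precision, x$summary$recall,
              x$summary$specificity))
  if (length(x$skipped)) {
    cat("  skipped folds:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a cross-validation report
#' @param x A `mirboost_cv` object.
#' @param ... Unused.
#' @return Long tibble: one row per fold and metric.
#' @method tidy mirboost_cv
#' @export
tidy.mirboost_cv <- function(x, ...) {
  tidyr::pivot_longer(x$folds,
                      cols = c("acc", "precision", "recall", "specificity"),
                      names_to = "metric", values_to = "value")
}

#' Glance at a cross-validation report
#' @param x A `mirboost_cv` object.
#' @param ... Unused.
#' @return One-row tibble of fold-averaged metrics.
#' @method glance mirboost_cv
#' @export
glance.mirboost_cv <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(v = x$v, rounds = x$rounds,
                                  n_folds_used = nrow(x$folds)),
                   x$summary)
}

#' Plot per-fold metric curves
#'
#' Line plot of accuracy, precision, recall and specificity across the
#' cross-validation folds.
#'
#' @param object A `mirboost_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mirboost_cv
#' @export
autoplot.mirboost_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$value,
                                   colour = .data$metric,
                                   linetype = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_x_continuous(breaks = unique(df$fold)) +
    ggplot2::labs(x = "fold", y = "metric value",
                  title = "Cross-validated classification metrics per fold") +
    ggplot2::theme_minimal()
}

#' Per-class accuracy of multi-class predictions
#'
#' For each class, the fraction of its members predicted correctly
#' (correct-in-class / total-in-class), plus a pooled `total` row (overall
#' correct fraction) and a `macro_mean` row (unweighted mean of the
#' per-class accuracies).
#'
#' @param truth True class labels.
#' @param estimate Predicted class labels.
#' @return A tibble with columns `class`, `n`, `n_correct`, `accuracy`.
#' @export
species_accuracy <- function(truth, estimate) {
  truth <- as.character(truth); estimate <- as.character(estimate)
  stopifnot(length(truth) == length(estimate), length(truth) > 0)
  per <- tibble::tibble(truth = truth, correct = truth == estimate) |>
    dplyr::group_by(class = .data$truth) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$correct),
                     accuracy = mean(.data$correct), .groups = "drop") |>
    dplyr::arrange(.data$class)
  dplyr::bind_rows(
    per,
    tibble::tibble(class = "total", n = length(truth),
                   n_correct = sum(truth == estimate),
                   accuracy = mean(truth == estimate)),
    tibble::tibble(class = "macro_mean", n = length(truth),
                   n_correct = NA_integer_,
                   accuracy = mean(per$accuracy))
  )
}
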