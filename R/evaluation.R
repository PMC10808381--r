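#' Confusion counts for plate status predictions
#'
#' The positive class is salt: `tp` = salt plates predicted salt, `tn` =
#' non-salt predicted non-salt, `fp` = non-salt predicted salt, `fn` =
#' salt predicted non-salt.
#'
#' @param predicted,reference Equal-length vectors of `"salt"` /
#'   `"non-salt"` labels (length >= 1). Alternatively `predicted` may be
#'   the four counts directly via [confusion()].
#' @return Object of class `confusion_counts` with elements `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
#' @examples
#' confusion_counts(c("salt", "salt", "non-salt"),
#'                  c("salt", "non-salt", "non-salt"))
confusion_counts <- function(predicted, reference) {
  if (length(predicted) != length(reference) || length(predicted) < 1) {
    abort("`predicted` and `reference` must have equal length >= 1.",
          class = "seedsalt_input_error")
  }
  ok <- c(predicted, reference) %in% CONDITION_LEVELS
  if (!all(ok)) {
    abort("Status labels must be 'salt' or 'non-salt'.",
          class = "seedsalt_input_error")
  }
  confusion(
    tp = sum(predicted == "salt" & reference == "salt"),
    tn = sum(predicted == "non-salt" & reference == "non-salt"),
    fp = sum(predicted == "salt" & reference == "non-salt"),
    fn = sum(predicted == "non-salt" & reference == "salt")
  )
}

#' Build confusion counts directly
#'
#' @param tp,tn,fp,fn Non-negative integer cell counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.",
          class = "seedsalt_input_error")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d tn=%d fp=%d fn=%d (total %d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' The five performance metrics
#'
#' Accuracy `(tp+tn)/total`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, precision `tp/(tp+fp)` and F1
#' `2*precision*sensitivity/(precision+sensitivity)`. A ratio with a zero
#' denominator is reported as `NA`, never as 0.
#'
#' @param counts A [confusion_counts()] object.
#' @return Object of class `metrics_report`.
#' @export
#' @examples
#' performance_metrics(confusion(tp = 130, tn = 96, fp = 3, fn = 14))
performance_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total < 1) {
    abort("Metrics need at least one observation.",
          class = "seedsalt_input_error")
  }
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(counts$tp, counts$tp + counts$fn)
  prec <- ratio(counts$tp, counts$tp + counts$fp)
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  structure(
    list(accuracy = (counts$tp + counts$tn) / total,
         sensitivity = sens,
         specificity = ratio(counts$tn, counts$tn + counts$fp),
         precision = prec,
         f1 = f1,
         counts = counts),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> accuracy=%.4f sensitivity=%.4f specificity=%.4f precision=%.4f f1=%.4f\n",
    x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1))
  invisible(x)
}

#' Two-decimal display of a metric
#'
#' Published tables mix rounding and truncation at two decimals; this
#' helper produces either display of a full-precision metric.
#'
#' @param x Numeric metric in `[0, 1]`.
#' @param method `"round"` or `"truncate"`.
#' @return Numeric at 2 decimals.
#' @export
format_metric <- function(x, method = c("round", "truncate")) {
  method <- match.arg(method)
  if (method == "round") round(x, 2) else trunc(x * 100) / 100
}

#' Fisher's exact test for a 2x2 status table
#'
#' Two-sided p-value by exhaustive hypergeometric enumeration at fixed
#' margins: all tables whose probability does not exceed the observed
#' table's (with a 1e-7 relative slack) contribute. Degenerate margins
#' (an all-zero row or column) give p = 1 by convention.
#'
#' @param counts A [confusion_counts()] object.
#' @return The p-value in `(0, 1]`.
#' @export
#' @examples
#' fisher_exact(confusion(tp = 3, tn = 3, fp = 1, fn = 1))
fisher_exact <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  m <- counts$tp + counts$fn      # reference salt
  n <- counts$fp + counts$tn      # reference non-salt
  k <- counts$tp + counts$fp      # predicted salt
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0L, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(counts$tp, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Evaluate plate predictions against reference labels
#'
#' Convenience wrapper joining a [classify_plates()] table with reference
#' conditions, then computing counts, the five metrics and the Fisher
#' exact p-value.
#'
#' @param predictions Tibble with `plate` and `status` columns.
#' @param reference Tibble with `plate` and `condition` columns.
#' @return A `metrics_report` with a `fisher_p` element.
#' @export
evaluate_predictions <- function(predictions, reference) {
  joined <- dplyr::inner_join(predictions, reference, by = "plate")
  if (nrow(joined) < nrow(predictions)) {
    abort("Some predicted plates have no reference condition.",
          class = "seedsalt_input_error")
  }
  counts <- confusion_counts(joined$status, joined$condition)
  report <- performance_metrics(counts)
  report$fisher_p <- fisher_exact(counts)
  report
}

#' Stratified plate-level k-fold cross-validation
#'
#' Plates are split into `k` folds at the plate level (never splitting a
#' plate's seeds across folds), stratified by condition and shuffled by
#' `seed`. Each fold is held out in turn: the ensemble is trained on the
#' remaining plates and the held-out plates are classified by consensus.
#' Confusion counts are pooled over folds (micro-averaging) and the
#' metrics computed once on the pooled counts. A training fold containing
#' a single class is skipped with a warning.
#'
#' @param records Labeled seed records spanning >= `k` plates, with
#'   `plate`, `condition` and feature columns.
#' @param subset Attribute subset (`"all"`, `"morpho"`, `"color"`).
#' @param k Number of folds (default 10).
#' @param seed Integer RNG seed driving the fold shuffle and the
#'   per-fold training.
#' @param stratified Stratify folds by condition (default `TRUE`).
#' @return Object of class `kfold_result`: pooled `counts`, `metrics`,
#'   `fisher_p`, the fold assignment and the per-plate predictions.
#' @export
run_kfold <- function(records, subset = c("all", "morpho", "color"),
                      k = 10L, seed = 1L, stratified = TRUE) {
  subset <- match.arg(subset)
  plates <- dplyr::distinct(records, .data$plate, .data$condition)
  if (anyNA(plates$condition)) {
    abort("Every plate needs a condition label.",
          class = "seedsalt_input_error")
  }
  if (k < 2 || k > nrow(plates)) {
    abort("`k` must satisfy 2 <= k <= number of plates.",
          class = "seedsalt_input_error")
  }
  if (dplyr::n_distinct(plates$condition) < 2) {
    abort("Both classes must be present.",
          class = "seedsalt_training_error")
  }
  folds <- withr::with_seed(seed, {
    if (stratified) {
      assign_fold <- function(n) sample(rep_len(seq_len(k), n))
      plates |>
        dplyr::group_by(.data$condition) |>
        dplyr::mutate(fold = assign_fold(dplyr::n())) |>
        dplyr::ungroup()
    } else {
      dplyr::mutate(plates, fold = sample(rep_len(seq_len(k),
                                                  nrow(plates))))
    }
  })
  preds <- list()
  for (f in sort(unique(folds$fold))) {
    test_plates <- folds$plate[folds$fold == f]
    train <- records[!records$plate %in% test_plates, , drop = FALSE]
    if (dplyr::n_distinct(train$condition) < 2) {
      warn(sprintf("Fold %d skipped: training data has a single class.", f))
      next
    }
    model <- train_ensemble(train, subset = subset, seed = seed + f)
    pf <- classify_plates(model,
                          records[records$plate %in% test_plates, ,
                                  drop = FALSE])
    pf$fold <- f
    preds[[length(preds) + 1L]] <- pf
  }
  predictions <- dplyr::bind_rows(preds)
  joined <- dplyr::inner_join(predictions,
                              folds[, c("plate", "condition")],
                              by = "plate")
  counts <- confusion_counts(joined$status, joined$condition)
  metrics <- performance_metrics(counts)
  metrics$fisher_p <- fisher_exact(counts)
  structure(
    list(counts = counts, metrics = metrics,
         fisher_p = metrics$fisher_p, folds = folds,
         predictions = predictions, k = k, subset = subset, seed = seed),
    class = "kfold_result"
  )
}

#' @export
print.kfold_result <- function(x, ...) {
  cat(sprintf("<kfold_result> k=%d subset=%s pooled over %d plates\n",
              x$k, x$subset, nrow(x$predictions)))
  print(x$metrics)
  invisible(x)
}
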