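#' Tidy a confusion matrix
#'
#' @param x A [confusion_counts()] object.
#' @param ... Unused.
#' @return Tibble with one row per cell (`reference`, `predicted`, `n`).
#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble(
    reference = c("salt", "non-salt", "non-salt", "salt"),
    predicted = c("salt", "non-salt", "salt", "non-salt"),
    n = c(x$tp, x$tn, x$fp, x$fn)
  )
}

#' Tidy a metrics report
#'
#' @param x A [performance_metrics()] report.
#' @param ... Unused.
#' @return Tibble with `metric` and `value` columns (and `fisher_p` when
#'   present).
#' @export
tidy.metrics_report <- function(x, ...) {
  metrics <- c("accuracy", "sensitivity", "specificity", "precision", "f1")
  vals <- unlist(x[metrics])
  out <- tibble(metric = metrics, value = unname(vals))
  if (!is.null(x$fisher_p)) {
    out <- dplyr::bind_rows(out, tibble(metric = "fisher_p",
                                        value = x$fisher_p))
  }
  out
}

#' One-row summary of a metrics report
#'
#' @inheritParams tidy.metrics_report
#' @return One-row tibble of the five metrics, the total count and
#'   `fisher_p` when present.
#' @export
glance.metrics_report <- function(x, ...) {
  out <- tibble(
    accuracy = x$accuracy, sensitivity = x$sensitivity,
    specificity = x$specificity, precision = x$precision, f1 = x$f1,
    n = x$counts$tp + x$counts$tn + x$counts$fp + x$counts$fn
  )
  if (!is.null(x$fisher_p)) out$fisher_p <- x$fisher_p
  out
}

#' Tidy an ensemble fit
#'
#' @param x A [train_ensemble()] fit.
#' @param ... Unused.
#' @return Tibble with one row per ensemble member.
#' @export
tidy.seed_ensemble <- function(x, ...) {
  tibble(
    algorithm = names(x$models),
    class = vapply(x$models, function(m) class(m)[1], character(1))
  )
}

#' One-row summary of an ensemble fit
#'
#' @inheritParams tidy.seed_ensemble
#' @return One-row tibble: member count, subset, feature count, training
#'   size and seed.
#' @export
glance.seed_ensemble <- function(x, ...) {
  tibble(
    n_algorithms = length(x$models), subset = x$subset,
    n_features = length(x$columns), n_train = x$n_train, seed = x$seed
  )
}

#' Tidy a cross-validation result
#'
#' @param x A [run_kfold()] result.
#' @param ... Unused.
#' @return The per-plate prediction tibble with fold assignments and
#'   reference conditions.
#' @export
tidy.kfold_result <- function(x, ...) {
  dplyr::inner_join(as_tibble(x$predictions),
                    x$folds[, c("plate", "condition")], by = "plate")
}

#' One-row summary of a cross-validation result
#'
#' @inheritParams tidy.kfold_result
#' @return One-row tibble of the pooled metrics plus `k` and `subset`.
#' @export
glance.kfold_result <- function(x, ...) {
  out <- glance(x$metrics)
  out$k <- x$k
  out$subset <- x$subset
  out
}

#' Consensus bar chart for plate predictions
#'
#' One bar per plate at its consensus percentage, coloured by the called
#' status, with the 50% decision line.
#'
#' @param object A `plate_predictions` tibble from [classify_plates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plate_predictions <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$plate, y = .data$consensus,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "consensus (% of seeds called salt)",
                  fill = "status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Metric bar chart
#'
#' @param object A [performance_metrics()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$metric != "fisher_p", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Segmentation overlay plot
#'
#' Debug view of a segmentation: the image's selected channel as a raster
#' with each detected region's outer contour drawn on top.
#'
#' @param image A [plate_image].
#' @param regions Regions from [segment_plate()].
#' @param channel Channel to display (defaults to grey).
#' @return A ggplot object.
#' @export
plot_segmentation <- function(image, regions, channel = "grey") {
  ch <- channel_matrix(image, channel)
  df <- tibble(
    row = as.vector(row(ch)), col = as.vector(col(ch)),
    value = as.vector(ch)
  )
  contours <- purrr::imap(regions, function(rg, i) {
    ct <- rg$outer_contour
    tibble(row = c(ct[, 1], ct[1, 1]), col = c(ct[, 2], ct[1, 2]),
           label = rg$label)
  }) |> dplyr::bind_rows()
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (nrow(contours) > 0) {
    p <- p + ggplot2::geom_path(
      data = contours,
      ggplot2::aes(group = .data$label),
      colour = "red", linewidth = 0.3
    )
  }
  p
}
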