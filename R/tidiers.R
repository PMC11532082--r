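# broom-style tidiers and autoplot methods for fitted objects and reports.

#' Tidy a fold report
#'
#' @param x A `fold_report` from [evaluate()].
#' @param ... Unused.
#' @return A tibble with one row per class: precision, recall, F1, AUC,
#'   support.
#' @method tidy fold_report
#' @export
tidy.fold_report <- function(x, ...) {
  dplyr::mutate(x$metrics, fold = x$fold_index, .before = 1)
}

#' @rdname tidy.fold_report
#' @method glance fold_report
#' @export
glance.fold_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall,
                 macro_f1 = x$macro_f1,
                 mean_auc = mean(x$metrics$auc, na.rm = TRUE))
}

#' Tidy a cross-validation report
#'
#' @param x A `cv_report` from [cross_validate()].
#' @param ... Unused.
#' @return `tidy()`: per-class metrics for every fold. `glance()`: one row
#'   with the mean and standard deviation of fold accuracy and macro F1.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  purrr::map_dfr(x$folds, tidy)
}

#' @rdname tidy.cv_report
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    k = x$k,
    accuracy = mean(s$accuracy), accuracy_sd = sd(s$accuracy),
    macro_f1 = mean(s$macro_f1), macro_f1_sd = sd(s$macro_f1),
    mean_auc = mean(s$mean_auc, na.rm = TRUE)
  )
}

#' Tidy a fitted fusion network
#'
#' @param x A `fusion_fit` from [fit()].
#' @param ... Unused.
#' @return `tidy()`: the per-epoch training history. `glance()`: one row
#'   with the final epoch's loss and accuracy and the parameter count.
#' @method tidy fusion_fit
#' @export
tidy.fusion_fit <- function(x, ...) {
  x$history
}

#' @rdname tidy.fusion_fit
#' @method glance fusion_fit
#' @export
glance.fusion_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    epochs = nrow(x$history),
    train_loss = last$train_loss,
    train_accuracy = last$train_accuracy,
    n_parameters = n_parameters(x$model)
  )
}

#' Plot training curves
#'
#' Loss and accuracy per epoch (train and, when logged, test).
#'
#' @param object A `fusion_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fusion_fit
#' @export
autoplot.fusion_fit <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(
    h, dplyr::any_of(c("train_loss", "train_accuracy", "test_loss",
                       "test_accuracy")),
    names_to = c("split", "metric"), names_sep = "_",
    values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cross-validation accuracy per fold
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = factor(.data$fold),
                               y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = mean(object$summary$accuracy),
                        linetype = 2) +
    ggplot2::labs(x = "fold", y = "accuracy") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param report A `fold_report` from [evaluate()].
#' @return A ggplot heat map of row-normalized confusion counts.
#' @export
plot_confusion <- function(report) {
  cm <- report$confusion
  df <- as.data.frame(as.table(cm))
  names(df) <- c("truth", "prediction", "count")
  totals <- rowSums(cm)[as.character(df$truth)]
  df$fraction <- ifelse(totals > 0, df$count / totals, 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(fill = "row fraction") +
    ggplot2::theme_minimal()
}
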