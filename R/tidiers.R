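# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted fold
#'
#' @param x a `"mil_fit"`.
#' @param ... unused.
#' @return The per-epoch training history tibble (epoch, train_loss,
#'   val_auroc, lr).
#' @export
tidy.mil_fit <- function(x, ...) x$history

#' @rdname tidy.mil_fit
#' @export
glance.mil_fit <- function(x, ...) {
  tibble::tibble(variant = x$model$variant,
                 backbone = x$model$backbone_variant,
                 epochs = nrow(x$history),
                 best_epoch = x$best_epoch,
                 best_val_auroc = x$best_val_auroc,
                 final_train_loss = x$history$train_loss[nrow(x$history)],
                 fold_index = x$fold_index)
}

#' Tidy a cross-validation result
#'
#' @param x a `"mil_cv"`.
#' @param ... unused.
#' @return `tidy()`: the per-fold test-metric tibble. `glance()`: one row of
#'   mean ± sd test metrics.
#' @export
tidy.mil_cv <- function(x, ...) x$test_metrics

#' @rdname tidy.mil_cv
#' @export
glance.mil_cv <- function(x, ...) {
  s <- x$summary
  out <- tibble::tibble(variant = x$variant, n_folds = length(x$fits))
  for (i in seq_len(nrow(s))) {
    out[[paste0(s$metric[i], "_mean")]] <- s$mean[i]
    out[[paste0(s$metric[i], "_sd")]] <- s$sd[i]
  }
  out
}

#' Plot the training history of a fitted fold
#'
#' Training loss and validation AUROC per epoch, with the selected epoch
#' marked.
#'
#' @param object a `"mil_fit"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mil_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_auroc"),
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("%s (best epoch %d, val AUROC %.3f)",
                                  object$model$variant, object$best_epoch,
                                  object$best_val_auroc)) +
    ggplot2::theme_minimal()
}

#' Plot per-fold test metrics of a cross-validation run
#'
#' @param object a `"mil_cv"`.
#' @param metrics which metric columns to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mil_cv <- function(object, metrics = c("auroc", "auprc"), ...) {
  d <- tidyr::pivot_longer(object$test_metrics,
                           dplyr::all_of(metrics),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$fold_index),
                                  y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "fold", y = NULL,
                  title = sprintf("%s: held-out test metrics per fold",
                                  object$variant)) +
    ggplot2::theme_minimal()
}

#' Plot attention weights of an instance ranking
#'
#' @param object an `"instance_ranking"` tibble from [rank_instances()].
#' @param ... unused.
#' @return A ggplot object; bars are coloured by ground-truth instance
#'   label when available.
#' @export
autoplot.instance_ranking <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$alpha))
  if ("instance_label" %in% names(object))
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = factor(.data$instance_label))) +
      ggplot2::labs(fill = "instance label")
  else p <- p + ggplot2::geom_col()
  p + ggplot2::labs(x = "attention rank", y = expression(alpha),
                    title = object$patient_id[1]) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
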