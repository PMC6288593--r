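# broom-style accessors for fitted objects and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training log of a fitted entity recognizer
#'
#' @param x An `ade_ner`.
#' @param ... Unused.
#' @return A tibble with one row per epoch.
#' @method tidy ade_ner
#' @export
tidy.ade_ner <- function(x, ...) x$log

#' @rdname tidy.ade_ner
#' @method tidy ade_re
#' @export
tidy.ade_re <- function(x, ...) x$log

#' Tidy the joint training log of a multi-task model
#'
#' @param x An `ade_mtl`.
#' @param ... Unused.
#' @return A tibble with per-epoch NER/RE losses and the tying penalty.
#' @method tidy ade_mtl
#' @export
tidy.ade_mtl <- function(x, ...) x$log

#' One-row summary of a fitted entity recognizer
#'
#' @param x An `ade_ner`.
#' @param ... Unused.
#' @return A one-row tibble: epochs trained, final loss, parameter count.
#' @method glance ade_ner
#' @export
glance.ade_ner <- function(x, ...) {
  tibble::tibble(
    epochs = if (is.null(x$log)) NA_integer_ else max(x$log$epoch),
    final_loss = if (is.null(x$log)) NA_real_ else
      x$log[[nrow(x$log), grep("loss", names(x$log))[1L]]],
    n_parameters = sum(vapply(x$params, length, 0L)))
}

#' @rdname glance.ade_ner
#' @method glance ade_re
#' @export
glance.ade_re <- glance.ade_ner

#' Plot a training log
#'
#' @param object A fitted `ade_ner`, `ade_re`, or `ade_mtl`.
#' @param ... Unused.
#' @return A ggplot of loss against epoch.
#' @method autoplot ade_mtl
#' @export
autoplot.ade_mtl <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, -"epoch", names_to = "series",
                            values_to = "value")
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss / penalty", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ade_mtl
#' @method autoplot ade_ner
#' @export
autoplot.ade_ner <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean CRF negative log-likelihood") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ade_mtl
#' @method autoplot ade_re
#' @export
autoplot.ade_re <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation table
#'
#' Per-type precision/recall/F1 bars for entities and relations.
#'
#' @param object An `ade_evaluation` from [evaluate_extraction()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ade_evaluation
#' @export
autoplot.ade_evaluation <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$type, .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~task, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
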