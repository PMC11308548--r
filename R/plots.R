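# ggplot2 views of the main result types.

#' Plot per-class test performance of a registry
#'
#' @param object A `model_registry`.
#' @param ... Unused.
#' @return A ggplot: classes ordered by held-out MCC, colored by the
#'   selected algorithm, with the configured success threshold marked.
#' @export
autoplot.model_registry <- function(object, ...) {
  td <- tidy(object)
  thr <- object$manifest$config$mcc_success_threshold %||% 0.7
  ggplot2::ggplot(td, ggplot2::aes(
    x = stats::reorder(.data$class, .data$test_mcc),
    y = .data$test_mcc, fill = .data$algorithm
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "held-out MCC", fill = "algorithm") +
    ggplot2::theme_minimal()
}

#' Plot a prediction report as a call heatmap
#'
#' @param object A `prediction_report`.
#' @param ... Unused.
#' @return A ggplot tile map of binary calls (genomes by classes).
#' @export
autoplot.prediction_report <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"genome_id",
                              names_to = "class", values_to = "call")
  ggplot2::ggplot(long, ggplot2::aes(.data$class, .data$genome_id,
                                     fill = factor(.data$call))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey90", `1` = "steelblue"),
                               name = "call") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an importance table
#'
#' @param importance Tibble from [extract_importance()].
#' @param top_n How many KOs (by absolute score) to show.
#' @return A ggplot lollipop of signed scores.
#' @export
plot_importance <- function(importance, top_n = 30) {
  shown <- head(importance[order(-abs(importance$score)), ], top_n)
  ggplot2::ggplot(shown, ggplot2::aes(
    x = stats::reorder(.data$ko, abs(.data$score)), y = .data$score
  )) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$ko, yend = 0), color = "grey60") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "importance score",
      title = attr(importance, "class_name"),
      subtitle = paste("source:", attr(importance, "source_algorithm"))
    ) +
    ggplot2::theme_minimal()
}

#' Long view of a prediction report
#'
#' @param x A `prediction_report`.
#' @param ... Unused.
#' @return Tibble with `genome_id`, `class`, `call`.
#' @export
tidy.prediction_report <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"genome_id",
                      names_to = "class", values_to = "call")
}
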