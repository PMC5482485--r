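#' Plot fitted item blocks
#'
#' Heat map of the conditional option-selection probabilities
#' `P_c(eta_jh)`, one facet per item, reduced patterns on the y axis.
#'
#' @param object A `gndm_fit`.
#' @param items Item positions to show (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gndm_fit <- function(object, items = seq_len(object$qmatrix$J),
                              ...) {
  d <- tidy(object) %>%
    filter(.data$item %in% vapply(object$qmatrix$items[items], `[[`,
                                  object$qmatrix$items[[1]]$item, "item"))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$option), y = .data$bits,
                                  fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$estimate)),
                       size = 2.7) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(~item, scales = "free") +
    ggplot2::labs(x = "option", y = "reduced attribute pattern",
                  fill = "P") +
    ggplot2::theme_minimal()
}

#' Plot misfit statistics
#'
#' Bars of the per-option root-mean-square z statistics `sl_jc`, grouped
#' by item, with the test-level `sl` as a reference line.
#'
#' @param object A `gndm_assessment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gndm_assessment <- function(object, ...) {
  d <- mutate(object$option_stats,
              id = paste0(.data$item, ":", .data$option))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$id, y = .data$sl_jc,
                                  fill = factor(.data$item))) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$sl, linetype = 2) +
    ggplot2::labs(x = "item:option", y = "sl (option level)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot study results
#'
#' Distribution of the per-replication classification accuracies.
#'
#' @param object A `gndm_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gndm_study <- function(object, ...) {
  d <- tidyr::pivot_longer(object$ca, -"rep", names_to = "statistic")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$statistic, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::labs(x = NULL, y = "classification accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
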