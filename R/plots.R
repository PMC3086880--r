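#' Plot the per-pathway breakdown of a prediction set
#'
#' Bar chart of predicted pathway annotations per pathway, the standard
#' first look at a transfer run.
#'
#' @param predictions A `signalog_predictions` tibble.
#' @return A ggplot object.
#' @export
plot_pathway_counts <- function(predictions) {
  s <- summarize_predictions(predictions)
  ggplot2::ggplot(s$per_pathway,
                  ggplot2::aes(x = stats::reorder(.data$pathway, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "predicted annotations",
                  title = "Signalog predictions per pathway") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.signalog_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_pathway,
                  ggplot2::aes(x = stats::reorder(.data$pathway, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "predicted annotations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.coverage_stats <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::starts_with("frac_"),
                        names_to = "statistic", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species,
                                     y = .data$percent,
                                     fill = .data$statistic)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of annotated proteins",
                  title = "Orthology coverage of known signaling proteins") +
    ggplot2::theme_minimal()
}

#' Plot relevance scores of drug-target candidates
#'
#' Counts of signalog proteins per relevance score, split by whether
#' each protein is already an established drug target.
#'
#' @param candidates Output of [candidate_table()].
#' @return A ggplot object.
#' @export
plot_relevance_scores <- function(candidates) {
  ggplot2::ggplot(candidates,
                  ggplot2::aes(x = factor(.data$score, levels = 0:4),
                               fill = .data$is_current_target)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               name = "current drug target") +
    ggplot2::labs(x = "drug-target relevance score (0-4)",
                  y = "signalog proteins") +
    ggplot2::theme_minimal()
}
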