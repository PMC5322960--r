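# ggplot2 views of the standard result tables.

#' Plot a stress-position distribution
#'
#' Bar chart of a [stress_distribution()] table: type percentages by stress
#' position, facetted by the grouping column when the table was computed by
#' syllabic length or PoS category.
#'
#' @param dist A [stress_distribution()] tibble.
#' @param weighting Plot `"type"` or `"token"` percentages.
#' @return A ggplot object.
#' @export
plot_stress_distribution <- function(dist, weighting = c("type", "token")) {
  weighting <- match.arg(weighting)
  ycol <- paste0("pct_", weighting)
  facet <- intersect(c("n_syll", "pos_primary"), names(dist))
  p <- ggplot2::ggplot(
    dist,
    ggplot2::aes(x = .data$stress, y = .data[[ycol]])
  ) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "stress position",
      y = paste0("% of ", weighting, "s")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (length(facet) > 0) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", facet[1])))
  }
  p
}

#' Plot neighbourhood-density summaries of a built lexicon
#'
#' Histograms of Coltheart's N counts and OLD20 values (stressed variants) of a
#' [build_lexicon()] table.
#'
#' @param lexicon A [build_lexicon()] tibble.
#' @return A ggplot object.
#' @export
plot_neighbourhood <- function(lexicon) {
  d <- lexicon |>
    dplyr::select(
      `Coltheart's N` = "coltheart_n_stressed",
      "OLD20" = "old20_stressed"
    ) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey30") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "entries") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Confusion plot for a stress-prediction evaluation
#'
#' @param object A `stress_eval` object from [evaluate_stress_prediction()].
#' @param ... Unused.
#' @return A ggplot object (true vs predicted position, tile counts).
#' @method autoplot stress_eval
#' @export
autoplot.stress_eval <- function(object, ...) {
  d <- object$confusion |>
    dplyr::mutate(
      true = stress_label(.data$true),
      predicted = stress_label(.data$predicted)
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$true)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$n_type)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_type), colour = "white") +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(
      title = sprintf(
        "%s-method stress prediction (type acc. %.3f)",
        object$method, object$accuracy_type
      ),
      x = "predicted position", y = "true position"
    ) +
    ggplot2::theme_minimal()
}
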