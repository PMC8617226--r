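#' Plot resilience scores by dimension
#'
#' Boxplots of the country-level dimension and overall scores, optionally
#' split by species — the standard at-a-glance view of where resilience
#' is gained and lost across the fishery.
#'
#' @param object A `resilience_scores` object.
#' @param by_species Facet by species.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot resilience_scores
#' @export
autoplot.resilience_scores <- function(object, by_species = FALSE, ...) {
  dm <- object$scores[object$scores$entity_level == "country" &
                        object$scores$level %in% c("dimension", "overall"), ]
  dm$node_id <- factor(dm$node_id, levels = c("ecological", "socioeconomic",
                                              "institutional", "overall"))
  dm$species <- sub("^.*:", "", dm$entity)
  p <- ggplot2::ggplot(dm, ggplot2::aes(x = .data$node_id, y = .data$score)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6, na.rm = TRUE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "resilience score") +
    ggplot2::theme_minimal()
  if (by_species) p <- p + ggplot2::facet_wrap(~species)
  p
}

#' Plot factor importance
#'
#' Horizontal bar chart of permutation importance (% increase in
#' prediction error), factors ordered by rank.
#'
#' @param object A `factor_importance` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot factor_importance
#' @export
autoplot.factor_importance <- function(object, ...) {
  tb <- object$importance
  ggplot2::ggplot(tb, ggplot2::aes(
    x = .data$importance_pct,
    y = stats::reorder(.data$factor, .data$importance_pct)
  )) +
    ggplot2::geom_col(fill = "firebrick", alpha = 0.7) +
    ggplot2::labs(x = "mean decrease accuracy (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the fitted latitude curve
#'
#' @param object A `latitude_effect` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot latitude_effect
#' @export
autoplot.latitude_effect <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$latitude, y = .data$fitted)) +
    ggplot2::geom_line(linewidth = 1, color = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "latitude (°N)", y = "fitted resilience score") +
    ggplot2::theme_minimal()
}
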