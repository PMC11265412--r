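#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a reactome partition as a frequency histogram
#'
#' Reaction carriage frequencies colored by core/accessory/rare class, with
#' the partition thresholds drawn as dashed lines.
#'
#' @param object A `reactome_partition`.
#' @param binwidth Histogram bin width in frequency percent.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reactome_partition <- function(object, binwidth = 2.5, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$class != "absent", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, fill = .data$class)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(attr(object, "accessory_min"),
                                       attr(object, "core_min")),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "reaction frequency across strains (%)",
                  y = "reactions", fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot niche enrichment as a log-odds heat map
#'
#' @param object An `enrichment_result` (optionally pre-filtered with
#'   [select_enriched()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$niche, y = .data$reaction_id,
                               fill = .data$log_or)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log odds ratio") +
    ggplot2::theme_minimal()
}

#' Plot a PCA embedding of strains
#'
#' @param object A `pca_embedding` from [pca_embed()].
#' @param colour Optional vector (one entry per strain) used as the point
#'   colour, e.g. species or niche labels.
#' @param ... Unused.
#' @return A ggplot object of the first two components.
#' @export
autoplot.pca_embedding <- function(object, colour = NULL, ...) {
  df <- object$scores
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
}

#' Plot fermentation capability ranges
#'
#' Secretion flux ranges (FVA min/max) per exchange reaction, with the FBA
#' point estimate overlaid.
#'
#' @param object A `fermentation_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fermentation_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$producible | df$secreted, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exchange_id)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                            linewidth = 1.2, colour = "grey55") +
    ggplot2::geom_point(ggplot2::aes(y = .data$fba_flux), colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "secretion flux (mmol/gDCW/h)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
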