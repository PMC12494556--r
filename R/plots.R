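# ggplot2 display methods for the main result types.

#' Stick-spectrum plot of a peak list
#'
#' @param peaks A data frame with `neutral_mass` and `intensity`.
#' @param label_top Label the `label_top` most intense peaks with their
#'   composition when a `composition` column is present.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(peaks, label_top = 5) {
  stopifnot(all(c("neutral_mass", "intensity") %in% names(peaks)))
  p <- ggplot2::ggplot(peaks, ggplot2::aes(x = .data$neutral_mass,
                                           y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$neutral_mass, yend = 0)) +
    ggplot2::labs(x = "neutral monoisotopic mass (Da)", y = "intensity") +
    ggplot2::theme_minimal()
  if ("composition" %in% names(peaks) && label_top > 0) {
    top <- dplyr::slice_max(tibble::as_tibble(peaks), .data$intensity,
                            n = label_top, with_ties = FALSE)
    p <- p + ggplot2::geom_text(data = top,
                                ggplot2::aes(label = .data$composition),
                                vjust = -0.4, size = 3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of a glycoform table
#'
#' Relative glycoform abundances per composition, faceted by site, filled by
#' sample — the standard at-a-glance comparison of glycoform distributions
#' between genotypes.
#'
#' @param object A `glycoform_table`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @examples
#' autoplot(subex_c57y_glycoforms())
#' @export
autoplot.glycoform_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$composition,
                                       y = .data$rel_amount,
                                       fill = .data$sample)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$site)) +
    ggplot2::labs(x = NULL, y = "relative amount (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
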