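# ggplot2 visualisations of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a kappa matrix
#'
#' Subcategory-by-subcategory tile plot of Fleiss' kappa, coloured from
#' red (poor agreement, kappa = -1) through white to dark blue (perfect
#' agreement, kappa = 1).
#'
#' @param object A `kappa_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kappa_matrix <- function(object, ...) {
  cells <- object$cells
  if (object$mode == "within_C") {
    cells <- dplyr::bind_rows(
      cells,
      dplyr::rename(cells, subcat_x = "subcat_y", subcat_y = "subcat_x")
    )
  }
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$subcat_y, y = .data$subcat_x,
                                      fill = .data$kappa)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$kappa)),
                       size = 2.8, na.rm = TRUE) +
    ggplot2::scale_fill_gradient2(low = "firebrick3", mid = "white",
                                  high = "navy", midpoint = 0,
                                  limits = c(-1, 1), name = "kappa") +
    ggplot2::scale_y_discrete(limits = rev(object$axes$x)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Fleiss' kappa by subcategory pair (%s)",
                                  object$mode)) +
    ggplot2::theme_minimal()
}

#' Bar chart of an agreement report
#'
#' @param object An `agreement_report` from [stratify()].
#' @param panel `"strata"` for the five difference strata, `"levels"` for
#'   the severity-level distribution within full agreement.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_report <- function(object, panel = c("strata", "levels"), ...) {
  panel <- match.arg(panel)
  if (panel == "strata") {
    d <- object$strata
    ggplot2::ggplot(d, ggplot2::aes(x = .data$stratum, y = .data$count)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_text(ggplot2::aes(label = sprintf("%s%%", .data$pct)),
                         vjust = -0.3, size = 3) +
      ggplot2::labs(x = NULL, y = "drug pairs",
                    title = sprintf("Agreement strata (N = %d pairs)",
                                    object$total_pairs)) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  } else {
    d <- object$by_level
    ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$count)) +
      ggplot2::geom_col(fill = "darkseagreen4") +
      ggplot2::labs(x = NULL, y = "drug pairs",
                    title = sprintf("Severity levels within agreement (N = %d)",
                                    object$denominators$by_level)) +
      ggplot2::theme_minimal()
  }
}

#' Convenience wrapper: heatmap for a catalog + ratings
#'
#' @param catalog A drug catalog.
#' @param ratings Harmonized long ratings table.
#' @param mode Matrix mode, see [build_kappa_matrix()].
#' @param ... Forwarded to [build_kappa_matrix()].
#' @return A ggplot object.
#' @export
plot_kappa_heatmap <- function(catalog, ratings, mode = "within_C", ...) {
  autoplot(build_kappa_matrix(catalog, ratings, mode = mode, ...))
}
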