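#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_abline geom_tile
#'   geom_raster scale_fill_gradient2 scale_fill_viridis_c labs coord_equal
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object A [roc_points()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot renotex_roc
#' @export
autoplot.renotex_roc <- function(object, ...) {
  a <- attr(object, "auc")
  ggplot(object, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_step() +
    coord_equal() +
    labs(x = "False positive rate (1 - specificity)",
         y = "True positive rate (sensitivity)",
         title = sprintf("ROC curve (AUC = %.4f)", a)) +
    theme_minimal()
}

#' Plot a feature correlation heatmap
#'
#' @param object A [correlation_matrix()] object.
#' @param absolute Plot correlation magnitudes (default TRUE, matching the
#'   usual radiomics presentation).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot renotex_cormat
#' @export
autoplot.renotex_cormat <- function(object, absolute = TRUE, ...) {
  m <- if (absolute) attr(object, "abs") else unclass(object)
  df <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("feature_1", "feature_2", "rho")
  p <- ggplot(df, aes(x = .data$feature_1, y = .data$feature_2,
                      fill = .data$rho)) +
    geom_tile() +
    labs(x = NULL, y = NULL,
         fill = if (absolute) "|rho|" else "rho") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
  if (absolute) {
    p + ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                     limits = c(0, 1))
  } else {
    p + scale_fill_gradient2(limits = c(-1, 1))
  }
}

#' Display a tumor phantom
#'
#' @param object A [generate_phantom()] object.
#' @param which `"pre"` or `"post"` image.
#' @param outline Draw the ROI outline (default TRUE).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tumor_phantom
#' @export
autoplot.tumor_phantom <- function(object, which = c("pre", "post"),
                                   outline = TRUE, ...) {
  which <- match.arg(which)
  img <- object[[which]]
  df <- tibble::tibble(
    row = as.vector(row(img)), col = as.vector(col(img)),
    hu = as.vector(img))
  p <- ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$hu)) +
    geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    coord_equal() +
    labs(title = sprintf("%s (%s grade, %s-contrast)", object$patient_id,
                         object$grade, which),
         x = "column (transverse)", y = "row (anteroposterior)",
         fill = "HU") +
    theme_minimal()
  if (outline) {
    edge <- object$mask & !erode4(object$mask)
    de <- tibble::tibble(row = as.vector(row(img))[edge],
                         col = as.vector(col(img))[edge])
    p <- p + ggplot2::geom_point(data = de, aes(x = .data$col, y = .data$row),
                                 inherit.aes = FALSE, colour = "yellow",
                                 size = 0.1)
  }
  p
}
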