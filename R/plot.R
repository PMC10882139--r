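#' Plot a projection image
#'
#' Renders a MIP or mask projection with ggplot2 (rows = axial position,
#' flipped so the head is up).
#'
#' @param x a [projection_image()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_projection <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- expand.grid(row = seq_len(nrow(x$values)), col = seq_len(ncol(x$values)))
  df$value <- as.vector(x$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = x$provenance) +
    ggplot2::coord_fixed(ratio = x$pixel_spacing[1] / x$pixel_spacing[2]) +
    ggplot2::labs(title = sprintf("%s projection, %.4g deg", x$provenance,
                                  x$angle),
                  x = "frame column", y = "axial row") +
    ggplot2::theme_minimal()
}

#' Plot a projection-count study curve
#'
#' Mean HD95 (mm) against the number of projections, with per-case curves in
#' the background.
#'
#' @param object a `tpdm_study` from [projection_count_study()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tpdm_study <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  res <- object$results[!object$results$flagged, ]
  ggplot2::ggplot(res, ggplot2::aes(x = .data$n_angles, y = .data$hd95_mm)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$case), alpha = 0.25) +
    ggplot2::geom_line(data = object$summary, linewidth = 1.2,
                       colour = "firebrick") +
    ggplot2::geom_point(data = object$summary, colour = "firebrick") +
    ggplot2::scale_x_continuous(trans = "log2",
                                breaks = sort(unique(res$n_angles))) +
    ggplot2::labs(x = "number of projections",
                  y = "HD95 (mm), binarized TPDM vs ground truth") +
    ggplot2::theme_minimal()
}

# re-export ggplot2's autoplot generic lazily: define a plain generic if
# ggplot2 is unavailable so the method above can still be registered
#' @export
autoplot <- function(object, ...) UseMethod("autoplot")
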