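#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_tile geom_point
#'   geom_line facet_wrap labs scale_fill_viridis_c scale_fill_gradient2
#'   theme_minimal theme element_text
NULL

#' @export
ggplot2::autoplot

#' Heatmap of similarity-score matrices
#'
#' One heatmap per score, mirroring the published layout: rows are
#' (experimental, simulated) surface pairs, columns are the relative mesh
#' points ordered as concentric rings around the peaks. Colour scales are
#' heatmap-specific; `delta_zr` uses a diverging scale centred at 0 so
#' bluer shades mean the simulation descends more steeply.
#'
#' @param object A `similarity_matrix` from [compare_all()].
#' @param score One of `"rho"`, `"theta"`, `"delta_zr"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.similarity_matrix <- function(object, score = c("rho", "theta", "delta_zr"),
                                       ...) {
  score <- match.arg(score)
  m <- object[[score]]
  df <- tibble::as_tibble(m, rownames = "pair") |>
    tidyr::pivot_longer(-"pair", names_to = "point", values_to = "value")
  df$pair <- factor(df$pair, levels = rev(rownames(m)))
  df$point <- factor(df$point, levels = colnames(m))
  p <- ggplot(df, aes(x = .data$point, y = .data$pair, fill = .data$value)) +
    geom_tile() +
    labs(x = "relative mesh point (ring order)", y = NULL, fill = score) +
    theme_minimal(base_size = 9) +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 5))
  if (score == "delta_zr") {
    p + scale_fill_gradient2(low = "#2c7bb6", mid = "#ffffbf",
                             high = "#d7191c", midpoint = 0)
  } else {
    p + scale_fill_viridis_c()
  }
}

#' Project surfaces into the evaluation plane
#'
#' Renders each surface's z values over the (xw, xn) plane, one facet per
#' surface, each on its own colour scale spanning that surface's minimum
#' and maximum (scales are normalised per surface before plotting so one
#' shared legend covers all facets).
#'
#' @param models Named list of surface models.
#' @param grid An [eval_grid()].
#' @return A ggplot object.
#' @export
plot_surface_projections <- function(models, grid = eval_grid()) {
  df <- purrr::imap_dfr(models, function(model, nm) {
    z <- surface_grid(model, grid)
    tidyr::expand_grid(xw = grid$water, xn = grid$nitrogen) |>
      dplyr::mutate(z = as.vector(t(z)),
                    z_scaled = (.data$z - min(.data$z)) /
                      max(diff(range(.data$z)), .Machine$double.eps),
                    surface = nm)
  })
  df$surface <- factor(df$surface, levels = names(models))
  ggplot(df, aes(x = .data$xw, y = .data$xn, fill = .data$z_scaled)) +
    geom_raster() +
    facet_wrap(~surface) +
    scale_fill_viridis_c() +
    labs(x = "recentred water", y = "recentred nitrogen",
         fill = "z (per-surface scale)") +
    theme_minimal(base_size = 9)
}

#' Scan profile plot
#'
#' -log10 of the smoothed p-values along the genome, faceted by
#' chromosome, with the Sidak threshold drawn when available.
#'
#' @param object A `scan_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.scan_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ycol <- if (!is.null(df[["smoothed_p"]])) "smoothed_p" else "raw_p"
  df$y <- -log10(df[[ycol]])
  p <- ggplot(df[!df$skipped, ],
              aes(x = .data$pos_cm, y = .data$y)) +
    geom_line(colour = "grey60") +
    geom_point(size = 0.8) +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "map position (cM)",
         y = sprintf("-log10 %s", gsub("_", " ", ycol))) +
    theme_minimal(base_size = 9)
  thr <- attr(object, "sidak_threshold")
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(thr),
                                 linetype = "dashed", colour = "red")
  }
  p
}
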