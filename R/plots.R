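#' Scatter plot of the MIB-1 regression
#'
#' Weighted percentage decrease against the MIB-1 index with the fitted
#' least-squares line and the correlation in the subtitle.
#'
#' @param object a `mib1_fit` from [regress_mib1()].
#' @param ... unused.
#' @method autoplot mib1_fit
#' @export
autoplot.mib1_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mib1, y = .data$weighted_pct)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "MIB-1 labeling index (%)",
                  y = "Tract decrease / tumor volume (%/cm³)",
                  subtitle = sprintf("r = %.2f, p = %.2g (n = %d)",
                                     object$r, object$p, object$n)) +
    ggplot2::theme_minimal()
}

#' Project streamlines onto a coordinate plane
#'
#' Quick-look 2D projection of a tractogram, optionally overlaying a mask
#' outline (e.g. the lesion).
#'
#' @param t a `tractogram`.
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param mask optional [mask_volume()] drawn as shaded voxels.
#' @param max_streamlines cap on the number of streamlines drawn.
#' @export
plot_streamlines <- function(t, plane = c("yz", "xy", "xz"), mask = NULL,
                             max_streamlines = 200) {
  plane <- match.arg(plane)
  ax <- switch(plane, xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  sl <- t$streamlines
  if (length(sl) > max_streamlines) {
    sl <- sl[round(seq(1, length(sl), length.out = max_streamlines))]
  }
  df <- dplyr::bind_rows(lapply(seq_along(sl), function(i) {
    tibble::tibble(u = sl[[i]]$points[, ax[1]], v = sl[[i]]$points[, ax[2]], id = i)
  }))
  p <- ggplot2::ggplot()
  if (!is.null(mask)) {
    idx <- which(mask$data, arr.ind = TRUE) - 1
    xyz <- voxel_to_world(mask$grid, idx)
    mdf <- tibble::tibble(u = xyz[, ax[1]], v = xyz[, ax[2]])
    p <- p + ggplot2::geom_tile(data = mdf, ggplot2::aes(x = .data$u, y = .data$v),
                                fill = "firebrick", alpha = 0.25)
  }
  p + ggplot2::geom_path(data = df,
                         ggplot2::aes(x = .data$u, y = .data$v, group = .data$id),
                         alpha = 0.3, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(substr(plane, 1, 1), " (mm)"),
                  y = paste0(substr(plane, 2, 2), " (mm)")) +
    ggplot2::theme_minimal()
}

#' Heatmap of one slice of a connection-probability image
#'
#' @param map a [scalar_volume()].
#' @param slice 1-based slice index along `axis`.
#' @param axis slicing axis (1-3).
#' @export
plot_connection_map <- function(map, slice = NULL, axis = 1) {
  d <- dim(map$data)
  if (is.null(slice)) slice <- which.max(apply(map$data, axis, sum))
  sl <- switch(axis, map$data[slice, , ], map$data[, slice, ], map$data[, , slice])
  df <- tibble::tibble(u = as.vector(row(sl)), v = as.vector(col(sl)),
                       p = as.vector(sl))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "P(connect)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "voxel", y = "voxel") +
    ggplot2::theme_minimal()
}
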