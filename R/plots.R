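# ggplot2 visualizations for the package's result types.

#' @exportS3Method ggplot2::autoplot
autoplot.ellipse_field <- function(object, n_poly = 90, ...) {
  ell <- object$ellipses
  polys <- purrr::map(seq_len(nrow(ell)), function(i) {
    b <- ellipse_boundary(as.numeric(ell[i, c("x", "y", "a", "b", "theta")]),
                          n_poly)
    tibble(x = b[, 1], y = b[, 2], id = paste(ell$channel[i], ell$id[i]),
           channel = ell$channel[i])
  })
  df <- dplyr::bind_rows(polys)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$id,
                                   fill = .data$channel)) +
    ggplot2::geom_polygon(alpha = 0.6, colour = "grey20", linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = object$halfwidth_nm,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = NULL)
}

#' @exportS3Method ggplot2::autoplot
autoplot.distance_summary <- function(object, ...) {
  df <- tibble(bin = factor(object$bin, levels = object$bin),
               fraction = object$fraction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "edge-to-edge distance (nm)",
                  y = "fraction of query clusters") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.placement_result <- function(object, ...) {
  h <- object$mean_histogram
  df <- tibble(bin = factor(h$bin, levels = h$bin), fraction = h$fraction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(
      x = "edge-to-edge distance (nm)", y = "mean fraction over reps",
      title = sprintf("placement model, f = %g", object$config$attraction_f)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.kd_estimate <- function(object, ...) {
  abort("plot the walk trace via autoplot.walk_trace")
}

#' @exportS3Method ggplot2::autoplot
autoplot.walk_trace <- function(object, ...) {
  df <- tibble(step = seq_along(object$bound_trace),
               bound = object$bound_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$bound)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time step", y = "bound channels")
}

#' @exportS3Method ggplot2::autoplot
autoplot.arrangement_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_rep, cols = c("kd_clustered",
                                                     "kd_distributed"),
                            names_to = "arrangement", values_to = "kd_nM")
  df$arrangement <- sub("kd_", "", df$arrangement)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arrangement, y = .data$kd_nM)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "Kd (nM)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.height_map <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object$z)),
                    col = seq_len(ncol(object$z)))
  df$x <- (df$col - 1) * object$spacing_nm
  df$y <- (df$row - 1) * object$spacing_nm
  df$z <- as.vector(object$z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "z (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.power_spectrum <- function(object, ...) {
  rp <- object$radial_profile[-1, ]
  ggplot2::ggplot(rp, ggplot2::aes(x = .data$freq_per_nm,
                                   y = .data$power)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(
      xintercept = 1 / object$dominant_period_nm,
      linetype = "dashed", colour = "darkorange", na.rm = TRUE) +
    ggplot2::labs(x = "spatial frequency (1/nm)", y = "radial mean power")
}

#' Plot a two-channel raster (e.g. a particle average)
#'
#' @param img Array `[y, x, 2]`.
#' @param pixel_nm Pixel size for axis labelling.
#' @return A ggplot object with one panel per channel.
#' @export
plot_two_channel <- function(img, pixel_nm = 20) {
  d <- dim(img)
  df <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]),
                    channel = c("reference", "secondary"))
  df$value <- c(as.vector(img[, , 1]), as.vector(img[, , 2]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}
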