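#' Plot methods
#'
#' `autoplot()` methods render the package's result types with ggplot2:
#' the depth or brightness image of a scan, the curvature image (bright =
#' positive, i.e. concave; the furrow shows as a bright midline band),
#' candidate-curve families in image coordinates, spatial curves in the
#' frontal and sagittal planes, manual-vs-automatic comparisons, and
#' repeatability SD-vs-X curves.
#'
#' @param object The object to plot.
#' @param channel For scans, `"z"` (depth) or `"brightness"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name spinescan-plots
NULL

#' @rdname spinescan-plots
#' @exportS3Method ggplot2::autoplot
autoplot.back_scan <- function(object, channel = c("z", "brightness"), ...) {
  channel <- match.arg(channel)
  df <- as_tibble(object)
  df <- df[df$valid, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v, fill = .data[[channel]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (channel == "z") "Z [mm]" else "brightness") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u [samples]", y = "v [profiles]") +
    ggplot2::theme_minimal()
}

#' @rdname spinescan-plots
#' @exportS3Method ggplot2::autoplot
autoplot.curvature_map <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$valid, ]
  lim <- max(abs(df$k))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v, fill = .data$k)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(
      name = "K [1/mm]",
      low = "black", mid = "grey50", high = "white", limits = c(-lim, lim)
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u [samples]", y = "v [profiles]") +
    ggplot2::theme_minimal()
}

#' @rdname spinescan-plots
#' @exportS3Method ggplot2::autoplot
autoplot.candidate_set <- function(object, ...) {
  df <- tidyr::unnest(
    dplyr::mutate(object, curve = lapply(.data$curve, tibble::as_tibble)),
    "curve"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$u, y = .data$v,
    group = .data$candidate, colour = factor(.data$candidate)
  )) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "u [samples]", y = "v [profiles]", colour = "candidate") +
    ggplot2::theme_minimal()
}

#' @rdname spinescan-plots
#' @exportS3Method ggplot2::autoplot
autoplot.curve3d <- function(object, ...) {
  df <- dplyr::bind_rows(
    frontal = tibble::as_tibble(project_curve(object, "frontal")),
    sagittal = tibble::as_tibble(project_curve(object, "sagittal")),
    .id = "plane"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$x)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~plane, scales = "free_x") +
    ggplot2::labs(x = "lateral / depth [mm]", y = "X [mm]") +
    ggplot2::theme_minimal()
}

#' @rdname spinescan-plots
#' @exportS3Method ggplot2::autoplot
autoplot.repeatability_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_x, -"x",
    names_to = "quantity", values_to = "sd_mm"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$sd_mm, colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "X [mm]", y = "SD [mm]", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay manual and automatic spine curves in one plane
#'
#' @param manual,auto `curve3d` tibbles.
#' @param plane `"frontal"` or `"sagittal"`.
#' @return A ggplot object.
#' @export
plot_curves <- function(manual, auto, plane = c("frontal", "sagittal")) {
  plane <- match.arg(plane)
  df <- dplyr::bind_rows(
    manual = tibble::as_tibble(project_curve(manual, plane)),
    automatic = tibble::as_tibble(project_curve(auto, plane)),
    .id = "curve"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$x, colour = .data$curve)) +
    ggplot2::geom_path() +
    ggplot2::labs(
      x = if (plane == "frontal") "Y [mm]" else "Z [mm]",
      y = "X [mm]", colour = NULL,
      title = sprintf("%s plane", plane)
    ) +
    ggplot2::theme_minimal()
}
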