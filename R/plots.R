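#' Plot a cylindrical density profile
#'
#' One trace per bead group along the cylinder axis, the standard
#' cross-section view of a micelle or aggregate.
#'
#' @param object A `density_profile` from [cylinder_density_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_center, y = .data$count,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = sprintf("position along %s axis (Å)",
                  attr(object, "axis") %||% "x"),
      y = "mean beads per bin", colour = NULL,
      title = sprintf("Cylinder density profile (d = %g Å, bin = %g Å)",
                      attr(object, "diameter") %||% 6,
                      attr(object, "bin") %||% 0.5)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an aggregation time series
#'
#' Cluster count and largest aggregate size against time.
#'
#' @param object A tibble from [cluster_timeseries()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_cluster_timeseries <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("time", "n_clusters", "largest_size")],
    c("n_clusters", "largest_size"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ns)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cargo-exposure (SASA) time series
#'
#' @param object A tibble from [sasa_timeseries()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_sasa_timeseries <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$sasa)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)",
                  y = expression("headgroup SASA (" * ring(A)^2 * ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
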