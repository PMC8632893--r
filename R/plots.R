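#' Plot the tool-use-location timeseries of a run
#'
#' Line plot of the number of tool-use locations through time — the run's
#' niche-construction trajectory. Under static trees the curve typically
#' rises and plateaus; with tree turnover it keeps climbing towards the
#' total tree count.
#'
#' @param object A `toolscape_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.toolscape_run <- function(object, ...) {
  ggplot2::ggplot(object$timeseries,
                  ggplot2::aes(x = .data$step, y = .data$n_locations)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time-step", y = "tool-use locations",
                  title = sprintf("%d trees (%s), %d sources, seed %d",
                                  object$config$n_trees,
                                  if (object$config$dynamic_trees)
                                    "dynamic" else "static",
                                  object$config$n_sources, object$seed)) +
    ggplot2::theme_minimal()
}

#' Map the material record of a run
#'
#' Scatter map of every assemblage cell, sized by record count and coloured
#' by whether a usable tool remains, with source positions overplotted —
#' the run's "archaeological survey" view.
#'
#' @param run A `toolscape_run`.
#' @param assemblages Optional precomputed [build_assemblages()] table.
#' @return A ggplot.
#' @export
plot_assemblage_map <- function(run, assemblages = build_assemblages(run)) {
  assemblages$usable <- assemblages$n_usable >= 1
  ggplot2::ggplot(assemblages,
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_total,
                                     colour = .data$usable), alpha = 0.6) +
    ggplot2::geom_point(data = run$sources, shape = 17, size = 2,
                        colour = "black") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#1b9e77", `FALSE` = "#d95f02"),
      name = "usable tool present") +
    ggplot2::scale_size_area(name = "records per cell", max_size = 4) +
    ggplot2::coord_equal(xlim = c(0, run$config$width - 1),
                         ylim = c(0, run$config$height - 1)) +
    ggplot2::labs(x = "x (cells)", y = "y (cells)") +
    ggplot2::theme_minimal()
}

#' Plot distance-decay relationships
#'
#' Two panels worth of data in one scatter: per-cell record counts against
#' nearest-source distance, on a log1p scale, with the fitted exponential
#' decay overlaid.
#'
#' @param object A `toolscape_decay` from [distance_decay()].
#' @param relation `"counts"` or `"mass"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.toolscape_decay <- function(object, relation = c("counts", "mass"),
                                     ...) {
  relation <- match.arg(relation)
  if (relation == "counts") {
    df <- object$data$assemblages
    df$dist <- df$nearest_source_distance
    df$y <- df$n_total
    f <- object$counts
    ylab <- "records per cell (+1, log scale)"
    off <- 1
  } else {
    u <- object$data$usable
    df <- tibble::tibble(
      dist = chebyshev_distance(u$origin_x, u$origin_y, u$x, u$y),
      y = u$mass)
    f <- object$mass
    ylab <- "usable tool mass (g, log scale)"
    off <- 0
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dist, y = .data$y + off)) +
    ggplot2::geom_point(alpha = 0.4, colour = "#555555") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance to source (cells)", y = ylab) +
    ggplot2::theme_minimal()
  if (!f$degenerate) {
    p <- p + ggplot2::geom_function(
      fun = function(d) exp(f$intercept + f$slope * d),
      colour = "#d7301f")
  }
  p
}
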