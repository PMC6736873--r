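#' Plot methods
#'
#' ggplot2 autoplot methods for the package's result types: an axial slice
#' of a fitted segmentation, the SSD matching curve of an age prediction,
#' predicted-versus-nominal ages of a leave-one-out run, a volumetric trend
#' fit, and the median growth curve of an atlas within a structure mask.
#'
#' @param object the fitted object.
#' @param slice axial slice index (default: middle slice).
#' @param ... unused.
#' @return A [ggplot2::ggplot].
#' @name neomyelin-plots
NULL

#' @rdname neomyelin-plots
#' @export
autoplot.mls_em <- function(object, slice = NULL, ...) {
  dm <- dim(object$posteriors)
  slice <- slice %||% ceiling(dm[3] / 2)
  lab <- max_vote(object)
  df <- expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]))
  df$class <- factor(object$classes[lab[, , slice]],
                     levels = object$classes)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s hard labels, slice %d",
                                  object$method, slice)) +
    ggplot2::theme_minimal()
}

#' @rdname neomyelin-plots
#' @export
autoplot.age_prediction <- function(object, ...) {
  ggplot2::ggplot(object$ssd_curve,
                  ggplot2::aes(.data$ga_weeks, .data$ssd)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$predicted_ga,
                        linetype = "dashed") +
    ggplot2::labs(x = "candidate GA (weeks)", y = "SSD",
                  title = sprintf("predicted GA = %.1f weeks",
                                  object$predicted_ga)) +
    ggplot2::theme_minimal()
}

#' @rdname neomyelin-plots
#' @export
autoplot.ga_loo <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$nominal_ga, .data$predicted_ga)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "nominal GA (weeks)", y = "predicted GA (weeks)",
                  title = sprintf("leave-one-out RMSE = %.2f weeks",
                                  attr(object, "rmse_weeks"))) +
    ggplot2::theme_minimal()
}

#' @rdname neomyelin-plots
#' @export
autoplot.trend_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble(x = seq(min(df$x), max(df$x), length.out = 200))
  grid$y <- if (object$model == "exponential") {
    object$a * exp(object$b * grid$x)
  } else {
    object$a + object$b * grid$x
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "GA at scan (weeks)", y = "MLS volume",
                  title = sprintf("%s trend, R^2 = %.2f",
                                  object$model, object$r2)) +
    ggplot2::theme_minimal()
}

#' Median growth curve of an atlas within a structure
#'
#' @param atlas a `growth_atlas`.
#' @param structure_mask logical array on the atlas grid.
#' @param step evaluation step in weeks.
#' @return A [ggplot2::ggplot] of the median voxel probability against GA.
#' @export
plot_growth_curve <- function(atlas, structure_mask, step = 0.1) {
  rng <- atlas$ga_range_weeks
  grid <- seq(rng[1], rng[2], by = step)
  med <- vapply(grid, function(t) {
    median(query_atlas(atlas, t)[structure_mask])
  }, numeric(1))
  ggplot2::ggplot(tibble(ga_weeks = grid, p = med),
                  ggplot2::aes(.data$ga_weeks, .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "GA (weeks)", y = "median P(MLS)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
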