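#' Plot adaptation trajectories
#'
#' Doubling time against cumulative generations for each population, with
#' per-population LOESS smooths.
#'
#' @param trajectories Output of [assemble_trajectories()].
#' @param span,degree LOESS parameters for the displayed smooth.
#' @param max_populations Cap on the number of populations drawn (sampled
#'   deterministically by order) to keep the panel readable.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, span = 0.4, degree = 2,
                              max_populations = 50) {
  pops <- trajectories |> distinct(.data$strain_id, .data$replicate)
  if (nrow(pops) > max_populations) {
    pops <- pops[seq_len(max_populations), ]
    trajectories <- trajectories |>
      semi_join(pops, by = c("strain_id", "replicate"))
  }
  ggplot(trajectories,
         aes(x = .data$cum_generations, y = .data$D_h,
             group = interaction(.data$strain_id, .data$replicate),
             colour = .data$strain_id)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                method.args = list(degree = degree), span = span,
                linewidth = 0.4) +
    guides(colour = "none") +
    labs(x = "Cumulative generations", y = "Doubling time (h)",
         title = "Adaptation trajectories") +
    theme_minimal()
}

#' @describeIn regress_adaptation Scatter of strain adaptation against
#'   preadaptation doubling time with the fitted regression line and its
#'   R^2.
#' @param object An `"adaptation_fit"`.
#' @method autoplot adaptation_fit
#' @export
autoplot.adaptation_fit <- function(object, ...) {
  df <- object$data
  lab <- sprintf("R² = %.2f, slope = %.2f", object$r_squared, object$slope)
  ggplot(df, aes(x = .data$preadaptation_D_h, y = .data[[object$milestone]])) +
    geom_point(alpha = 0.5) +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "firebrick") +
    annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5, label = lab) +
    labs(x = "Preadaptation doubling time (h)",
         y = sprintf("Adaptation %s (h reduction)", object$milestone)) +
    theme_minimal()
}

#' @describeIn fit_diminishing_return Scatter of mutation benefit against
#'   background stress doubling time with the diminishing-return fit.
#' @param object An `"epistasis_fit"`.
#' @method autoplot epistasis_fit
#' @export
autoplot.epistasis_fit <- function(object, ...) {
  df <- object$data
  x_col <- if (object$predictor == "stress_D") "D_stress_bg" else "resistance_bg"
  lab <- sprintf("R² = %.2f, slope = %.2f", object$r_squared, object$slope)
  ggplot(df, aes(x = .data[[x_col]], y = .data$delta_h)) +
    geom_point(alpha = 0.6) +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "firebrick") +
    annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5, label = lab) +
    labs(x = if (object$predictor == "stress_D")
               "Background doubling time under stress (h)"
             else "Background stress deficit (h)",
         y = sprintf("%s benefit (h)", object$class)) +
    theme_minimal()
}

#' Plot a fitted reference surface
#'
#' Tile map of the multiplicative spatial correction (as percent deviation)
#' per plate, a quick visual check of gradient structure.
#'
#' @param surface A `"reference_surface"` from [fit_reference_surface()].
#' @return A ggplot object.
#' @export
plot_reference_surface <- function(surface) {
  facet_keys <- intersect(c("plate_id", "cycle"), names(surface))
  p <- ggplot(surface, aes(x = .data$col, y = .data$row,
                           fill = 100 * (2^.data$offset_log2 - 1))) +
    geom_tile() +
    scale_y_reverse() +
    scale_fill_gradient2(name = "Deviation (%)") +
    labs(x = "Column", y = "Row", title = "Spatial reference surface") +
    theme_minimal()
  if (length(facet_keys) > 0) {
    p <- p + facet_wrap(facet_keys)
  }
  p
}
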