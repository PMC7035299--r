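#' Plot a simulation run
#'
#' Bacterial (solid) and free-phage (dotted) trajectories on a log axis, in
#' densities per mL where the simulated volume is known.
#'
#' @param object A `phage_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phage_run
#' @export
autoplot.phage_run <- function(object, ...) {
  s <- object$series
  per_ml <- object$units == "per_mL"
  scale <- if (per_ml || is.na(object$volume_ml)) 1 else object$volume_ml
  df <- tibble(
    time_h = rep(s$time_h, 2),
    population = c(s$B / scale, s$P / scale),
    species = rep(c("bacteria (B)", "free phages (P)"), each = nrow(s))
  ) %>% filter(is.finite(.data$population))
  floor_val <- max(1e-2, min(df$population[df$population > 0], na.rm = TRUE))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h,
                                   pmax(.data$population, floor_val / 10),
                                   colour = .data$species,
                                   linetype = .data$species)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c("#2166ac", "#b2182b")) +
    ggplot2::scale_linetype_manual(values = c("solid", "dotted")) +
    ggplot2::labs(x = "time (h)",
                  y = if (per_ml) "density (per mL)" else "density (per mL)",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a survival phase diagram
#'
#' Mean bacterial density over the (initial bacteria, initial phage) plane on
#' log axes, faceted by report time, with the mean-nutrient = K contour
#' overlaid.
#'
#' @param object A `survival_grid` from [phase_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot survival_grid
#' @export
autoplot.survival_grid <- function(object, ...) {
  df <- object %>%
    group_by(.data$b0, .data$p0, .data$time_h) %>%
    summarise(mean_B = mean(.data$mean_B), .groups = "drop")
  contour <- nutrient_contour(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$b0, .data$p0,
                                         fill = log10(pmax(.data$mean_B, 1)))) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "log10 B/mL") +
    ggplot2::facet_wrap(~time_h, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "initial bacteria (per mL)",
                  y = "initial phages (per mL)") +
    ggplot2::theme_minimal()
  if (any(is.finite(contour$p0_at_K)))
    gg <- gg + ggplot2::geom_line(
      data = dplyr::filter(contour, is.finite(.data$p0_at_K)),
      ggplot2::aes(.data$b0, .data$p0_at_K), colour = "red",
      inherit.aes = FALSE)
  gg
}

#' Plot a plate experiment
#'
#' Visible-colony fraction against phage spray time, one line per penetration
#' depth plus the protection-off control, with binomial standard-error
#' ribbons.
#'
#' @param object A `plate_result` from [plate_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plate_result
#' @export
autoplot.plate_result <- function(object, ...) {
  df <- object %>%
    mutate(condition = ifelse(.data$protection,
                              paste0("zeta = ", .data$zeta), "control"))
  ggplot2::ggplot(df, ggplot2::aes(.data$spray_time, .data$visible_fraction,
                                   colour = .data$condition)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(0, .data$visible_fraction - .data$standard_error),
                   ymax = pmin(1, .data$visible_fraction + .data$standard_error),
                   fill = .data$condition), alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "phage spray time (h)", y = "fraction of visible colonies",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
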