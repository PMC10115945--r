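#' Plot a daily glucose trace
#'
#' Glucose over the scored day with the ADA reference zones shaded: the
#' 80-130 mg/dL preprandial band and the 180 mg/dL postprandial ceiling.
#'
#' @param trace a `glycemic_trace`.
#' @return a ggplot object.
#' @export
plot_trace <- function(trace) {
  df <- as.data.frame(trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min / 60,
                                   y = .data$glucose_mg_dl)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 80, ymax = 130,
                      alpha = 0.15, fill = "grey40") +
    ggplot2::geom_hline(yintercept = 180, colour = "darkgreen",
                        linetype = 2) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "hour of day", y = "plasma glucose (mg/dL)",
                  title = attr(trace, "patient_name")) +
    ggplot2::theme_minimal()
}

#' Plot the fitness history of an optimization run
#'
#' @param history the `history` data.frame of an [evolve_plans()] result.
#' @return a ggplot object.
#' @export
plot_fitness_history <- function(history) {
  ggplot2::ggplot(history, ggplot2::aes(x = .data$generation,
                                        y = .data$best_fitness)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "generation", y = "best fitness") +
    ggplot2::theme_minimal()
}

#' Plot the insulin-dose history of an optimization run
#'
#' Basal (U/h) and total prandial (U) doses of the generation-best plan.
#'
#' @inheritParams plot_fitness_history
#' @return a ggplot object.
#' @export
plot_dose_history <- function(history) {
  df <- rbind(
    data.frame(generation = history$generation, dose = history$basal_U_per_h,
               which = "basal (U/h)"),
    data.frame(generation = history$generation,
               dose = history$prandial_U_total, which = "prandial (U/day)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$dose,
                                   colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c("steelblue", "firebrick")) +
    ggplot2::labs(x = "generation", y = "insulin dose", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot time-in-range band occupancy
#'
#' Stacked percentage of the day in each glucose band, optionally across
#' several scored days (for example one per optimization scenario).
#'
#' @param metrics a [compute_day_metrics()] result, or a named list of them.
#' @return a ggplot object.
#' @export
plot_tir <- function(metrics) {
  if (inherits(metrics, "day_metrics")) metrics <- list(day = metrics)
  df <- do.call(rbind, lapply(names(metrics), function(nm) {
    data.frame(run = nm, band = factor(names(metrics[[nm]]$tir),
                                       levels = rev(c("below_80", "in_80_130",
                                                      "in_130_180",
                                                      "above_180"))),
               fraction = as.numeric(metrics[[nm]]$tir))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$run, y = 100 * .data$fraction,
                                   fill = .data$band)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(below_80 = "#d73027",
                                          in_80_130 = "#91bfdb",
                                          in_130_180 = "#fee090",
                                          above_180 = "#fc8d59")) +
    ggplot2::labs(x = NULL, y = "% of day", fill = "glucose band") +
    ggplot2::theme_minimal()
}
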