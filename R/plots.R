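# ggplot2 methods for the package's result types.

#' Plot a grid world
#'
#' @param object An `animat_world`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.animat_world <- function(object, ...) {
  df <- tidy(object)
  df$fill <- ifelse(df$type == "gate", ifelse(df$rewarding, "rewarding gate", "gate"),
                    ifelse(df$start_slot, "start slot", df$type))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$fill)) +
    ggplot2::geom_tile(color = "grey80", linewidth = 0.1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(
      "wall" = "grey20", "empty" = "white", "start slot" = "steelblue",
      "rewarding gate" = "forestgreen", "gate" = "orange")) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$name, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot fitness evolution across generations
#'
#' @param object An `animat_lineage`.
#' @param ... Unused.
#' @return A ggplot of mean and best fitness per generation.
#' @export
autoplot.animat_lineage <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object),
                            c("mean_fitness", "best_fitness"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "fitness F", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a task-fitness sweep
#'
#' @param object A `task_fitness_table`.
#' @param ... Unused.
#' @return A ggplot of TF against group size, faceted by condition.
#' @export
autoplot.task_fitness_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group_size, y = .data$TF,
                                       color = .data$setup)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "group size", y = "task fitness <TF>", color = "setup") +
    ggplot2::theme_minimal()
}

#' Plot a behavior profile
#'
#' @param object A `behavior_profile`.
#' @param ... Unused.
#' @return A stacked-area ggplot of action fractions across group sizes.
#' @export
autoplot.behavior_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group_size, y = .data$fraction,
                                       fill = .data$action)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "group size", y = "share of animat-timesteps", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an occupancy heat map
#'
#' @param object An `occupancy_map`.
#' @param ... Unused.
#' @return A ggplot heat map of mean occupancy per cell.
#' @export
autoplot.occupancy_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$occupancy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "lightyellow", high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "occupancy") +
    ggplot2::theme_minimal()
}
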