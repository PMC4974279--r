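#' Plot a spike-density curve
#'
#' Mean rate against distance from the screen, with a +/- SEM ribbon when
#' the curve is a trial average. The x axis is reversed so that the
#' approach reads left to right, matching how the trials unfold.
#'
#' @param object A `density_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.density_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$distance_mm,
                                    y = .data$rate_hz))
  if ("sem_hz" %in% names(object) && !all(is.na(object$sem_hz))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$rate_hz - .data$sem_hz,
                   ymax = .data$rate_hz + .data$sem_hz),
      alpha = 0.25)
  }
  p + ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Distance from screen (mm)",
                  y = "Mean spike rate (Hz)")
}

#' Plot the averaged curves of a classified neuron
#'
#' Overlays the trial-averaged density curves per grating with vertical
#' marks at each maximum.
#'
#' @param object A `neuron_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.neuron_classification <- function(object, ...) {
  if (is.null(object$avg_curves)) {
    abort("No curves stored for this classification.",
          class = "approachscan_invalid_argument")
  }
  df <- purrr::imap_dfr(object$avg_curves, function(cv, lb) {
    tibble::tibble(label = lb, distance_mm = cv$distance_mm,
                   rate_hz = cv$rate_hz)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_mm,
                                   y = .data$rate_hz,
                                   colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = object$maxima,
                        ggplot2::aes(xintercept = .data$distance_mm,
                                     colour = .data$label),
                        linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Distance from screen (mm)",
                  y = "Mean spike rate (Hz)", colour = "Grating",
                  title = sprintf("%s: %s", object$neuron_id,
                                  object$label))
}

#' Plot the population shift distribution
#'
#' Classified neurons' shift values sorted in ascending order, coloured by
#' label, with the constant/shifting thresholds drawn as horizontal lines —
#' the standard way to display the two-cluster structure of the shift
#' distribution.
#'
#' @param object A `population_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.population_summary <- function(object, ...) {
  df <- object$neurons[object$neurons$label %in%
                         c("constant", "shifting", "unclassified"), ]
  df <- df[order(df$mean_pairwise_shift_pct), ]
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                   y = .data$mean_pairwise_shift_pct,
                                   colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(object$cfg$constant_threshold_pct,
                                       object$cfg$shifting_threshold_pct),
                        linetype = "dotted") +
    ggplot2::labs(x = "Neuron (sorted by shift)", y = "Shift (%)",
                  colour = "Class")
}

#' Plot a coding population
#'
#' Tuning curves of all cells against distance.
#'
#' @param object A `coding_population`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coding_population <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            -"distance_mm",
                            names_to = "cell", values_to = "rate_hz")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_mm,
                                   y = .data$rate_hz,
                                   colour = .data$cell)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Distance from screen (mm)", y = "Rate (Hz)",
                  colour = "Cell")
}
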