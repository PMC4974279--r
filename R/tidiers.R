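#' Tidy a shift result
#'
#' @param x A `shift_result`.
#' @param ... Unused.
#' @return The all-pairs shift tibble (`m1_mm`, `m2_mm`, `shift_pct`).
#' @exportS3Method generics::tidy
tidy.shift_result <- function(x, ...) {
  x$pairs
}

#' @rdname tidy.shift_result
#' @return For `glance()`: a one-row summary tibble.
#' @exportS3Method generics::glance
glance.shift_result <- function(x, ...) {
  tibble::tibble(
    m1_mm = x$m1_mm, m2_mm = x$m2_mm, shift_pct = x$shift_pct,
    mean_pairwise_shift_pct = x$mean_pairwise_shift_pct,
    frac_above_shifting = x$frac_above_shifting,
    frac_below_constant = x$frac_below_constant,
    n_pairs = x$n_pairs, p_sign = x$p_sign, class_label = x$class_label
  )
}

#' Tidy a neuron classification
#'
#' @param x A `neuron_classification`.
#' @param ... Unused.
#' @return `tidy()`: the per-grating maxima tibble; `glance()`: a one-row
#'   summary with the label, the averaged maxima and the shift statistics.
#' @exportS3Method generics::tidy
tidy.neuron_classification <- function(x, ...) {
  x$maxima %||% tibble::tibble()
}

#' @rdname tidy.neuron_classification
#' @exportS3Method generics::glance
glance.neuron_classification <- function(x, ...) {
  get_max <- function(lb) {
    if (is.null(x$maxima)) return(NA_real_)
    v <- x$maxima$distance_mm[x$maxima$label == lb]
    if (length(v)) v else NA_real_
  }
  s <- x$shift
  tibble::tibble(
    neuron_id = x$neuron_id,
    label = x$label,
    m1_mm = get_max("1F"),
    m2_mm = get_max("2F"),
    shift_pct = if (!is.null(s)) s$shift_pct else NA_real_,
    mean_pairwise_shift_pct =
      if (!is.null(s)) s$mean_pairwise_shift_pct else NA_real_,
    n_pairs = if (!is.null(s)) s$n_pairs else NA_integer_,
    p_sign = if (!is.null(s)) s$p_sign else NA_real_,
    shift_2f_3f_pct = x$shift_2f_3f_pct,
    truth = x$truth %||% NA_character_
  )
}

#' Tidy a population summary
#'
#' @param x A `population_summary`.
#' @param ... Unused.
#' @return `tidy()`: the per-neuron tibble; `glance()`: the count table
#'   with the pooled Lilliefors p-value and per-cluster shift means/SDs
#'   appended.
#' @exportS3Method generics::tidy
tidy.population_summary <- function(x, ...) {
  x$neurons
}

#' @rdname tidy.population_summary
#' @exportS3Method generics::glance
glance.population_summary <- function(x, ...) {
  cl <- x$normality$clusters
  below <- cl[cl$cluster == "below_50", ]
  above <- cl[cl$cluster == "above_50", ]
  dplyr::bind_cols(
    x$counts,
    tibble::tibble(
      pooled_lilliefors_p = x$normality$pooled_p,
      constant_cluster_mean_pct = below$mean_shift_pct,
      constant_cluster_sd_pct = below$sd_shift_pct,
      constant_cluster_lilliefors_p = below$lilliefors_p,
      shifting_cluster_mean_pct = above$mean_shift_pct,
      shifting_cluster_sd_pct = above$sd_shift_pct,
      shifting_cluster_lilliefors_p = above$lilliefors_p
    )
  )
}
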