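#' Boundary and outlier rules for response maxima
#'
#' Applied after both gratings' maxima pass the significance test, with the
#' trial-averaged maxima `m1` (1F), `m2` (2F), and all available maxima
#' `m_all` (including 3F when present):
#'
#' * all maxima within `tol` of the end (closest) distance →
#'   `constant_at_min_distance`: the cell's rate rises monotonically toward
#'   the screen; its constant maximum sits at (or beyond) the minimal
#'   distance of the track;
#' * otherwise, 1F maximum within `tol` of the start (farthest) distance:
#'   the 1F response only decreases along the track so its true maximum is
#'   unresolvable — `outlier_excluded` if the 2F maximum is closer than
#'   half the start distance (its implied 1F position lies beyond the
#'   track), else `monotonic_far_excluded` (a constant maximum beyond the
#'   far end cannot be ruled out, nor can a shifting one);
#' * otherwise `NULL` (no boundary rule fires).
#'
#' @param m1_mm,m2_mm Trial-averaged maximum distances for 1F and 2F.
#' @param m_all_mm All per-grating maximum distances.
#' @param protocol The [protocol()] of the recording.
#' @param tol Boundary tolerance in mm (one window span by default upstream).
#' @return A label string or `NULL`.
#' @export
classify_boundary <- function(m1_mm, m2_mm, m_all_mm, protocol, tol) {
  if (all(m_all_mm <= protocol$end_distance_mm + tol)) {
    return("constant_at_min_distance")
  }
  if (m1_mm >= protocol$start_distance_mm - tol) {
    if (m2_mm < protocol$start_distance_mm / 2) {
      return("outlier_excluded")
    }
    return("monotonic_far_excluded")
  }
  NULL
}

#' Classify one neuron
#'
#' Runs the full per-neuron analysis: (1) per-trial spike-density curves
#' for each grating (excluded trials dropped first); (2) trial-averaged
#' curve and its maximum per grating; (3) bootstrap significance of each
#' maximum — any non-significant grating stops the analysis at
#' `nonsignificant`; (4) boundary/outlier rules ([classify_boundary()]);
#' (5) the all-pairs shift distribution from per-trial maxima and the
#' sign-test classification ([classify_shift()]).
#'
#' When a 3F grating is present, classification still uses 1F vs 2F; the
#' 2F-vs-3F shift is computed as a consistency check (a frequency-tuned
#' cell predicts 50%: `M3 = (2/3) M2`) and reported in the notes.
#'
#' @param rec A `neuron_recording`.
#' @param cfg An [analysis_config()].
#' @param seed Integer seed for the bootstrap; `NULL` uses the current RNG.
#' @return An object of class `neuron_classification`: a list with
#'   `neuron_id`, `label`, `maxima` (per-grating tibble), `avg_curves`,
#'   `shift` (a `shift_result` or `NULL`), `shift_2f_3f_pct` and `notes`.
#' @examples
#' \donttest{
#' rec <- simulate_recording(neuron_model("distance_tuned",
#'                                        optimal_distance_mm = 2200),
#'                           seed = 1)
#' cl <- classify_neuron(rec, analysis_config(step_s = 0.1,
#'                                            bootstrap_n = 200), seed = 2)
#' glance(cl)
#' }
#' @export
classify_neuron <- function(rec, cfg = analysis_config(), seed = NULL) {
  stopifnot(inherits(rec, "neuron_recording"))
  run <- function() classify_neuron_impl(rec, cfg)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

classify_neuron_impl <- function(rec, cfg) {
  trials <- rec$trials[!rec$trials$excluded, ]
  labels <- unique(rec$trials$label)
  if (!all(c("1F", "2F") %in% labels)) {
    abort("Recording must contain 1F and 2F trials.",
          class = "approachscan_invalid_argument")
  }
  notes <- character(0)
  out <- function(label, maxima = NULL, avg = NULL, shift = NULL,
                  shift23 = NA_real_) {
    structure(
      list(neuron_id = rec$neuron_id, label = label, maxima = maxima,
           avg_curves = avg, shift = shift, shift_2f_3f_pct = shift23,
           truth = rec$metadata$archetype, notes = notes),
      class = "neuron_classification"
    )
  }
  n_by_label <- table(trials$label)
  if (any(n_by_label[c("1F", "2F")] < cfg$min_trials) ||
      anyNA(n_by_label[c("1F", "2F")])) {
    notes <- sprintf("fewer than %d non-excluded trials per grating",
                     cfg$min_trials)
    return(out("rejected"))
  }

  per_grating <- lapply(split(trials, trials$label), function(tr) {
    curves <- lapply(tr$spike_times_s, spike_density,
                     trajectory = rec$trajectory, cfg = cfg)
    avg <- average_density(curves)
    boot <- bootstrap_max_significance(curves, cfg)
    trial_max <- vapply(curves, function(cv) find_maximum(cv, cfg)$distance_mm,
                        numeric(1))
    list(avg = avg, boot = boot, trial_max = trial_max, n = nrow(tr))
  })
  labs <- intersect(c("1F", "2F", "3F"), names(per_grating))
  per_grating <- per_grating[labs]
  maxima <- purrr::map_dfr(labs, function(lb) {
    b <- per_grating[[lb]]$boot
    tibble::tibble(label = lb, distance_mm = b$distance_mm,
                   rate_hz = b$rate_hz, significant = b$significant,
                   null_upper_hz = b$null_upper_hz,
                   n_trials = per_grating[[lb]]$n)
  })
  avg_curves <- purrr::map(per_grating, "avg")

  shift23 <- NA_real_
  if ("3F" %in% labs && isTRUE(maxima$significant[maxima$label == "3F"]) &&
      !is.na(maxima$distance_mm[maxima$label == "2F"])) {
    shift23 <- shift_statistic(maxima$distance_mm[maxima$label == "2F"],
                               maxima$distance_mm[maxima$label == "3F"])
    notes <- c(notes, sprintf("2F vs 3F consistency shift: %.1f%%", shift23))
  }

  if (!all(maxima$significant[maxima$label %in% c("1F", "2F")])) {
    return(out("nonsignificant", maxima, avg_curves, shift23 = shift23))
  }

  m1 <- maxima$distance_mm[maxima$label == "1F"]
  m2 <- maxima$distance_mm[maxima$label == "2F"]
  sig_labs <- maxima$label[maxima$significant %in% TRUE]
  boundary <- classify_boundary(
    m1, m2, maxima$distance_mm[maxima$label %in% sig_labs],
    rec$protocol, boundary_tolerance(cfg, rec$protocol))
  if (!is.null(boundary)) {
    return(out(boundary, maxima, avg_curves, shift23 = shift23))
  }

  m1_trials <- per_grating[["1F"]]$trial_max
  m2_trials <- per_grating[["2F"]]$trial_max
  keep1 <- is.finite(m1_trials)
  keep2 <- is.finite(m2_trials)
  if (!all(keep1) || !all(keep2)) {
    notes <- c(notes, "trials with undefined maxima dropped from the pairs")
  }
  sr <- classify_shift(m1_trials[keep1], m2_trials[keep2], cfg,
                       m1_mm = m1, m2_mm = m2)
  out(sr$class_label, maxima, avg_curves, shift = sr, shift23 = shift23)
}

#' @export
print.neuron_classification <- function(x, ...) {
  cat(sprintf("<neuron_classification '%s'> %s\n", x$neuron_id, x$label))
  if (!is.null(x$maxima)) print(x$maxima)
  if (!is.null(x$shift)) print(x$shift)
  invisible(x)
}

#' Run the population analysis
#'
#' Classifies every recording, assembles the per-neuron table, the
#' category counts, the classified-shift distribution with its normality
#' and cluster structure, and the constant-maximum position list.
#' Constant-maximum positions are the per-cell means of the per-grating
#' maxima; cells monotonically rising toward the screen
#' (`constant_at_min_distance`) are listed at the track's end distance and
#' flagged. The expected number of neurons passing both significance tests
#' by chance, `n * (1 - conf)^2`, is reported alongside the counts.
#'
#' @param recordings A list of `neuron_recording`s.
#' @param cfg An [analysis_config()].
#' @param seed Integer seed governing every bootstrap; same seed, same
#'   report.
#' @return An object of class `population_summary` with elements `neurons`
#'   (per-neuron tibble), `counts` (one-row tibble), `normality`
#'   ([normality_and_clusters()] output), `constant_positions` (tibble),
#'   and `classifications` (the full per-neuron objects).
#' @export
run_population <- function(recordings, cfg = analysis_config(),
                           seed = NULL) {
  if (inherits(recordings, "neuron_recording")) {
    recordings <- list(recordings)
  }
  if (length(recordings) < 1) {
    abort("Need at least one recording.",
          class = "approachscan_invalid_argument")
  }
  run <- function() lapply(recordings, classify_neuron, cfg = cfg)
  cls <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  neurons <- purrr::map_dfr(cls, glance)
  n_of <- function(lbl) sum(neurons$label == lbl)
  counts <- tibble::tibble(
    studied = nrow(neurons),
    rejected = n_of("rejected"),
    nonsignificant = n_of("nonsignificant"),
    constant_at_min_distance = n_of("constant_at_min_distance"),
    monotonic_far_excluded = n_of("monotonic_far_excluded"),
    outlier_excluded = n_of("outlier_excluded"),
    constant = n_of("constant"),
    shifting = n_of("shifting"),
    unclassified = n_of("unclassified"),
    significant_both = n_of("constant") + n_of("shifting") +
      n_of("unclassified"),
    expected_chance_significant = nrow(neurons) * (1 - cfg$conf_level)^2
  )

  classified <- neurons[neurons$label %in%
                          c("constant", "shifting", "unclassified"), ]
  const_rows <- neurons[neurons$label == "constant", ]
  const_pos <- tibble::tibble(
    neuron_id = const_rows$neuron_id,
    position_mm = (const_rows$m1_mm + const_rows$m2_mm) / 2,
    at_min_distance = FALSE
  )
  min_rows <- neurons[neurons$label == "constant_at_min_distance", ]
  if (nrow(min_rows)) {
    ends <- vapply(recordings[match(min_rows$neuron_id,
                                    neurons$neuron_id)],
                   function(r) r$protocol$end_distance_mm, numeric(1))
    const_pos <- dplyr::bind_rows(
      const_pos,
      tibble::tibble(neuron_id = min_rows$neuron_id, position_mm = ends,
                     at_min_distance = TRUE))
  }
  # population shift distribution: each cell is represented by its mean
  # pairwise shift, the estimator the sign-test classification assesses
  # (averaging the n1 x n2 trial pairs is far less noisy than the single
  # ratio of the two averaged-curve argmaxes, which is reported alongside)
  normality <- normality_and_clusters(
    classified$mean_pairwise_shift_pct,
    positions_mm = const_pos$position_mm[!const_pos$at_min_distance])

  structure(
    list(neurons = neurons, counts = counts, normality = normality,
         constant_positions = const_pos, classifications = cls,
         cfg = cfg),
    class = "population_summary"
  )
}

#' @export
print.population_summary <- function(x, ...) {
  cat("<population_summary>\n")
  print(x$counts)
  cat(sprintf("pooled Lilliefors p = %.3g\n", x$normality$pooled_p))
  print(x$normality$clusters)
  invisible(x)
}
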