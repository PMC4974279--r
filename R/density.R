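#' Analysis configuration
#'
#' Collects the constants of the per-neuron analysis: the spike-density
#' smoothing window (20 s, stepped by 0.01 s), the bootstrap settings for
#' maximum significance (1000 resamples, 95% confidence), the shift
#' classification thresholds (constant below 30%, shifting above 70%) with
#' the sign-test level, and the boundary tolerance used by the
#' boundary/outlier rules.
#'
#' @param window_s Sliding-window length in seconds, default 20.
#' @param step_s Window step in seconds, default 0.01.
#' @param bootstrap_n Number of bootstrap resamples, default 1000.
#' @param conf_level Confidence level for maximum significance, default 0.95.
#' @param constant_threshold_pct Mean-shift threshold below which a cell can
#'   be called constant, default 30.
#' @param shifting_threshold_pct Mean-shift threshold above which a cell can
#'   be called shifting, default 70.
#' @param alpha Sign-test level, default 0.05.
#' @param min_trials Minimum non-excluded trials per grating, default 6.
#' @param min_pairs Minimum trial pairs for the sign test, default 5.
#' @param boundary_tolerance_mm Margin for declaring a maximum "at the
#'   boundary"; `NULL` (default) means one smoothing-window span on the
#'   distance axis (`window_s * speed`, i.e. 200 mm for the distant
#'   protocol, 34 mm for near space) — a maximum cannot be localised more
#'   finely than the window.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(window_s = 20, step_s = 0.01,
                            bootstrap_n = 1000, conf_level = 0.95,
                            constant_threshold_pct = 30,
                            shifting_threshold_pct = 70,
                            alpha = 0.05, min_trials = 6, min_pairs = 5,
                            boundary_tolerance_mm = NULL) {
  check_positive(window_s, "window_s")
  check_positive(step_s, "step_s")
  if (step_s > window_s) {
    abort("`step_s` must not exceed `window_s`.",
          class = "approachscan_invalid_argument")
  }
  check_number(conf_level, "conf_level", 0, 1, strict_lower = TRUE)
  if (conf_level >= 1) {
    abort("`conf_level` must be < 1.",
          class = "approachscan_invalid_argument")
  }
  if (constant_threshold_pct >= shifting_threshold_pct) {
    abort("`constant_threshold_pct` must be below `shifting_threshold_pct`.",
          class = "approachscan_invalid_argument")
  }
  check_number(alpha, "alpha", 0, 1, strict_lower = TRUE)
  structure(
    list(window_s = window_s, step_s = step_s, bootstrap_n = bootstrap_n,
         conf_level = conf_level,
         constant_threshold_pct = constant_threshold_pct,
         shifting_threshold_pct = shifting_threshold_pct,
         alpha = alpha, min_trials = min_trials, min_pairs = min_pairs,
         boundary_tolerance_mm = boundary_tolerance_mm),
    class = "analysis_config"
  )
}

boundary_tolerance <- function(cfg, protocol) {
  cfg$boundary_tolerance_mm %||% (cfg$window_s * protocol$speed_mm_s)
}

# Window centres over the approach phase, identical for every trial of one
# protocol so that maxima are comparable across trials and gratings.
window_centers <- function(protocol, cfg) {
  t0 <- protocol$dwell_start_s
  t1 <- protocol$dwell_start_s + approach_duration_s(protocol)
  centers <- seq(t0, t1, by = cfg$step_s)
  if (centers[length(centers)] < t1 - 1e-9) centers <- c(centers, t1)
  centers
}

#' Spike-density curve of one trial
#'
#' Estimates the firing rate along the approach with a sliding rectangular
#' (boxcar) window of `cfg$window_s` seconds stepped every `cfg$step_s`
#' seconds: at each window centre, the spike count inside the window
#' (intersected with the trial span) is divided by the covered duration
#' (edge truncation). Window centres are restricted to the approach phase
#' and mapped to distance via the trajectory, so curves from all trials of
#' one protocol share an identical grid.
#'
#' @param spike_times_s Sorted spike times in seconds (may be empty).
#' @param trajectory A [build_trajectory()] tibble.
#' @param cfg An [analysis_config()].
#' @return A tibble of class `density_curve` with columns `time_s`,
#'   `distance_mm`, `rate_hz` (and attribute `n_trials = 1`).
#' @examples
#' traj <- build_trajectory(protocol_near(dwell_start_s = 5, dwell_end_s = 5))
#' curve <- spike_density(c(100, 101, 102.5), traj,
#'                        analysis_config(step_s = 1))
#' @export
spike_density <- function(spike_times_s, trajectory, cfg = analysis_config()) {
  stopifnot(inherits(trajectory, "trajectory"))
  p <- trajectory_protocol(trajectory)
  spikes <- sort(as.numeric(spike_times_s))
  t_end <- max(trajectory$time_s)
  if (length(spikes) && (spikes[1] < 0 || spikes[length(spikes)] > t_end)) {
    abort("Spike times must lie within the trial span.",
          class = "approachscan_invalid_argument")
  }
  centers <- window_centers(p, cfg)
  lo <- pmax(centers - cfg$window_s / 2, 0)
  hi <- pmin(centers + cfg$window_s / 2, t_end)
  counts <- findInterval(hi, spikes) - findInterval(lo, spikes)
  out <- tibble::tibble(
    time_s = centers,
    distance_mm = distance_at(trajectory, centers),
    rate_hz = counts / (hi - lo)
  )
  class(out) <- c("density_curve", class(out))
  attr(out, "n_trials") <- 1L
  out
}

# Density curve of one trial row of a recording; refuses excluded trials.
trial_density <- function(rec, trial_index, cfg = analysis_config()) {
  stopifnot(inherits(rec, "neuron_recording"))
  i <- match(trial_index, rec$trials$trial_index)
  if (is.na(i)) {
    abort("Unknown trial index.", class = "approachscan_invalid_argument")
  }
  if (rec$trials$excluded[i]) {
    abort(sprintf("Trial %d is excluded (%s) and has no density curve.",
                  trial_index, rec$trials$exclusion_reason[i]),
          class = "approachscan_excluded_trial")
  }
  spike_density(rec$trials$spike_times_s[[i]], rec$trajectory, cfg)
}

density_grid_identical <- function(curves) {
  ref <- curves[[1]]$time_s
  all(vapply(curves, function(cv) {
    length(cv$time_s) == length(ref) && all(abs(cv$time_s - ref) < 1e-9)
  }, logical(1)))
}

density_matrix <- function(curves) {
  vapply(curves, function(cv) cv$rate_hz, numeric(nrow(curves[[1]])))
}

#' Average spike-density curves across trials
#'
#' Pointwise mean of per-trial density curves on a common grid, with the
#' per-window standard error of the mean.
#'
#' @param curves A list of `density_curve` tibbles sharing one grid.
#' @return A `density_curve` tibble with columns `time_s`, `distance_mm`,
#'   `rate_hz`, `sem_hz` and attribute `n_trials`. With a single curve the
#'   SEM is `NA`.
#' @export
average_density <- function(curves) {
  if (inherits(curves, "density_curve")) curves <- list(curves)
  if (length(curves) < 1) {
    abort("Need at least one curve.",
          class = "approachscan_invalid_argument")
  }
  if (!density_grid_identical(curves)) {
    abort("Density curves are not on a common grid.",
          class = "approachscan_invalid_argument")
  }
  k <- length(curves)
  m <- density_matrix(curves)
  mean_rate <- rowMeans(m)
  sem <- if (k > 1) {
    sqrt(rowSums((m - mean_rate)^2) / (k - 1)) / sqrt(k)
  } else {
    rep(NA_real_, length(mean_rate))
  }
  out <- tibble::tibble(
    time_s = curves[[1]]$time_s,
    distance_mm = curves[[1]]$distance_mm,
    rate_hz = mean_rate,
    sem_hz = sem
  )
  class(out) <- c("density_curve", class(out))
  attr(out, "n_trials") <- k
  out
}

#' Locate the response maximum of a density curve
#'
#' Global argmax of the rate over the approach-phase grid. Ties are broken
#' toward the farthest distance (the window reached first in time, least
#' contaminated by retinal drift). A completely flat curve is flagged
#' degenerate; an all-zero curve additionally gets an undefined (`NA`)
#' location and is marked non-significant outright. The `significant` flag
#' is otherwise left `NA` until filled by [bootstrap_max_significance()].
#'
#' @param curve A `density_curve`.
#' @param cfg An [analysis_config()] (reserved; the location itself needs no
#'   tuning constants).
#' @return A one-row tibble of class `maximum_estimate` with columns
#'   `distance_mm`, `rate_hz`, `significant`, `degenerate`, `null_upper_hz`.
#' @export
find_maximum <- function(curve, cfg = analysis_config()) {
  stopifnot(inherits(curve, "density_curve"))
  if (nrow(curve) == 0) {
    abort("Empty density curve.", class = "approachscan_invalid_argument")
  }
  r <- curve$rate_hz
  flat <- diff(range(r)) == 0
  if (flat && max(r) == 0) {
    out <- tibble::tibble(distance_mm = NA_real_, rate_hz = 0,
                          significant = FALSE, degenerate = TRUE,
                          null_upper_hz = NA_real_)
  } else {
    ties <- which(r == max(r))
    # distance decreases along the grid, so the first index is the farthest
    i <- ties[which.max(curve$distance_mm[ties])]
    # exact ties between overlapping windows are routine for count data;
    # only warn for tied peaks of an averaged curve further apart than one
    # window (genuinely distinct response maxima)
    n_tr <- attr(curve, "n_trials") %||% 2L
    spread <- diff(range(curve$time_s[ties]))
    if (!flat && n_tr > 1 && length(ties) > 1 && spread > cfg$window_s) {
      warn("Multiple equal, separated maxima; farthest distance chosen.")
    }
    out <- tibble::tibble(distance_mm = curve$distance_mm[i],
                          rate_hz = r[i],
                          significant = NA, degenerate = flat,
                          null_upper_hz = NA_real_)
  }
  class(out) <- c("maximum_estimate", class(out))
  out
}
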