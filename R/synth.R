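#' Archetypal neuron model for simulation
#'
#' Parameterises the firing-rate archetypes that the approach paradigm is
#' designed to separate:
#'
#' * `sf_tuned` — classical spatial-frequency tuning: a log-Gaussian tuning
#'   curve (in octaves) over the retinal spatial frequency that the grating
#'   attains at the current distance. Its response maximum moves when the
#'   grating period changes.
#' * `distance_tuned` — absolute-distance tuning: a Gaussian bump over
#'   physical distance, identical for every grating.
#' * `monotonic_near` / `monotonic_far` — rate rises monotonically toward
#'   the screen / toward the far end (logistic in distance), with no
#'   interior maximum on the track.
#' * `nonresponsive` — constant baseline rate.
#'
#' All archetypes share a baseline (ongoing) rate and a peak rate added at
#' the optimum, plus a slowly varying multiplicative gain ("free-gaze"
#' surrogate) applied during spike simulation, see [simulate_recording()].
#'
#' @param archetype One of `"sf_tuned"`, `"distance_tuned"`,
#'   `"monotonic_near"`, `"monotonic_far"`, `"nonresponsive"`.
#' @param baseline_rate_hz Ongoing rate in Hz (>= 0). Default 3, consistent
#'   with the low ongoing activity typical of these cells.
#' @param peak_rate_hz Rate added at the optimum (>= 0). Default 15
#'   (peak/baseline ratio 5).
#' @param optimal_sf_cpd Preferred spatial frequency in cycles/degree
#'   (`sf_tuned`). Default 0.7, the mode reported for central cat V1.
#' @param sf_bandwidth_oct Tuning standard deviation in octaves
#'   (`sf_tuned`). Default 0.5, i.e. a full width at half maximum of about
#'   1.2 octaves, the typical bandwidth of central V1 cells.
#' @param sf_range_cpd Plausible range for `optimal_sf_cpd`; default
#'   c(0.25, 2), the range reported for central cat V1.
#' @param optimal_distance_mm Preferred distance (`distance_tuned`).
#' @param distance_sigma_mm Distance tuning width (`distance_tuned`).
#' @param half_distance_mm Logistic midpoint for the monotonic archetypes.
#' @param logistic_width_mm Logistic width (mm) for the monotonic
#'   archetypes.
#' @param rate_jitter_cv Coefficient of variation of the slowly varying
#'   multiplicative rate gain. Default 0.15.
#' @param eye [eye_model()] used to convert distance to spatial frequency.
#' @return An object of class `neuron_model`.
#' @examples
#' m <- neuron_model("sf_tuned", optimal_sf_cpd = 0.7)
#' rate_function(m, 38, c(2500, 1524, 800))
#' @export
neuron_model <- function(archetype = c("sf_tuned", "distance_tuned",
                                       "monotonic_near", "monotonic_far",
                                       "nonresponsive"),
                         baseline_rate_hz = 3, peak_rate_hz = 15,
                         optimal_sf_cpd = 0.7, sf_bandwidth_oct = 0.5,
                         sf_range_cpd = c(0.25, 2),
                         optimal_distance_mm = 1500,
                         distance_sigma_mm = 250,
                         half_distance_mm = 500,
                         logistic_width_mm = 150,
                         rate_jitter_cv = 0.15,
                         eye = eye_model()) {
  archetype <- match.arg(archetype)
  check_nonnegative(baseline_rate_hz, "baseline_rate_hz")
  check_nonnegative(peak_rate_hz, "peak_rate_hz")
  check_nonnegative(rate_jitter_cv, "rate_jitter_cv")
  if (archetype == "sf_tuned") {
    check_positive(optimal_sf_cpd, "optimal_sf_cpd")
    check_positive(sf_bandwidth_oct, "sf_bandwidth_oct")
    if (optimal_sf_cpd < sf_range_cpd[1] || optimal_sf_cpd > sf_range_cpd[2]) {
      abort(sprintf("`optimal_sf_cpd` outside the plausible range [%g, %g].",
                    sf_range_cpd[1], sf_range_cpd[2]),
            class = "approachscan_invalid_argument")
    }
  }
  if (archetype == "distance_tuned") {
    check_positive(optimal_distance_mm, "optimal_distance_mm")
    check_positive(distance_sigma_mm, "distance_sigma_mm")
  }
  if (archetype %in% c("monotonic_near", "monotonic_far")) {
    check_positive(half_distance_mm, "half_distance_mm")
    check_positive(logistic_width_mm, "logistic_width_mm")
  }
  structure(
    list(archetype = archetype,
         baseline_rate_hz = baseline_rate_hz,
         peak_rate_hz = peak_rate_hz,
         optimal_sf_cpd = optimal_sf_cpd,
         sf_bandwidth_oct = sf_bandwidth_oct,
         sf_range_cpd = sf_range_cpd,
         optimal_distance_mm = optimal_distance_mm,
         distance_sigma_mm = distance_sigma_mm,
         half_distance_mm = half_distance_mm,
         logistic_width_mm = logistic_width_mm,
         rate_jitter_cv = rate_jitter_cv,
         eye = eye),
    class = "neuron_model"
  )
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf("<neuron_model '%s'> baseline %g Hz, peak %g Hz, jitter CV %g\n",
              x$archetype, x$baseline_rate_hz, x$peak_rate_hz,
              x$rate_jitter_cv))
  invisible(x)
}

#' Expected firing rate of a model neuron
#'
#' Evaluates the noiseless intensity (Hz) of a [neuron_model()] for a given
#' grating at given distances. For the `sf_tuned` archetype the rate depends
#' on the grating only through the retinal spatial frequency it attains at
#' each distance; for all other archetypes the grating is irrelevant.
#'
#' @param model A [neuron_model()].
#' @param grating Grating period in mm or a row with `period_mm`.
#' @param distance_mm Distances from the screen (mm, > 0); vectorised.
#' @return Rates in Hz (always >= 0).
#' @export
rate_function <- function(model, grating, distance_mm) {
  stopifnot(inherits(model, "neuron_model"))
  check_positive(distance_mm, "distance_mm")
  base <- model$baseline_rate_hz
  peak <- model$peak_rate_hz
  r <- switch(
    model$archetype,
    sf_tuned = {
      sfv <- spatial_frequency(grating, distance_mm, model$eye)
      base + peak * exp(-log2(sfv / model$optimal_sf_cpd)^2 /
                          (2 * model$sf_bandwidth_oct^2))
    },
    distance_tuned =
      base + peak * exp(-(distance_mm - model$optimal_distance_mm)^2 /
                          (2 * model$distance_sigma_mm^2)),
    monotonic_near =
      base + peak * stats::plogis((model$half_distance_mm - distance_mm) /
                                    model$logistic_width_mm),
    monotonic_far =
      base + peak * stats::plogis((distance_mm - model$half_distance_mm) /
                                    model$logistic_width_mm),
    nonresponsive = rep(base, length(distance_mm))
  )
  pmax(r, 0)
}

# Ornstein-Uhlenbeck log-gain path on a time grid: stationary, mean gain 1,
# coefficient of variation cv, correlation time tau_s.
ou_gain <- function(times_s, cv, tau_s = 5) {
  n <- length(times_s)
  if (cv <= 0) return(rep(1, n))
  sigma2 <- log(1 + cv^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sqrt(sigma2))
  if (n > 1) {
    dt <- diff(times_s)
    a <- exp(-dt / tau_s)
    innov_sd <- sqrt(sigma2 * (1 - a^2))
    eps <- rnorm(n - 1)
    for (i in 2:n) x[i] <- a[i - 1] * x[i - 1] + innov_sd[i - 1] * eps[i - 1]
  }
  exp(x - sigma2 / 2)
}

# One inhomogeneous-Poisson spike train by thinning. The intensity is the
# archetype rate at the trajectory distance times the slowly varying gain,
# tabulated on the trajectory grid and linearly interpolated at candidates.
simulate_trial_spikes <- function(model, grating, traj) {
  t_end <- max(traj$time_s)
  gain <- ou_gain(traj$time_s, model$rate_jitter_cv)
  lambda <- rate_function(model, grating, traj$distance_mm) * gain
  lmax <- max(lambda)
  if (lmax <= 0) return(numeric(0))
  ceiling_hz <- lmax * 1.001
  n_cand <- rpois(1, ceiling_hz * t_end)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(runif(n_cand, 0, t_end))
  lam_c <- approx(traj$time_s, lambda, xout = cand)$y
  cand[runif(n_cand) < lam_c / ceiling_hz]
}

#' Simulate a full recording of one neuron
#'
#' Draws spike trains for repeated approach trials with alternating
#' gratings, from an inhomogeneous Poisson process (thinning) whose
#' intensity is the archetype rate at the momentary distance multiplied by a
#' slowly varying log-normal gain (an Ornstein-Uhlenbeck process on the log
#' rate, correlation time 5 s, coefficient of variation
#' `model$rate_jitter_cv`) standing in for free-gaze variability.
#' Trials alternate through the grating set in order (1F, 2F\[, 3F\], 1F,
#' ...), `n_trials_per_grating` cycles in total. The same `seed` always
#' yields an identical recording; the caller's RNG state is untouched.
#'
#' @param model A [neuron_model()].
#' @param protocol A [protocol()]; default [protocol_distant()].
#' @param gratings A [grating_set()] (or compatible tibble).
#' @param n_trials_per_grating Trials per grating, default 6.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG.
#' @param neuron_id Identifier stored in the recording.
#' @return An object of class `neuron_recording`: a list with `neuron_id`,
#'   `trials` (a tibble with columns `trial_index`, `label`, `period_mm`,
#'   `excluded`, `exclusion_reason` and list-column `spike_times_s`),
#'   `trajectory`, `protocol`, `gratings` and `metadata` (protocol name and
#'   the archetype truth label).
#' @examples
#' rec <- simulate_recording(neuron_model("distance_tuned",
#'                                        optimal_distance_mm = 2200),
#'                           seed = 1)
#' rec
#' @export
simulate_recording <- function(model, protocol = protocol_distant(),
                               gratings = grating_set(38),
                               n_trials_per_grating = 6, seed = NULL,
                               neuron_id = "synthetic") {
  stopifnot(inherits(model, "neuron_model"), inherits(protocol, "protocol"))
  validate_grating_set(gratings)
  if (n_trials_per_grating < 1) {
    abort("`n_trials_per_grating` must be >= 1.",
          class = "approachscan_invalid_argument")
  }
  run <- function() {
    traj <- build_trajectory(protocol)
    order <- rep(seq_len(nrow(gratings)), times = n_trials_per_grating)
    trials <- tibble::tibble(
      trial_index = seq_along(order),
      label = gratings$label[order],
      period_mm = gratings$period_mm[order],
      excluded = FALSE,
      exclusion_reason = NA_character_,
      spike_times_s = purrr::map(order, function(g) {
        simulate_trial_spikes(model, gratings$period_mm[g], traj)
      })
    )
    structure(
      list(neuron_id = neuron_id,
           trials = trials,
           trajectory = traj,
           protocol = protocol,
           gratings = gratings,
           metadata = list(protocol_name = protocol$name,
                           archetype = model$archetype)),
      class = "neuron_recording"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.neuron_recording <- function(x, ...) {
  cat(sprintf(
    "<neuron_recording '%s'> %d trials (%s), protocol '%s', archetype %s\n",
    x$neuron_id, nrow(x$trials),
    paste(sprintf("%s x %d", unique(x$trials$label),
                  table(x$trials$label)[unique(x$trials$label)]),
          collapse = ", "),
    x$protocol$name, x$metadata$archetype %||% "unknown"))
  invisible(x)
}

#' Mark trials as excluded
#'
#' Flags trials (e.g. contaminated by drowsiness) so that every downstream
#' computation drops them; excluded trials always carry a reason.
#'
#' @param rec A `neuron_recording`.
#' @param trial_index Indices of trials to exclude.
#' @param reason A short reason string.
#' @return The modified recording.
#' @export
exclude_trials <- function(rec, trial_index, reason = "sleep_contaminated") {
  stopifnot(inherits(rec, "neuron_recording"))
  i <- match(trial_index, rec$trials$trial_index)
  if (anyNA(i)) {
    abort("Unknown trial index.", class = "approachscan_invalid_argument")
  }
  rec$trials$excluded[i] <- TRUE
  rec$trials$exclusion_reason[i] <- reason
  rec
}

# Sample archetype optima restricted to the part of the track where both the
# 1F and 2F maxima stay clearly interior (margin_mm inside each boundary).
sample_archetype_model <- function(archetype, protocol, gratings,
                                   margin_mm, baseline_rate_hz,
                                   peak_rate_hz, rate_jitter_cv,
                                   eye = eye_model()) {
  lo <- protocol$end_distance_mm + margin_mm
  hi <- protocol$start_distance_mm - margin_mm
  track <- protocol$start_distance_mm - protocol$end_distance_mm
  if (archetype == "sf_tuned") {
    p1 <- gratings$period_mm[gratings$label == "1F"]
    p2 <- gratings$period_mm[gratings$label == "2F"]
    sf_lo <- max(lo / (p2 * eye$degrees_per_radian), 0.25)
    sf_hi <- min(hi / (p1 * eye$degrees_per_radian), 2)
    sf <- 2^runif(1, log2(sf_lo), log2(sf_hi))
    neuron_model("sf_tuned", baseline_rate_hz, peak_rate_hz,
                 optimal_sf_cpd = sf, sf_bandwidth_oct = 0.5,
                 rate_jitter_cv = rate_jitter_cv, eye = eye)
  } else if (archetype == "distance_tuned") {
    neuron_model("distance_tuned", baseline_rate_hz, peak_rate_hz,
                 optimal_distance_mm = runif(1, lo, hi),
                 distance_sigma_mm = 0.1 * track,
                 rate_jitter_cv = rate_jitter_cv, eye = eye)
  } else if (archetype %in% c("monotonic_near", "monotonic_far")) {
    neuron_model(archetype, baseline_rate_hz, peak_rate_hz,
                 half_distance_mm = if (archetype == "monotonic_near")
                   protocol$end_distance_mm + 0.15 * track
                 else protocol$start_distance_mm - 0.15 * track,
                 logistic_width_mm = 0.05 * track,
                 rate_jitter_cv = rate_jitter_cv, eye = eye)
  } else {
    neuron_model("nonresponsive", baseline_rate_hz, peak_rate_hz = 0,
                 rate_jitter_cv = rate_jitter_cv, eye = eye)
  }
}

#' Simulate a population of archetypal neurons
#'
#' Generates independent recordings for a mixture of archetypes under one
#' protocol. Tuning optima are drawn per neuron: spatial-frequency optima
#' log-uniform over the part of 0.25-2 cycles/degree whose 1F and 2F maxima
#' both fall at least `margin_mm` inside the track; distance optima uniform
#' over the same interior band.
#'
#' @param n_per_archetype Named integer vector, e.g.
#'   `c(sf_tuned = 50, distance_tuned = 50)`.
#' @param protocol A [protocol()].
#' @param gratings A [grating_set()]; defaults to the 38 mm set for the
#'   distant protocol and the 12 mm set for the near protocol.
#' @param n_trials_per_grating Trials per grating, default 6.
#' @param baseline_rate_hz,peak_rate_hz,rate_jitter_cv Shared rate
#'   parameters, defaults 3 Hz, 15 Hz (peak/baseline 5) and 0.15.
#' @param margin_mm Interior margin for sampled optima; default 1.5 density
#'   window spans (30 s of travel).
#' @param seed Integer seed (recommended for reproducibility).
#' @return A list of `neuron_recording` objects with truth labels in
#'   `metadata$archetype`.
#' @export
simulate_population <- function(n_per_archetype = c(sf_tuned = 50,
                                                    distance_tuned = 50),
                                protocol = protocol_distant(),
                                gratings = NULL,
                                n_trials_per_grating = 6,
                                baseline_rate_hz = 3, peak_rate_hz = 15,
                                rate_jitter_cv = 0.15,
                                margin_mm = 30 * protocol$speed_mm_s,
                                seed = NULL) {
  stopifnot(inherits(protocol, "protocol"))
  if (is.null(gratings)) {
    gratings <- if (protocol$name == "near") grating_set(12) else
      grating_set(38)
  }
  archetypes <- rep(names(n_per_archetype), times = n_per_archetype)
  run <- function() {
    purrr::imap(archetypes, function(arch, i) {
      model <- sample_archetype_model(arch, protocol, gratings, margin_mm,
                                      baseline_rate_hz, peak_rate_hz,
                                      rate_jitter_cv)
      simulate_recording(model, protocol, gratings, n_trials_per_grating,
                         seed = NULL,
                         neuron_id = sprintf("%s_%03d", arch, i))
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
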