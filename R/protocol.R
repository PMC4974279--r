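#' Approach protocol
#'
#' Describes one trial of the approach paradigm: the trolley dwells at the
#' far starting position, moves toward the screen at constant speed, and
#' dwells again at the near end position before being returned (the rapid
#' return is not part of the trial record).
#'
#' @param start_distance_mm Starting eye-to-screen distance (mm).
#' @param end_distance_mm Final distance (mm), smaller than the start.
#' @param speed_mm_s Constant approach speed V2 (mm/s, > 0).
#' @param dwell_start_s Stationary time at the start, default 60 s.
#' @param dwell_end_s Stationary time at the end, default 30 s.
#' @param sample_dt_s Trajectory sampling step, default 0.1 s.
#' @param name Optional protocol name.
#' @return An object of class `protocol`.
#' @seealso [protocol_distant()], [protocol_near()], [build_trajectory()]
#' @export
protocol <- function(start_distance_mm, end_distance_mm, speed_mm_s,
                     dwell_start_s = 60, dwell_end_s = 30,
                     sample_dt_s = 0.1, name = NULL) {
  check_positive(start_distance_mm, "start_distance_mm")
  check_positive(end_distance_mm, "end_distance_mm")
  check_positive(speed_mm_s, "speed_mm_s")
  check_nonnegative(dwell_start_s, "dwell_start_s")
  check_nonnegative(dwell_end_s, "dwell_end_s")
  check_positive(sample_dt_s, "sample_dt_s")
  if (start_distance_mm <= end_distance_mm) {
    abort("`start_distance_mm` must exceed `end_distance_mm`.",
          class = "approachscan_invalid_argument")
  }
  structure(
    list(start_distance_mm = start_distance_mm,
         end_distance_mm = end_distance_mm,
         speed_mm_s = speed_mm_s,
         dwell_start_s = dwell_start_s,
         dwell_end_s = dwell_end_s,
         sample_dt_s = sample_dt_s,
         name = name %||% "custom"),
    class = "protocol"
  )
}

#' Standard protocols
#'
#' `protocol_distant()` explores distant space: approach from 2.8 m to
#' 0.2 m at 1 cm/s (about 4.3 min of motion), used with 38/19 mm gratings.
#' `protocol_near()` explores near space: approach from 1.03 m to 0.11 m at
#' 1.7 mm/s (about 9 min), used with 12/6 mm gratings.
#'
#' @inheritParams protocol
#' @return A `protocol` object.
#' @examples
#' approach_duration_s(protocol_distant()) / 60  # ~4.3 min
#' approach_duration_s(protocol_near()) / 60     # ~9 min
#' @export
protocol_distant <- function(dwell_start_s = 60, dwell_end_s = 30,
                             sample_dt_s = 0.1) {
  protocol(2800, 200, 10, dwell_start_s, dwell_end_s, sample_dt_s,
           name = "distant")
}

#' @rdname protocol_distant
#' @export
protocol_near <- function(dwell_start_s = 60, dwell_end_s = 30,
                          sample_dt_s = 0.1) {
  protocol(1030, 110, 1.7, dwell_start_s, dwell_end_s, sample_dt_s,
           name = "near")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf(
    "<protocol '%s'> %g -> %g mm at %g mm/s (approach %.1f s), dwell %g + %g s\n",
    x$name, x$start_distance_mm, x$end_distance_mm, x$speed_mm_s,
    approach_duration_s(x), x$dwell_start_s, x$dwell_end_s))
  invisible(x)
}

#' Durations of a protocol
#'
#' `approach_duration_s()` is the time spent in motion,
#' `(start - end) / speed`; `trial_duration_s()` adds both dwell phases.
#'
#' @param p A [protocol()].
#' @return Duration in seconds.
#' @export
approach_duration_s <- function(p) {
  stopifnot(inherits(p, "protocol"))
  (p$start_distance_mm - p$end_distance_mm) / p$speed_mm_s
}

#' @rdname approach_duration_s
#' @export
trial_duration_s <- function(p) {
  stopifnot(inherits(p, "protocol"))
  p$dwell_start_s + approach_duration_s(p) + p$dwell_end_s
}

#' Build the trial trajectory of a protocol
#'
#' Samples the piecewise-linear distance-from-screen trace: constant at the
#' start distance during the far dwell, linear descent at the protocol speed,
#' constant at the end distance during the near dwell. The phase breakpoints
#' are included exactly in the sample grid so linear interpolation of the
#' samples reproduces the analytic trace everywhere.
#'
#' @param p A [protocol()].
#' @return A tibble of class `trajectory` with columns `time_s`,
#'   `distance_mm` and `phase` (`dwell_far`, `approach`, `dwell_near`), and
#'   the protocol stored as an attribute.
#' @examples
#' traj <- build_trajectory(protocol_distant())
#' range(traj$distance_mm)
#' @export
build_trajectory <- function(p) {
  stopifnot(inherits(p, "protocol"))
  t_move <- p$dwell_start_s
  t_stop <- p$dwell_start_s + approach_duration_s(p)
  t_end <- trial_duration_s(p)
  times <- sort(unique(c(seq(0, t_end, by = p$sample_dt_s),
                         t_move, t_stop, t_end)))
  dist <- pmin(p$start_distance_mm,
               pmax(p$end_distance_mm,
                    p$start_distance_mm - p$speed_mm_s * (times - t_move)))
  phase <- ifelse(times < t_move, "dwell_far",
                  ifelse(times <= t_stop, "approach", "dwell_near"))
  out <- tibble::tibble(time_s = times, distance_mm = dist, phase = phase)
  class(out) <- c("trajectory", class(out))
  attr(out, "protocol") <- p
  out
}

#' Distance from the screen at given trial times
#'
#' Linear interpolation of a trajectory; exact at the sample points and, for
#' trajectories built by [build_trajectory()], exact everywhere because the
#' trace is piecewise linear with breakpoints on the grid.
#'
#' @param traj A `trajectory` tibble.
#' @param t_s Times in seconds, within the trajectory's time range.
#' @return Distances in mm.
#' @export
distance_at <- function(traj, t_s) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(t_s) == 0) return(numeric(0))
  rng <- range(traj$time_s)
  if (any(t_s < rng[1] - 1e-9) || any(t_s > rng[2] + 1e-9)) {
    abort("`t_s` outside the trajectory time range.",
          class = "approachscan_out_of_range")
  }
  approx(traj$time_s, traj$distance_mm,
         xout = pmin(pmax(t_s, rng[1]), rng[2]))$y
}

trajectory_protocol <- function(traj) {
  p <- attr(traj, "protocol")
  if (is.null(p)) {
    abort("Trajectory carries no protocol attribute.",
          class = "approachscan_invalid_argument")
  }
  p
}
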