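#' Write a recording to a directory
#'
#' Serialises a `neuron_recording` as plain text: `recording.json`
#' (metadata, protocol, gratings, trial table), `trajectory.csv`
#' (`time_s`, `distance_mm`, `phase`) and one `trial_###.csv` spike-time
#' file per trial. [read_recording()] round-trips the result losslessly
#' (up to floating-point text precision).
#'
#' @param rec A `neuron_recording`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "neuron_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- rec$protocol
  meta <- list(
    neuron_id = rec$neuron_id,
    metadata = rec$metadata,
    protocol = p[c("start_distance_mm", "end_distance_mm", "speed_mm_s",
                   "dwell_start_s", "dwell_end_s", "sample_dt_s", "name")],
    gratings = rec$gratings,
    trials = rec$trials[c("trial_index", "label", "period_mm", "excluded",
                          "exclusion_reason")]
  )
  jsonlite::write_json(meta, file.path(dir, "recording.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  write.csv(as.data.frame(rec$trajectory),
            file.path(dir, "trajectory.csv"), row.names = FALSE)
  purrr::walk(seq_len(nrow(rec$trials)), function(i) {
    write.csv(
      data.frame(spike_time_s = rec$trials$spike_times_s[[i]]),
      file.path(dir, sprintf("trial_%03d.csv", rec$trials$trial_index[i])),
      row.names = FALSE)
  })
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir Directory containing `recording.json` and the CSV files.
#' @return A `neuron_recording`.
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "recording.json"),
                              simplifyVector = TRUE)
  p <- do.call(protocol, meta$protocol)
  traj <- tibble::as_tibble(read.csv(file.path(dir, "trajectory.csv")))
  class(traj) <- c("trajectory", class(traj))
  attr(traj, "protocol") <- p
  trials <- tibble::as_tibble(meta$trials)
  trials$exclusion_reason <- as.character(trials$exclusion_reason)
  trials$spike_times_s <- purrr::map(trials$trial_index, function(i) {
    f <- file.path(dir, sprintf("trial_%03d.csv", i))
    df <- read.csv(f)
    as.numeric(df$spike_time_s)
  })
  structure(
    list(neuron_id = meta$neuron_id,
         trials = trials,
         trajectory = traj,
         protocol = p,
         gratings = tibble::as_tibble(meta$gratings),
         metadata = meta$metadata),
    class = "neuron_recording"
  )
}

#' Write a density curve as CSV
#'
#' Columns `distance_mm`, `rate_hz` and, for averaged curves, `sem_hz`.
#'
#' @param curve A `density_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_density_csv <- function(curve, path) {
  stopifnot(inherits(curve, "density_curve"))
  cols <- intersect(c("distance_mm", "rate_hz", "sem_hz"), names(curve))
  write.csv(as.data.frame(curve)[cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a population summary to a directory
#'
#' `classification.csv` holds the per-neuron rows (id, maxima, shift,
#' sign-test p, label); `population.json` the counts, normality tests and
#' constant-maximum positions.
#'
#' @param ps A `population_summary`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(ps, dir) {
  stopifnot(inherits(ps, "population_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(ps$neurons),
            file.path(dir, "classification.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(counts = ps$counts,
         normality = list(pooled_lilliefors_p = ps$normality$pooled_p,
                          clusters = ps$normality$clusters,
                          positions = ps$normality$positions),
         constant_positions = ps$constant_positions),
    file.path(dir, "population.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
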