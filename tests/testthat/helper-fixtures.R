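# Shared fixtures: fast configurations and small protocols keep the unit
# tests quick without changing the analysis logic under test.

fast_cfg <- function(...) {
  analysis_config(step_s = 0.05, bootstrap_n = 500, ...)
}

# short distant-style protocol for cheap simulations
short_protocol <- function(dwell = 10) {
  protocol(1400, 200, 10, dwell_start_s = dwell, dwell_end_s = dwell,
           name = "short")
}

# manually tabulated density curve (for maximum-location tests)
make_curve <- function(distance_mm, rate_hz, n_trials = 2L) {
  out <- tibble::tibble(
    time_s = 30 * seq_along(distance_mm),  # spaced beyond one window
    distance_mm = distance_mm,
    rate_hz = rate_hz
  )
  class(out) <- c("density_curve", class(out))
  attr(out, "n_trials") <- n_trials
  out
}

expect_no_30_70 <- function(shifts) {
  expect_equal(sum(shifts > 30 & shifts < 70, na.rm = TRUE), 0)
}
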