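test_that("an empty spike train gives an all-zero curve", {
  traj <- build_trajectory(short_protocol())
  curve <- spike_density(numeric(0), traj, fast_cfg())
  expect_true(all(curve$rate_hz == 0))
  expect_gt(nrow(curve), 0)
})

test_that("window counts match a brute-force oracle", {
  p <- short_protocol()
  traj <- build_trajectory(p)
  t_end <- trial_duration_s(p)
  spikes <- sort(withr::with_seed(5, runif(700, 0, t_end)))
  cfg <- analysis_config(step_s = 3)
  curve <- spike_density(spikes, traj, cfg)
  oracle <- vapply(curve$time_s, function(tc) {
    lo <- max(tc - cfg$window_s / 2, 0)
    hi <- min(tc + cfg$window_s / 2, t_end)
    sum(spikes > lo & spikes <= hi) / (hi - lo)
  }, numeric(1))
  expect_equal(curve$rate_hz, oracle)
})

test_that("a homogeneous deterministic train reads back its rate", {
  p <- short_protocol()
  traj <- build_trajectory(p)
  t_end <- trial_duration_s(p)
  spikes <- seq(0.05, t_end, by = 0.1)  # exact 10 Hz
  curve <- spike_density(spikes, traj, analysis_config(step_s = 1))
  # every interior window holds 10 spikes per second within one count
  expect_true(all(abs(curve$rate_hz - 10) <= 1 / 20))
})

test_that("the near-space window spans 3.4 cm of track", {
  p <- protocol_near()
  traj <- build_trajectory(p)
  cfg <- analysis_config()
  tc <- p$dwell_start_s + approach_duration_s(p) / 2
  span <- distance_at(traj, tc - cfg$window_s / 2) -
    distance_at(traj, tc + cfg$window_s / 2)
  expect_equal(span, 34)
})

test_that("window-sum conservation holds for non-overlapping windows", {
  p <- protocol(600, 200, 10, dwell_start_s = 0, dwell_end_s = 0)
  traj <- build_trajectory(p)
  spikes <- sort(withr::with_seed(6, runif(400, 0, trial_duration_s(p))))
  cfg <- analysis_config(window_s = 20, step_s = 20)
  curve <- spike_density(spikes, traj, cfg)
  t_end <- trial_duration_s(p)
  durations <- pmin(curve$time_s + 10, t_end) - pmax(curve$time_s - 10, 0)
  expect_equal(sum(curve$rate_hz * durations), length(spikes))
})

test_that("all trials of one protocol share one grid", {
  p <- short_protocol()
  traj <- build_trajectory(p)
  cfg <- fast_cfg()
  curves <- lapply(1:3, function(i) {
    spike_density(sort(withr::with_seed(i, runif(50, 0, 100))), traj, cfg)
  })
  expect_identical(curves[[1]]$time_s, curves[[2]]$time_s)
  expect_identical(curves[[2]]$distance_mm, curves[[3]]$distance_mm)
})

test_that("averaging matches the elementwise oracle", {
  p <- short_protocol()
  traj <- build_trajectory(p)
  cfg <- analysis_config(step_s = 2)
  curves <- lapply(1:5, function(i) {
    spike_density(sort(withr::with_seed(10 + i,
                                        runif(300, 0, trial_duration_s(p)))),
                  traj, cfg)
  })
  avg <- average_density(curves)
  m <- sapply(curves, function(cv) cv$rate_hz)
  expect_equal(avg$rate_hz, rowMeans(m))
  expect_equal(avg$sem_hz, apply(m, 1, sd) / sqrt(5))
  expect_equal(attr(avg, "n_trials"), 5)
  # duplicates have zero SEM; a single curve has undefined SEM
  dup <- average_density(list(curves[[1]], curves[[1]]))
  expect_equal(dup$rate_hz, curves[[1]]$rate_hz)
  expect_equal(max(abs(dup$sem_hz)), 0)
  single <- average_density(list(curves[[1]]))
  expect_true(all(is.na(single$sem_hz)))
})

test_that("averaging refuses mismatched grids", {
  p <- short_protocol()
  traj <- build_trajectory(p)
  a <- spike_density(numeric(0), traj, analysis_config(step_s = 1))
  b <- spike_density(numeric(0), traj, analysis_config(step_s = 2))
  expect_error(average_density(list(a, b)),
               class = "approachscan_invalid_argument")
})

test_that("maximum location matches an analytic unimodal oracle", {
  d <- seq(2800, 200, by = -10)
  curve <- make_curve(d, exp(-(d - 2200)^2 / (2 * 300^2)))
  est <- find_maximum(curve)
  expect_equal(est$distance_mm, 2200)
  expect_false(est$degenerate)
})

test_that("ties break to the farthest distance", {
  d <- seq(1000, 100, by = -100)
  # two equal separated peaks
  r <- rep(1, 10); r[c(3, 8)] <- 5
  expect_warning(est <- find_maximum(make_curve(d, r)),
                 "farthest")
  expect_equal(est$distance_mm, d[3])
  # flat non-zero curve: farthest, degenerate, no warning
  expect_silent(flat <- find_maximum(make_curve(d, rep(2, 10))))
  expect_equal(flat$distance_mm, 1000)
  expect_true(flat$degenerate)
  # all-zero curve: undefined location, non-significant outright
  zero <- find_maximum(make_curve(d, rep(0, 10)))
  expect_true(is.na(zero$distance_mm))
  expect_false(zero$significant)
})
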