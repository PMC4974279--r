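test_that("rate function peaks where the geometry predicts", {
  m <- neuron_model("sf_tuned", optimal_sf_cpd = 0.7)
  grid <- seq(200, 2800, by = 1)
  # grid-search oracle: invert the spatial-frequency relation numerically
  peak_1f <- grid[which.max(rate_function(m, 38, grid))]
  peak_2f <- grid[which.max(rate_function(m, 19, grid))]
  expect_equal(peak_1f, 0.7 * 38 * 57.3, tolerance = 1 / 1524)
  expect_equal(peak_2f, 0.7 * 19 * 57.3, tolerance = 1 / 762)
  # halving the period halves the peak distance: a 100% shift
  expect_equal(shift_statistic(peak_1f, peak_2f), 100, tolerance = 0.01)
})

test_that("distance-tuned rates ignore the grating", {
  m <- neuron_model("distance_tuned", optimal_distance_mm = 2200,
                    distance_sigma_mm = 260)
  grid <- seq(200, 2800, by = 1)
  peaks <- vapply(c(38, 19, 38 / 3),
                  function(p) grid[which.max(rate_function(m, p, grid))],
                  numeric(1))
  expect_equal(peaks, rep(2200, 3))
  expect_equal(rate_function(m, 38, grid), rate_function(m, 19, grid))
})

test_that("degenerate models flatten to the baseline", {
  m <- neuron_model("sf_tuned", baseline_rate_hz = 4, peak_rate_hz = 0)
  d <- seq(200, 2800, length.out = 50)
  expect_equal(rate_function(m, 38, d), rep(4, 50))
  expect_equal(rate_function(m, 19, d), rep(4, 50))
})

test_that("monotonic archetypes are monotone along the track", {
  d <- seq(200, 2800, length.out = 100)
  near <- rate_function(neuron_model("monotonic_near",
                                     half_distance_mm = 600), 38, d)
  far <- rate_function(neuron_model("monotonic_far",
                                    half_distance_mm = 2400), 38, d)
  expect_true(all(diff(near) <= 0))  # rises toward the screen (small d)
  expect_true(all(diff(far) >= 0))
})

test_that("simulation is reproducible and well-formed", {
  m <- neuron_model("distance_tuned", optimal_distance_mm = 800)
  p <- short_protocol()
  a <- simulate_recording(m, p, seed = 42)
  b <- simulate_recording(m, p, seed = 42)
  expect_identical(a$trials$spike_times_s, b$trials$spike_times_s)
  # alternating grating sequence
  expect_equal(a$trials$label, rep(c("1F", "2F"), 6))
  # spikes sorted and inside the trial span
  t_end <- trial_duration_s(p)
  for (s in a$trials$spike_times_s) {
    expect_true(!is.unsorted(s))
    expect_true(all(s >= 0 & s <= t_end))
  }
})

test_that("a nonresponsive neuron is homogeneous Poisson", {
  m <- neuron_model("nonresponsive", baseline_rate_hz = 5,
                    rate_jitter_cv = 0)
  p <- short_protocol()
  t_end <- trial_duration_s(p)
  counts <- vapply(1:200, function(i) {
    rec <- simulate_recording(m, p, grating_set(38), 1, seed = 1000 + i)
    length(rec$trials$spike_times_s[[1]])
  }, numeric(1))
  # empirical mean within 3 standard errors of 5 * T
  expect_lt(abs(mean(counts) - 5 * t_end),
            3 * sd(counts) / sqrt(length(counts)))
})

test_that("thinning passes the time-rescaling check", {
  # with zero gain jitter the intensity is known exactly; rescaled
  # inter-spike intervals must be Exp(1)
  m <- neuron_model("distance_tuned", optimal_distance_mm = 800,
                    distance_sigma_mm = 150, baseline_rate_hz = 5,
                    peak_rate_hz = 25, rate_jitter_cv = 0)
  p <- short_protocol()
  traj <- build_trajectory(p)
  spikes <- sort(unlist(lapply(1:6, function(i) {
    withr::with_seed(2000 + i, approachscan:::simulate_trial_spikes(m, 38, traj))
  })))
  # superposed trains from k trials have intensity k * lambda(t)
  tt <- traj$time_s
  lam <- 6 * rate_function(m, 38, traj$distance_mm)
  cum <- c(0, cumsum((lam[-1] + lam[-length(lam)]) / 2 * diff(tt)))
  rescaled <- approx(tt, cum, xout = spikes)$y
  ks <- stats::ks.test(diff(rescaled), "pexp", 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("averaged density recovers the analytic rate without jitter", {
  m <- neuron_model("distance_tuned", optimal_distance_mm = 800,
                    distance_sigma_mm = 200, rate_jitter_cv = 0)
  p <- short_protocol()
  cfg <- analysis_config(step_s = 1)
  rec <- simulate_recording(m, p, grating_set(38), 12, seed = 7)
  curves <- lapply(rec$trials$spike_times_s[rec$trials$label == "1F"],
                   spike_density, trajectory = rec$trajectory, cfg = cfg)
  avg <- average_density(c(curves,
    lapply(rec$trials$spike_times_s[rec$trials$label == "2F"],
           spike_density, trajectory = rec$trajectory, cfg = cfg)))
  # oracle: the exact expectation of each window is the time average of
  # the intensity over the window
  traj <- rec$trajectory
  t_end <- trial_duration_s(p)
  expected <- vapply(avg$time_s, function(tc) {
    tt <- seq(max(tc - cfg$window_s / 2, 0), min(tc + cfg$window_s / 2, t_end),
              length.out = 200)
    mean(rate_function(m, 38, distance_at(traj, tt)))
  }, numeric(1))
  rmse <- sqrt(mean((avg$rate_hz - expected)^2))
  # 24 pooled trials: Poisson standard error ~ sqrt(rate / (w * n)) < 0.3 Hz
  expect_lt(rmse, 0.6)
})

test_that("trial exclusion is recorded and validated", {
  rec <- simulate_recording(neuron_model("nonresponsive"),
                            short_protocol(), seed = 3)
  rec <- exclude_trials(rec, c(1, 4), reason = "sleep_spindles")
  expect_equal(sum(rec$trials$excluded), 2)
  expect_equal(unique(rec$trials$exclusion_reason[rec$trials$excluded]),
               "sleep_spindles")
  expect_error(exclude_trials(rec, 99),
               class = "approachscan_invalid_argument")
  expect_error(approachscan:::trial_density(rec, 1, analysis_config()),
               class = "approachscan_excluded_trial")
})
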