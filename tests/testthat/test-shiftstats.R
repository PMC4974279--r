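test_that("the shift statistic evaluates its closed form", {
  expect_equal(shift_statistic(2000, 1000), 100)
  expect_equal(shift_statistic(1500, 1500), 0)
  expect_equal(shift_statistic(1500, 1000), 50)
  expect_error(shift_statistic(1500, 0),
               class = "approachscan_invalid_argument")
})

test_that("pairwise shifts enumerate the Cartesian product", {
  m1 <- withr::with_seed(1, runif(6, 1000, 2000))
  m2 <- withr::with_seed(2, runif(6, 500, 1000))
  pairs <- pairwise_shift_distribution(m1, m2)
  expect_equal(nrow(pairs), 36)
  # brute-force double-loop oracle
  oracle <- c()
  for (a in m1) for (b in m2) oracle <- c(oracle, (a - b) / b * 100)
  expect_equal(sort(pairs$shift_pct), sort(oracle))
  # constant lists collapse to zero shift
  expect_true(all(pairwise_shift_distribution(rep(7, 4),
                                              rep(7, 5))$shift_pct == 0))
  expect_error(pairwise_shift_distribution(numeric(0), m2),
               class = "approachscan_invalid_argument")
  expect_error(pairwise_shift_distribution(m1, c(500, -1)),
               class = "approachscan_invalid_argument")
})

test_that("the exact sign test reproduces closed-form binomial tails", {
  # all sign patterns for a handful of sizes up to 36
  for (n in c(5, 12, 36)) {
    for (k in c(0, 1, floor(n / 2), n - 1, n)) {
      x <- c(rep(1, k), rep(-1, n - k))
      got <- sign_test(x, "greater")
      oracle <- sum(choose(n, k:n)) / 2^n
      expect_equal(got$p_value, oracle, tolerance = 1e-12)
      expect_equal(sign_test(x, "less")$p_value,
                   sum(choose(n, 0:k)) / 2^n, tolerance = 1e-12)
    }
  }
  # ties are dropped
  expect_equal(sign_test(c(0, 0, 1, 1), "greater")$n, 2)
  expect_true(is.na(sign_test(c(0, 0), "greater")$p_value))
})

test_that("clear shift distributions classify as the oracle predicts", {
  cfg <- analysis_config()
  # shifts spread over [90, 110]%: all 36 pair signs positive, p = 2^-36
  m2 <- rep(1000, 6)
  m1 <- 1000 * (1 + seq(0.90, 1.10, length.out = 6))
  sr <- classify_shift(m1, m2, cfg)
  expect_equal(sr$class_label, "shifting")
  expect_equal(sr$p_sign, 2^-36, tolerance = 1e-12)
  # shifts within [-10, 10]%
  sr0 <- classify_shift(1000 * (1 + seq(-0.10, 0.10, length.out = 6)),
                        m2, cfg)
  expect_equal(sr0$class_label, "constant")
  expect_equal(sr0$p_sign, 2^-36, tolerance = 1e-12)
  # shifts around 50% fall between the thresholds
  sr5 <- classify_shift(1000 * (1 + seq(0.45, 0.55, length.out = 6)),
                        m2, cfg)
  expect_equal(sr5$class_label, "unclassified")
})

test_that("classification is invariant to a common rescaling", {
  m1 <- withr::with_seed(3, runif(6, 1800, 2200))
  m2 <- withr::with_seed(4, runif(6, 950, 1050))
  a <- classify_shift(m1, m2)
  for (s in c(0.01, 3.7)) {
    b <- classify_shift(m1 * s, m2 * s)
    expect_equal(b$class_label, a$class_label)
    expect_equal(b$p_sign, a$p_sign)
    expect_equal(b$pairs$shift_pct, a$pairs$shift_pct)
  }
})

test_that("too few pairs leave the shift unclassified", {
  expect_warning(sr <- classify_shift(c(2000, 2100), c(1000, 990)),
                 "unclassified")
  expect_equal(sr$class_label, "unclassified")
})

test_that("identical flat trials are never significant", {
  traj <- build_trajectory(short_protocol())
  t_end <- trial_duration_s(short_protocol())
  spikes <- seq(0.05, t_end, by = 0.1)
  curves <- lapply(1:6, function(i) spike_density(spikes, traj, fast_cfg()))
  # the lattice train ties many windows exactly; ties are not under test
  est <- suppressWarnings(bootstrap_max_significance(curves, fast_cfg(),
                                                     seed = 1))
  expect_false(est$significant)
})

test_that("the bootstrap is reproducible and detects strong peaks", {
  m <- neuron_model("distance_tuned", optimal_distance_mm = 800)
  rec <- simulate_recording(m, short_protocol(), seed = 20)
  cfg <- fast_cfg()
  curves <- lapply(rec$trials$spike_times_s[rec$trials$label == "1F"],
                   spike_density, trajectory = rec$trajectory, cfg = cfg)
  a <- bootstrap_max_significance(curves, cfg, seed = 9)
  b <- bootstrap_max_significance(curves, cfg, seed = 9)
  expect_identical(a, b)
  # a peak five times the baseline is detected across independent seeds
  hits <- vapply(1:20, function(i) {
    r <- simulate_recording(m, short_protocol(), seed = 100 + i)
    cv <- lapply(r$trials$spike_times_s[r$trials$label == "1F"],
                 spike_density, trajectory = r$trajectory, cfg = cfg)
    bootstrap_max_significance(cv, cfg)$significant
  }, logical(1))
  expect_true(all(hits))
  expect_error(bootstrap_max_significance(curves[1], cfg),
               class = "approachscan_invalid_argument")
})

test_that("the Lilliefors test is calibrated on normal samples", {
  # a pure normal sample of the constant-cluster size should rarely reject
  keep <- withr::with_seed(30, vapply(1:500, function(i) {
    lilliefors_p(rnorm(24, 0, 13)) > 0.05
  }, logical(1)))
  expect_gte(mean(keep), 0.90)
})

test_that("the two-cluster mixture is detected as non-normal", {
  # cluster parameters typical of recorded populations: 6.5 +/- 13.3 and
  # 113 +/- 30.3; the simulation oracle (2000 draws) puts the rejection
  # rate at ~0.94
  reject <- withr::with_seed(31, vapply(1:500, function(i) {
    x <- c(rnorm(24, 6.5, 13.3), rnorm(25, 113, 30.3))
    lilliefors_p(x) < 0.001
  }, logical(1)))
  expect_gte(mean(reject), 0.90)
})

test_that("population normality splits and clusters sensibly", {
  shifts <- withr::with_seed(32, c(rnorm(40, 5, 10), rnorm(40, 105, 20)))
  positions <- withr::with_seed(33, c(rnorm(12, 800, 40),
                                      rnorm(12, 2200, 60)))
  out <- normality_and_clusters(shifts, positions)
  expect_lt(out$pooled_p, 0.001)
  expect_true(all(out$clusters$lilliefors_p > 0.05))
  expect_equal(out$clusters$n, c(40, 40))
  expect_equal(out$positions$n_clusters, 2)
  expect_equal(sort(out$positions$cluster_means_mm), c(800, 2200),
               tolerance = 0.05)
  # degenerate input skips the tests with a notice
  expect_message(tiny <- normality_and_clusters(5), "skipped")
  expect_true(is.na(tiny$pooled_p))
})
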