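test_that("response ratios are exactly gain invariant", {
  pop <- gaussian_coding_population(c(1500, 2500), 600)
  d <- seq(400, 3300, by = 50)
  base <- response_ratio(pop, "cell_1", "cell_2", d)
  for (g in c(2, 8)) {  # powers of two keep the arithmetic exact
    scaled <- coding_population(dplyr::mutate(
      tibble::as_tibble(pop),
      dplyr::across(-"distance_mm", ~ g * .x)))
    expect_identical(response_ratio(scaled, "cell_1", "cell_2", d), base)
  }
})

test_that("ratios between two Gaussian peaks are strictly monotone", {
  pop <- gaussian_coding_population(c(1500, 2500), 600)
  d <- seq(1500, 2500, by = 5)
  r <- response_ratio(pop, "cell_1", "cell_2", d)
  expect_true(all(diff(r) < 0))
})

test_that("zero denominators are flagged", {
  pop <- coding_population(tibble::tibble(
    distance_mm = c(1000, 2000), a = c(1, 2), b = c(0, 1)))
  expect_warning(r <- response_ratio(pop, "a", "b", c(1000, 2000)),
                 "undefined")
  expect_true(is.na(r[1]) && r[2] == 2)
})

test_that("decoding is self-consistent and gain invariant", {
  pop <- gaussian_coding_population(c(1500, 2500), 600)
  for (d0 in c(900, 1500, 2000, 3100)) {
    est <- decode_distance(pop, response_at(pop, d0))
    expect_false(est$flat)
    expect_equal(est$distance_mm, d0, tolerance = 5 / d0)
    # unknown common gain: exactly invariant without the regulariser
    est0 <- decode_distance(pop, response_at(pop, d0), epsilon = 0)
    est0_g <- decode_distance(pop, response_at(pop, d0, gain = 7.3),
                              epsilon = 0)
    expect_equal(est0_g$distance_mm, est0$distance_mm)
    # with the default regulariser the perturbation is negligible where
    # both rates dominate epsilon (interior of the support)
    if (d0 %in% c(1500, 2000)) {
      est_g <- decode_distance(pop, response_at(pop, d0, gain = 7.3))
      expect_equal(est_g$distance_mm, est$distance_mm, tolerance = 0.02)
    }
  }
})

test_that("identical tuning curves make distance unidentifiable", {
  g <- seq(500, 3000, by = 10)
  rate <- 20 * exp(-(g - 1700)^2 / (2 * 500^2))
  pop <- coding_population(tibble::tibble(distance_mm = g, a = rate,
                                          b = rate))
  est <- decode_distance(pop, response_at(pop, 1200))
  expect_true(est$flat)
  expect_true(is.na(est$distance_mm))
  expect_match(est$reason, "unidentifiable")
})

test_that("decoding is invariant to relabelling the cells", {
  pop <- gaussian_coding_population(c(1200, 1900, 2600), c(500, 600, 700))
  obs <- response_at(pop, 2100)
  est <- decode_distance(pop, obs)
  perm <- c(3, 1, 2)
  pop_p <- coding_population(tibble::tibble(
    distance_mm = pop$distance_mm,
    cell_1 = pop[[1 + perm[1]]], cell_2 = pop[[1 + perm[2]]],
    cell_3 = pop[[1 + perm[3]]]))
  expect_equal(decode_distance(pop_p, obs[perm])$distance_mm,
               est$distance_mm)
})

test_that("decoding refuses malformed inputs", {
  pop <- gaussian_coding_population(c(1500, 2500), 600)
  expect_error(decode_distance(pop, c(1, 2, 3)),
               class = "approachscan_invalid_argument")
  solo <- coding_population(tibble::tibble(distance_mm = 1:10,
                                           a = rep(1, 10)))
  expect_error(decode_distance(solo, 1),
               class = "approachscan_invalid_argument")
})

test_that("flank decoding beats peak decoding across tuning widths", {
  # additive rate noise at 5% of the peak rate; the crossing between the
  # two curves offers steep opposing flanks, the peaks a one-sided signal.
  # The grid covers the informative support of the pair: beyond it both
  # rates saturate at the regulariser and the ratio is uninformative.
  for (sigma in c(300, 600, 900)) {
    pop <- gaussian_coding_population(c(1500, 2500), sigma,
                                      grid = seq(1000, 3000, by = 5))
    res <- ratio_code_rmse(pop, c(1500, 2000, 2500), noise_sd_hz = 1.5,
                           n_draws = 300, seed = 400 + sigma)
    flank <- res$rmse_mm[res$distance_mm == 2000]
    peaks <- mean(res$rmse_mm[res$distance_mm != 2000])
    expect_lt(flank, peaks)
  }
})
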