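#' Bootstrap significance of a response maximum
#'
#' Tests whether the maximum of the trial-averaged density curve rises above
#' what trial-to-trial variability alone would produce at a flat (level)
#' firing profile. Trials are resampled with replacement `cfg$bootstrap_n`
#' times; each resample's residual curves (per-trial curve minus the
#' observed mean curve, rescaled by `sqrt(n/(n-1))` for finite-sample
#' variance) are averaged and added to the across-track grand mean rate,
#' giving one realisation of a flat-null mean curve. The observed maximum is
#' significant iff its height exceeds the `cfg$conf_level` quantile of the
#' distribution of the null curves' maxima. With identical (e.g. perfectly
#' flat) trials the null band degenerates to the flat level and nothing is
#' significant. Deterministic given `seed`.
#'
#' @param curves A list of at least two per-trial `density_curve`s on a
#'   common grid.
#' @param cfg An [analysis_config()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A one-row `maximum_estimate` tibble: `distance_mm`, `rate_hz`,
#'   `significant`, `degenerate`, `null_upper_hz` (the null quantile the
#'   maximum must exceed).
#' @export
bootstrap_max_significance <- function(curves, cfg = analysis_config(),
                                       seed = NULL) {
  if (inherits(curves, "density_curve") || length(curves) < 2) {
    abort("Need at least two trial curves for the bootstrap.",
          class = "approachscan_invalid_argument")
  }
  if (!density_grid_identical(curves)) {
    abort("Density curves are not on a common grid.",
          class = "approachscan_invalid_argument")
  }
  avg <- average_density(curves)
  est <- find_maximum(avg, cfg)
  if (isFALSE(est$significant)) return(est)  # all-zero curve
  n <- length(curves)
  m <- density_matrix(curves)
  resid <- (m - avg$rate_hz) * sqrt(n / (n - 1))
  grand <- mean(avg$rate_hz)
  if (max(abs(resid)) == 0) {
    # identical trials: no sampling variability to resample, the band
    # degenerates to the flat level and nothing can be called significant
    est$significant <- FALSE
    est$null_upper_hz <- grand
    return(est)
  }
  run <- function() {
    b_total <- cfg$bootstrap_n
    # chunk the resample matrix to bound memory at ~5e6 doubles
    chunk <- max(1L, min(b_total, floor(5e6 / nrow(m))))
    stat <- numeric(0)
    done <- 0L
    while (done < b_total) {
      b <- min(chunk, b_total - done)
      w <- vapply(seq_len(b),
                  function(j) tabulate(sample.int(n, n, replace = TRUE), n),
                  integer(n))
      null_curves <- grand + (resid %*% w) / n
      stat <- c(stat, apply(null_curves, 2, max))
      done <- done + b
    }
    stat
  }
  stat <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  upper <- quantile(stat, cfg$conf_level, names = FALSE, type = 7)
  est$null_upper_hz <- upper
  est$significant <- est$rate_hz > upper
  est
}

#' Maximum-shift statistic
#'
#' The relative displacement of the response maximum between the
#' low-frequency (1F) and high-frequency (2F) gratings:
#' `(M1 - M2) / M2 * 100` percent, where `M1` and `M2` are the distances
#' from the screen to the 1F and 2F maxima. A purely frequency-tuned cell
#' predicts 100% (the maximum halves its distance when the frequency
#' doubles); a purely distance-tuned cell predicts 0%.
#'
#' @param m1_mm,m2_mm Maximum distances in mm (`m2_mm > 0`); vectorised.
#' @return Shift in percent.
#' @examples
#' shift_statistic(2000, 1000)  # 100
#' shift_statistic(1500, 1500)  # 0
#' @export
shift_statistic <- function(m1_mm, m2_mm) {
  check_number(m1_mm, "m1_mm")
  check_positive(m2_mm, "m2_mm")
  (m1_mm - m2_mm) / m2_mm * 100
}

#' All-pairs shift distribution
#'
#' Per-trial maximum positions for the two gratings are combined over the
#' full Cartesian product (every 1F trial against every 2F trial, n1 x n2
#' pairs; 36 for six trials per grating), each pair evaluated with
#' [shift_statistic()]. Individual trials are treated as independent, which
#' the long trial duration justifies.
#'
#' @param m1_per_trial,m2_per_trial Per-trial maximum distances (mm).
#' @return A tibble with one row per pair: `m1_mm`, `m2_mm`, `shift_pct`.
#' @export
pairwise_shift_distribution <- function(m1_per_trial, m2_per_trial) {
  if (length(m1_per_trial) == 0 || length(m2_per_trial) == 0) {
    abort("Both trial lists must be non-empty.",
          class = "approachscan_invalid_argument")
  }
  check_positive(m2_per_trial, "m2_per_trial")
  grid <- tidyr::expand_grid(m1_mm = m1_per_trial, m2_mm = m2_per_trial)
  grid$shift_pct <- shift_statistic(grid$m1_mm, grid$m2_mm)
  grid
}

#' Exact sign test
#'
#' One-sided exact binomial sign test on the signs of `x` (zeros dropped):
#' under H0 the median of `x` is 0, so positive and negative signs are
#' equally likely.
#'
#' @param x Numeric values.
#' @param alternative `"greater"` (median > 0) or `"less"`.
#' @return A list with `p_value`, `n` (non-zero values) and `n_positive`.
#' @export
sign_test <- function(x, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[x != 0]
  n <- length(x)
  k <- sum(x > 0)
  p <- if (n == 0) {
    NA_real_
  } else if (alternative == "greater") {
    pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  } else {
    pbinom(n - k - 1, n, 0.5, lower.tail = FALSE)
  }
  list(p_value = p, n = n, n_positive = k)
}

#' Classify a neuron's shift
#'
#' Applies the two-threshold rule to the all-pairs shift distribution. With
#' per-pair differences `d = M1 - M2` and the full-shift reference
#' `r = M2` (the frequency-tuned geometry predicts `M1 = 2 * M2`):
#'
#' * `shifting` — mean pairwise shift above `cfg$shifting_threshold_pct`
#'   AND a one-sided exact sign test rejects, at `cfg$alpha`, that the
#'   median of `d - 0.7 r` is at or below 0 (the maxima sit demonstrably
#'   beyond the 70% boundary);
#' * `constant` — mean pairwise shift below `cfg$constant_threshold_pct`
#'   AND the mirrored sign test rejects that the median of `d - 0.3 r` is
#'   at or above 0;
#' * `unclassified` otherwise, or when fewer than `cfg$min_pairs` pairs are
#'   available.
#'
#' The label is invariant to a common rescaling of all distances.
#'
#' @param m1_per_trial,m2_per_trial Per-trial maximum distances (mm).
#' @param cfg An [analysis_config()].
#' @param m1_mm,m2_mm Maximum distances of the trial-averaged curves; used
#'   for the headline `shift_pct`. Default to the means of the per-trial
#'   values.
#' @return An object of class `shift_result`: a list with `m1_mm`, `m2_mm`,
#'   `shift_pct`, `pairs` (the pairwise tibble), `n_pairs`,
#'   `mean_pairwise_shift_pct`, `frac_above_shifting`, `frac_below_constant`,
#'   `p_sign` and `class_label`.
#' @export
classify_shift <- function(m1_per_trial, m2_per_trial,
                           cfg = analysis_config(),
                           m1_mm = mean(m1_per_trial),
                           m2_mm = mean(m2_per_trial)) {
  pairs <- pairwise_shift_distribution(m1_per_trial, m2_per_trial)
  n_pairs <- nrow(pairs)
  mean_shift <- mean(pairs$shift_pct)
  frac_above <- mean(pairs$shift_pct > cfg$shifting_threshold_pct)
  frac_below <- mean(pairs$shift_pct < cfg$constant_threshold_pct)
  d <- pairs$m1_mm - pairs$m2_mm
  r <- pairs$m2_mm
  label <- "unclassified"
  p_sign <- NA_real_
  if (n_pairs < cfg$min_pairs) {
    warn(sprintf("Only %d trial pairs (< %d); shift left unclassified.",
                 n_pairs, cfg$min_pairs))
  } else if (mean_shift > cfg$shifting_threshold_pct) {
    test <- sign_test(d - cfg$shifting_threshold_pct / 100 * r, "greater")
    p_sign <- test$p_value
    if (!is.na(p_sign) && p_sign < cfg$alpha) label <- "shifting"
  } else if (mean_shift < cfg$constant_threshold_pct) {
    test <- sign_test(d - cfg$constant_threshold_pct / 100 * r, "less")
    p_sign <- test$p_value
    if (!is.na(p_sign) && p_sign < cfg$alpha) label <- "constant"
  }
  structure(
    list(m1_mm = m1_mm, m2_mm = m2_mm,
         shift_pct = shift_statistic(m1_mm, m2_mm),
         pairs = pairs, n_pairs = n_pairs,
         mean_pairwise_shift_pct = mean_shift,
         frac_above_shifting = frac_above,
         frac_below_constant = frac_below,
         p_sign = p_sign, class_label = label),
    class = "shift_result"
  )
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf(
    "<shift_result> M1 %.0f mm, M2 %.0f mm, shift %.1f%% (mean pairwise %.1f%%, %d pairs) -> %s\n",
    x$m1_mm, x$m2_mm, x$shift_pct, x$mean_pairwise_shift_pct, x$n_pairs,
    x$class_label))
  invisible(x)
}

#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov test for normality with estimated mean and variance
#' (Lilliefors correction), via `nortest::lillie.test()`. Returns `NA` with
#' a notice for fewer than 5 values.
#'
#' @param x Numeric sample.
#' @return The p-value, or `NA` if the sample is too small.
#' @export
lilliefors_p <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5) {
    inform("Fewer than 5 values; Lilliefors test skipped.")
    return(NA_real_)
  }
  nortest::lillie.test(x)$p.value
}

#' Population normality and cluster structure
#'
#' Population-level structure of the shift values and of the constant-cell
#' maximum positions: a Lilliefors test on the pooled shifts (the two-class
#' hypothesis predicts rejection), a split at the 50% midpoint with
#' per-cluster Lilliefors tests and mean/SD (each cluster is predicted
#' normal), and, for the constant-maximum positions, a Lilliefors test plus
#' a 1-D Gaussian-mixture clustering with the number of components chosen
#' by BIC among 1-4 (`mclust`).
#'
#' @param shifts_pct Per-neuron shift values (percent) of classified cells.
#' @param positions_mm Optional maximum positions of constant-maximum cells.
#' @return A list of class `population_normality`: `pooled_p`, `clusters`
#'   (tibble with `cluster`, `n`, `mean_shift_pct`, `sd_shift_pct`,
#'   `lilliefors_p`), and `positions` (`lilliefors_p`, `n_clusters`,
#'   `cluster_means_mm`, `assignment`) or `NULL`.
#' @export
normality_and_clusters <- function(shifts_pct, positions_mm = NULL) {
  shifts_pct <- shifts_pct[is.finite(shifts_pct)]
  pooled_p <- if (length(shifts_pct) >= 5) lilliefors_p(shifts_pct) else {
    inform("Fewer than 5 classified neurons; pooled test skipped.")
    NA_real_
  }
  cluster_of <- split(shifts_pct,
                      ifelse(shifts_pct < 50, "below_50", "above_50"))
  clusters <- purrr::map_dfr(c("below_50", "above_50"), function(side) {
    v <- cluster_of[[side]] %||% numeric(0)
    tibble::tibble(
      cluster = side, n = length(v),
      mean_shift_pct = if (length(v)) mean(v) else NA_real_,
      sd_shift_pct = if (length(v) > 1) sd(v) else NA_real_,
      lilliefors_p = if (length(v) >= 5) lilliefors_p(v) else NA_real_
    )
  })
  positions <- NULL
  if (!is.null(positions_mm)) {
    positions_mm <- positions_mm[is.finite(positions_mm)]
    if (length(positions_mm) >= 5) {
      # Mclust() resolves mclustBIC in the caller's frame
      mclustBIC <- mclust::mclustBIC
      fit <- mclust::Mclust(positions_mm, G = 1:4, verbose = FALSE)
      positions <- list(
        lilliefors_p = lilliefors_p(positions_mm),
        n_clusters = fit$G,
        cluster_means_mm = as.numeric(fit$parameters$mean),
        assignment = as.integer(fit$classification)
      )
    } else {
      inform("Fewer than 5 constant-maximum positions; clustering skipped.")
    }
  }
  structure(list(pooled_p = pooled_p, clusters = clusters,
                 positions = positions),
            class = "population_normality")
}
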