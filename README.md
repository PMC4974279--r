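# approachscan

Analysis of single-unit recordings made while an observer is carried
slowly toward a large stationary sinusoidal grating. The paradigm asks a
sharp question about depth coding in primary visual cortex: when the
grating's spatial frequency is doubled (its physical period halved), does
a neuron's response maximum move half way closer to the screen — the
signature of classical retinal spatial-frequency tuning — or does it stay
at the same physical distance, the signature of tuning to *absolute*
depth?

`approachscan` provides, as a pipeline of tibble-returning functions:

* **Viewing geometry** — retinal spatial frequency of a physical grating,
  `f(D) = D / (p · 57.3)` cycles/degree for period `p` mm at distance `D`
  mm; retinal drift speed during approach, `V₁ = V₂·E·D₁/D₂²`; the
  frequency-tuned prediction `M₂ = M₁ / 2`.
* **Protocols** — the distant-space (2.8 → 0.2 m at 1 cm/s) and
  near-space (1.03 → 0.11 m at 1.7 mm/s) approach trajectories with their
  dwell phases.
* **Spike density and maxima** — sliding 20 s / 0.01 s boxcar rate
  estimate along the approach, trial averaging, and maximum location.
* **Significance and classification** — a trial-resampling bootstrap
  (1000 resamples, 95% level) for each maximum; the shift statistic
  `Shift = (M₁ − M₂)/M₂ · 100%` over all n₁ × n₂ trial pairs; exact
  binomial sign tests against the 30% (constant) and 70% (shifting)
  boundaries; boundary/outlier rules for monotonic cells; population
  counts, Lilliefors normality of the shift clusters, and
  Gaussian-mixture clustering of constant-maximum positions.
* **Synthetic recordings** — inhomogeneous-Poisson simulation of
  frequency-tuned, distance-tuned, monotonic and nonresponsive archetypes
  under either protocol, with slow log-normal gain drift standing in for
  free-gaze variability, so the whole pipeline is testable without
  recorded data.
* **Ratio code** — a demonstrative decoder of absolute distance from the
  rate *ratios* of overlapping tuning curves, gain-invariant by
  construction, with a Monte-Carlo tool showing that decoding is most
  precise on tuning-curve flanks.

## Worked example

Simulate a distance-tuned neuron (optimum 2.2 m) under the distant-space
protocol, six trials per grating, and classify it:

```r
library(approachscan)

spatial_frequency(c(12, 6), 1030)   # near-space gratings at the start
#> [1] 1.497964 2.995928              # ~1.5 and 3 cycles/degree

rec <- simulate_recording(
  neuron_model("distance_tuned", optimal_distance_mm = 2200),
  protocol_distant(), grating_set(38), seed = 7)
cl <- classify_neuron(rec, analysis_config(), seed = 8)
cl$maxima
#> # A tibble: 2 × 6
#>   label distance_mm rate_hz significant null_upper_hz n_trials
#>   <chr>       <dbl>   <dbl> <lgl>               <dbl>    <int>
#> 1 1F          2200.    17.3 TRUE                 8.21        6
#> 2 2F          2171.    18.8 TRUE                 8.31        6
glance(cl)[, c("label", "m1_mm", "m2_mm", "shift_pct", "p_sign")]
#> # A tibble: 1 × 5
#>   label    m1_mm m2_mm shift_pct   p_sign
#>   <chr>    <dbl> <dbl>     <dbl>    <dbl>
#> 1 constant 2200. 2171.      1.33 1.46e-11
```

Both gratings' maxima are significant (their heights, 17–19 Hz, far
exceed the ~8 Hz upper bound of the flat-null bootstrap band), they sit
at the same distance (2200 vs 2171 mm, a 1.3% shift), and the sign test
against the 30% boundary classifies the cell as a **constant maximum** —
distance-tuned. A frequency-tuned cell simulated the same way is instead
labelled `shifting`, with `m1_mm ≈ 2 · m2_mm` (a shift near 100%).

Population-level analysis takes a list of recordings:

```r
pop <- simulate_population(c(sf_tuned = 50, distance_tuned = 50), seed = 1)
ps  <- run_population(pop, analysis_config(), seed = 1001)
glance(ps)      # counts, pooled/cluster Lilliefors, cluster means ± SD
autoplot(ps)    # sorted shift distribution with the 30%/70% thresholds
```

## Vignette

`vignettes/approach-analysis.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, and the numerical design
choices (bootstrap null construction, tie-breaking, thresholds,
validation problem sizes).
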