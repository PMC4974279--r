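---
title: "Separating absolute-distance and spatial-frequency tuning during slow approach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating absolute-distance and spatial-frequency tuning during slow approach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(approachscan)
```

## The question and the paradigm

A neuron in primary visual cortex that prefers a particular retinal
spatial frequency will respond maximally to a *physical* grating at a
particular viewing distance, because the retinal frequency of a fixed
grating grows linearly with distance. A neuron tuned to *absolute
distance*, by contrast, should respond at the same physical distance
whatever grating is shown. The approach paradigm separates the two with a
single manipulation: record while the observer is carried slowly toward a
large stationary sinusoidal grating, then repeat with a grating of twice
the spatial frequency (half the physical period). For a
frequency-tuned cell the response maximum must move half way closer to the
screen; for a distance-tuned cell it must stay put.

`approachscan` implements the full analysis chain for such recordings —
spike-density estimation, bootstrap significance of response maxima, the
maximum-shift statistic with its resampled classification, population
summaries — together with a synthetic-recording generator that makes every
stage testable end to end, and a demonstrative "ratio code" decoder of
absolute distance.

## Viewing geometry

Under a small-angle pinhole model, one degree of visual angle corresponds
on the screen to `distance / degrees_per_radian` millimetres, so a grating
of period $p$ mm viewed from $D$ mm has retinal frequency

$$f(D) = \frac{D}{p \cdot 57.3} \;\text{cycles/degree}.$$

`eye_model()` fixes `degrees_per_radian = 57.3` (configurable); with the
12/6 mm near-space gratings this gives 1.5 and 3 c/deg at the 1.03 m start
position, and with the 38/19 mm distant-space gratings 0.09 and 0.18 c/deg
at the 0.2 m end position — the values quoted for the two protocols.
Inverting the relation, a cell preferring $f^\ast$ c/deg peaks at
$D^\ast = f^\ast p \cdot 57.3$ mm, so halving $p$ halves $D^\ast$
(`sf_peak_distance()`, `expected_shift_distance()`).

During approach at speed $V_2$, the projection of a screen point at
eccentricity $E$ (screen mm) drifts over the retina at
$V_1 = V_2 E D_1 / D_2^2$ mm/s, where $D_1$ is the eye diameter (13 mm);
conversion to deg/s multiplies by $57.3 / D_1 \approx 4.41$. We implement
the closed form rather than any rounded conversion constant. The quadratic
growth in $1/D_2$ is why the protocols keep the trolley slow: drift should
stay below the speeds that drive these cells for as much of the track as
possible.

## Protocols and trajectories

`protocol_distant()` (2.8 → 0.2 m at 1 cm/s, 4.3 min of motion, 38/19 mm
gratings) and `protocol_near()` (1.03 → 0.11 m at 1.7 mm/s, about 9 min,
12/6 mm gratings) bracket the trial with 60 s and 30 s stationary dwells.
`build_trajectory()` samples the piecewise-linear distance trace (default
0.1 s step, with the phase corners included exactly), and `distance_at()`
interpolates it. The rapid return to the start position is not part of a
trial record. One bookkeeping note: the 20 s window is sometimes said to
correspond to 18 cm of distant-space track, but 20 s at the nominal
1 cm/s is 20 cm; we use the nominal speed throughout (the near-space
figure, 3.4 cm, is exact).

## Spike density and response maxima

`spike_density()` uses a sliding rectangular window, 20 s long and stepped
every 0.01 s, dividing the spike count in each window (intersected with
the trial span) by the covered duration. The window is deliberately long:
these cells have very low ongoing rates and the free-gaze condition
produces incidental bursts, so the estimator must integrate over tens of
seconds to reveal distance-related structure. Rates are computed on the
time axis (the window is specified in seconds) and window centres are
mapped to distance through the trajectory; centres are restricted to the
approach phase, because only there does distance change. All trials of a
protocol share one grid, making maxima comparable across trials and
gratings. `average_density()` adds the pointwise mean and SEM;
`find_maximum()` takes the global argmax, breaking exact ties toward the
farthest distance (the window reached first, least contaminated by retinal
drift) and flagging flat curves as degenerate.

## Significance of a maximum

A maximum is only meaningful if it rises above what trial-to-trial
variability would produce around a flat firing profile.
`bootstrap_max_significance()` resamples trials with replacement (1000
times), averages each resample's *residual* curves (per-trial curve minus
the observed mean curve, scaled by $\sqrt{n/(n-1)}$), and adds them to the
across-track grand mean, producing realisations of a flat-null mean curve.
The observed maximum is significant if it exceeds the 95th percentile of
the null curves' maxima. Centring on the observed mean curve removes the
real response structure from the resampled noise, so the test is
calibrated by construction: on genuinely flat neurons it fires at about
the nominal rate (the test suite measures this over 200 simulated flat
Poisson cells), and taking the *maximum* of each null curve accounts for
the many correlated windows searched. A simpler band on the across-track
mean level alone would ignore that search and flag nearly every flat
neuron, so we use the max-calibrated construction. With identical trials
the null degenerates to the flat level and nothing is significant.

Both gratings' maxima must pass this test before any shift is computed;
the probability of a neuron passing both by chance is
$0.05 \times 0.05 = 0.0025$, and the population report prints the implied
expected false-discovery count rather than applying a per-neuron
correction.

## The shift statistic and classification

With $M_1$ and $M_2$ the maximum distances for the low- and high-frequency
gratings,

$$\mathrm{Shift} = \frac{M_1 - M_2}{M_2} \cdot 100\%,$$

so frequency tuning predicts 100% and distance tuning 0%. Each trial
contributes its own density argmax, and all $n_1 \times n_2$ trial pairs
(36 for six trials per grating) give the resampled shift distribution.
Classification uses the mean pairwise shift with an exact binomial sign
test (ties dropped) on the per-pair quantity $d - c \cdot r$, where
$d = M_1 - M_2$, $r = M_2$ is the full-shift reference implied by
$M_1 = 2 M_2$, and $c$ is the threshold:

* **shifting** — mean pairwise shift above 70% *and* the sign test rejects
  (at 0.05) that the median of $d - 0.7 r$ is at or below zero;
* **constant** — mean pairwise shift below 30% *and* the mirrored test
  rejects that the median of $d - 0.3 r$ is at or above zero;
* **unclassified** otherwise.

Two readings of this procedure are genuinely open. First, the null
hypothesis of the shifting-class sign test can be phrased in either
direction; we implement the one that mirrors the constant-class
construction, i.e. rejection demonstrates the maxima sit *beyond* the 70%
boundary. Second, "shift values above 70%" could mean the mean shift or
the fraction of pairwise shifts; we threshold the mean and report the
pair fraction alongside (`frac_above_shifting`, `frac_below_constant`).
The 30%/70% margins themselves reflect the empirical scatter (SD near
30%) of the classical frequency-tuned population under free gaze, applied
symmetrically to both classes. The label is invariant to a common
rescaling of all distances, as a ratio-based statistic must be.

## Boundary rules and the per-neuron pipeline

`classify_neuron()` chains the stages (densities → averaged maxima →
bootstrap → boundary rules → shift classification). Maxima cannot be
localised more finely than one smoothing-window span on the distance axis
(200 mm distant, 34 mm near), which is the default boundary tolerance.
Cells whose maxima for *all* gratings hug the closest position are
labelled `constant_at_min_distance` (monotonic rise toward the screen —
distance tuning whose optimum lies at or beyond the near end of the
track). Cells whose 1F maximum sits at the far boundary are unresolvable:
if the 2F maximum is closer than half the start distance, the implied 1F
optimum lies beyond the track and the cell is excluded as an outlier;
otherwise it is `monotonic_far_excluded`, since neither a constant
maximum beyond the track nor a shifting one can be ruled out. Cells with
a third (3F) grating are classified on 1F vs 2F only; the 2F-vs-3F shift
(50% expected for frequency tuning, 0% for distance tuning) is reported
as a consistency check. Neurons with any non-significant maximum are
`nonsignificant`; neurons with fewer than six usable trials per grating
after exclusions are `rejected` rather than silently dropped.

`run_population()` applies this to a list of recordings, conserves its
counts by construction (studied = classified + nonsignificant + excluded
categories), runs the population normality analysis, and collects the
constant-maximum positions. In the population shift distribution each
cell is represented by its *mean pairwise* shift — the quantity the sign
test assesses, and a far less noisy estimator than the single ratio of
two argmaxes (both are reported per neuron). The two-class picture
predicts that the pooled distribution fails a Lilliefors normality test
while the two clusters (split at 50%) individually pass, and that
constant-maximum positions cluster along the track; the position
clustering uses a one-dimensional Gaussian mixture with the number of
components (1–4) chosen by BIC.

## The synthetic generator

`simulate_recording()` draws spikes from an inhomogeneous Poisson process
(thinning against the tabulated intensity ceiling) whose intensity is an
archetype tuning function of the momentary distance multiplied by a
slowly varying gain. The archetypes realise the hypotheses the paradigm
tests: log-Gaussian spatial-frequency tuning in octaves (the standard V1
parameterisation), Gaussian distance tuning, logistic monotonic cells,
and flat nonresponsive cells. Free-gaze variability is modelled as an
Ornstein–Uhlenbeck process on the log gain with 5 s correlation time —
the analysis only ever sees its effect on 20 s window rates, so explicit
eye-movement modelling would add parameters without adding testable
structure. Gratings alternate 1F, 2F(, 3F) as in the recording protocol,
and the same seed always reproduces the same recording.

Defaults were chosen once to represent the study conditions: baseline
3 Hz and peak 15 Hz (peak/baseline 5, comfortably above the SNR at which
the paradigm is claimed to separate the classes), SF tuning sigma 0.5
octaves (FWHM about 1.2 octaves, the classic central-V1 bandwidth), gain
CV 0.15, SF optima drawn log-uniformly from the part of 0.25–2 c/deg
whose 1F *and* 2F maxima fall at least 1.5 window-spans inside the track,
distance optima uniform over the same interior band with tuning sigma
10% of track length. The generator emulates Poisson spiking, slow gain
drift, trial alternation and sleep-flag exclusions; it does *not* emulate
real eye movements, drift-driven excitation at short distances (an
optional archetype was considered and left out of v1), bursting, spike
sorting errors, or non-Poisson count statistics. Passing tests therefore
demonstrate that the analysis recovers the archetypes it formalises under
realistic noise — not that cortical data must behave this way.

## Numerical and validation choices

Tolerances and sizes used by the test-suite validation, chosen as the
package's own design: unit tests run density grids at 0.05–1 s steps
(the statistic is grid-insensitive at these scales; the default 0.01 s
step gives 0.1 mm distance resolution on the distant track); the
population validation runs 100 neurons (50 frequency-tuned + 50
distance-tuned) at a 0.02 s step for three pre-chosen seeds, requiring at
least 90% truth-label recovery in every run and the distributional
composite (empty 30–70% band, pooled Lilliefors rejection at 0.001 with
both clusters non-rejecting at 0.05) in at least two of three — with
three replicates a strict "90% of seeds" cannot be certified, and
two-of-three passes with high probability exactly when the per-seed rate
is near its claimed level. Bootstrap calibration is measured over 200
flat 5 Hz Poisson cells at a 0.05 s step (the construction is
step-independent). The exact sign test is verified against closed-form
binomial tails for all sign patterns up to $n = 36$.

## The ratio code

Constant-maximum cells are broadly tuned and strongly overlapping, so no
single cell identifies distance: rates are ambiguous across the peak and
confounded by stimulus gain. But the *ratios* of rates across cells
cancel any common gain — the same principle that makes three broadly
tuned cone classes suffice for hue — and vary steeply with distance
wherever the tuning curves' flanks cross. `decode_distance()` formalises
this: it matches observed rates to the population's tabulated curves by
least squares on centred log rates (algebraically the all-pairs
squared-log-ratio objective, up to a constant factor), with a small
`epsilon` (0.1 Hz) regularising near-zero rates. Centring removes the
gain exactly; identical tuning curves make the objective flat and the
decoder refuses rather than guessing. The proposal contributes the
decoding *principle* only, so the decoder design (log scale, grid argmin,
flatness flag) is this module's own, documented choice, and the Gaussian
demonstration curves (`gaussian_coding_population()`) are a stand-in for
tuning shapes the source material does not specify.

`ratio_code_rmse()` quantifies where decoding is precise: under additive
rate noise, the crossing region between two cells' curves — where both
rates are moderate and change in opposite directions — supports more
precise decoding than the peaks, where one cell carries no gradient and
the other's log-rate is noisiest relative to its slope. The test suite
verifies this flank-over-peak ordering for tuning widths of 300, 600 and
900 mm.

## Known limitations

* The bootstrap null construction is one reasonable reading of "95%
  bootstrap error bars"; the original toolbox's exact band is not
  recoverable from the text. Ours is chosen for calibration, which is the
  property the analysis depends on.
* The generator's archetypes are deliberately minimal; in particular
  drift-driven firing at short distances, which real distant-space
  records show, is not simulated, so the pipeline's robustness to it is
  untested here.
* The position-cluster analysis (Gaussian mixture by BIC) is descriptive;
  with the small constant-cell counts typical of one animal it should be
  read as a summary, not an inference.
* No multiple-testing correction is applied across neurons, matching the
  original analysis; the expected chance count (0.0025 per neuron) is
  reported instead.
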