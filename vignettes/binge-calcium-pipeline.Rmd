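---
title: "Methods: single-cell calcium trace analysis for binge-like eating sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell calcium trace analysis for binge-like eating sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bingetrace)
library(dplyr)
```

# The problem

Head-mounted miniature microscopes record the fluorescence of a calcium
indicator (here GCaMP6f) in tens of individually resolved neurons while an
animal behaves freely. In the recording design this package targets, a
palatable food stimulus is introduced halfway through a short session: two
minutes of baseline are followed by two minutes of response, acquired at 8
frames per second (a 125 ms frame period). Upstream acquisition software has
already motion-corrected the movie and extracted one fluorescence time
series per cell; the input to this package is that cells × frames matrix
plus a session schedule (stimulus onset, eating-bout onsets).

From these traces the pipeline answers four questions:

1. How does each cell's activity change when the food appears
   (ΔF/F₀ normalisation, up/down/non-response classification)?
2. When does each cell fire discrete calcium transients
   (median-filter detrending, MAD-threshold event detection)?
3. Which cells are time-locked to eating bouts (bout correlation)?
4. How does the population respond on average (heat-map ordering,
   paired pre/post test)?

Because recordings of this kind are rarely deposited, the package ships a
synthetic session generator with complete ground truth, and every stage is
validated by recovery from simulations rather than by comparison to an
archived dataset.

# The pipeline, stage by stage

## ΔF/F₀ (`compute_dff`)

Per cell, the baseline fluorescence F₀ is the mean raw fluorescence over the
pre-stimulus window (2 min by default), and

$$\Delta F/F_0(t) = \frac{F(t) - F_0}{F_0}.$$

The baseline standard deviation σ of ΔF/F₀ (sample s.d., ddof 1) is stored
with F₀ and reused verbatim by the classifier — one source of truth. The
mean was chosen as the F₀ estimator (over, say, a percentile or a median)
because the classification rule compares window *means*; using the same
statistic keeps the baseline mean of ΔF/F₀ exactly zero. A non-positive F₀
is a hard error: such a trace cannot be normalised and the cell must be
excluded upstream. ΔF/F₀ is exactly invariant under positive rescaling of
the raw fluorescence, and the tests assert this bit-exactly for power-of-two
scale factors (where floating point commutes with scaling).

Windows are half-open `[start, stop)` in seconds from session start; frame
k (0-based) covers `[k/fs, (k+1)/fs)`. All stages share this convention.

## Drift removal (`median_detrend`)

Slow drift (residual bleaching, lens warming, slow neuropil changes) is
estimated per cell as the sliding median of ΔF/F₀ in a 10-s window and
subtracted. At 8 frames/s the window is `round(10 × 8) = 80` samples,
forced odd to 81 so the window is centred; edges are handled by reflection
padding (mirror about the edge sample, excluding it), so the residual keeps
the input length. The sliding median passes a linear ramp unchanged
(interior residual ≈ 0) while leaving single-sample spikes at full height —
exactly the separation wanted between drift and transients. The filter is
`stats::runmed` behind the module surface; the tests check it against an
explicit per-window median loop.

## Transient detection (`detect_transients`)

The raw, unscaled MAD — `median(|x − median(x)|)`, no 1.4826 consistency
factor — is computed per cell on the *entire* detrended series, events
included. For Gaussian noise MAD ≈ 0.6745 σ, so the default 6-MAD threshold
corresponds to about 4.05 σ; applying the consistency factor would break
that equivalence, which is why the MAD is left unscaled. Computing the MAD
with events included inflates it slightly for very active cells; the
alternative (MAD of a presumed-quiet segment) would need an extra, arbitrary
choice of segment, so whole-series MAD is used.

Scanning left to right, an event is registered at the first sample whose
residual *strictly* exceeds `threshold_k × MAD` and that follows the
previous *accepted* event by at least `min_interval_s` (2 s), measured
onset-to-onset; the first event has no predecessor constraint, and
suprathreshold samples inside the refractory interval are absorbed into the
previous event. Ties exactly at threshold do not trigger. The event time is
the onset (threshold-crossing) sample, not the peak: onsets are what
bout-onset correlation needs. Time comparisons use a 1 ns slack so that a
gap of exactly 2 s (16 frames at 8 fps) registers regardless of how the
frame times were rounded. A flat cell (MAD = 0) yields zero events with a
warning rather than dividing the scan into nonsense.

`detection_metrics` scores a detected train against simulator ground truth
by greedy one-to-one matching in time order within a ±0.5 s tolerance;
sensitivity is matched/true, precision matched/detected (undefined, reported
NA, when nothing was detected).

## Response classification (`classify_cells`)

A cell is **up** if its mean ΔF/F₀ over the response window (first 2 min
after the stimulus) is strictly greater than its baseline mean + σ, **down**
if strictly less than baseline − σ, **non-response** otherwise — boundary
equality is non-response, reading "higher/lower than" strictly. The window
statistic is the time-average (configurable to the median). A cell with
σ = 0 and a non-zero response difference is classified by sign with a
warning. Summary percentages are rounded to one decimal by largest
remainder so they total 100.0, the convention of reported pie charts.

With 960 baseline frames the response-window mean of a pure-noise cell has
spread σ/√960, so the ±σ band is ~31 standard errors wide: the false-"up"
rate on independent noise is essentially zero (< 1% asserted). The band is
*not* adjusted for autocorrelated drift; that is faithful to the rule as
stated, and the simulator's drift (period-matched sinusoid) is constructed
so window means cancel — real photobleaching that is monotone across the
session would bias this classifier, a known limitation of the rule itself.

## Bout correlation (`correlate_bouts`)

For 1.5 min after the first eating bout, a cell counts as bout-correlated
if at least one of its transients falls within ±`tol_s` of any bout onset
inside that window; percentages are over all imaged cells. Two genuinely
open choices are made explicit:

- **Onset tolerance**: no standard exists for what "at the onset" means
  numerically; the default is ±1 s, it is a required, logged parameter, and
  the correlated fraction is (and is tested to be) monotone in it.
- **Windowed bouts**: bouts after `first bout + 90 s` are excluded from the
  counting; the alternative reading (any bout while food is present) is
  available by enlarging `window_s`.

Sessions with no eating bout raise an error; their cells never enter a
bout denominator, and `run_pipeline` logs the exclusion.

As a negative control, `shuffle_events` rigidly rotates each cell's train by
an independent uniform circular offset. For a rigid rotation the chance
level is exactly the measure of offsets that place any event in any bout
window (an interval-union computation), divided by the session length; the
acceptance tests verify the shuffled fraction matches this closed form
within Monte-Carlo error. A per-event Poisson approximation
`1 − exp(−m·W/T)` is deliberately *not* used as the reference: bout-locked
trains share the bouts' spacing, which makes their hit-offset sets overlap
and the Poisson form overestimate chance by several points.

## Session statistics (`paired_pre_post_test`, `make_heatmap_matrix`)

The paired two-tailed t test compares per-cell response-window means to
baseline-window means: `t = mean(d)/(sd(d)/√n)` with `n − 1` degrees of
freedom. All-zero differences return t = 0, p = 1 (a vacuous comparison);
constant non-zero differences raise a degenerate-test error since the
within-pair variance is zero. Heat maps are Gaussian-smoothed (display
only — detection and classification always run on unsmoothed data; default
σ = 0.5 s) and row-ordered by descending post-stimulus mean, ties kept in
input order (stable radix sort), with the permutation returned so rows stay
traceable.

# The synthetic session generator

`simulate_session` draws, per cell,

$$F(t) = F_0\,\bigl(1 + d(t) + s(t) + \textstyle\sum_i K(t-t_i)\bigr) + \varepsilon(t),$$

with i.i.d. Gaussian noise ε, drift d, a sustained step s for downregulated
cells, and a causal difference-of-exponentials kernel K normalised to unit
peak (rise 0.1 s, decay 1.0 s — GCaMP6f-like stand-ins; the indicator's true
amplitude and kinetics in this preparation are not published, so both are
configurable). Event times are homogeneous Poisson: background rate during
baseline, multiplied for "up" cells and suppressed to zero for "down" cells
after the stimulus; bout-locked cells add one transient within ±0.5 s of
every bout. Labels are apportioned deterministically by largest remainder
and assigned to cell indices in order, so a configured 33.3% of 57 cells is
exactly 19 cells. Each cell derives its own seed from the session seed and
its index, making sessions bit-reproducible and insensitive to adding cells.

Default conditions (chosen once as the simulated study design):

| parameter | default | rationale |
|---|---|---|
| `n_cells` | 57 | a typical pooled group size (40–60 cells) |
| `frame_rate_hz` | 8 | acquisition rate; 125 ms frame period |
| baseline / response | 120 s each | 2 min before and after food presentation |
| `f0_mean`, `f0_sd` | 100, 10 a.u. | arbitrary units; only ΔF/F₀ matters downstream |
| `noise_sigma` | 2 a.u. | σ(ΔF/F₀) = 0.02, a clean miniscope recording |
| `transient_amplitude` | 8 × noise σ | comfortably above the ~4 σ detection threshold |
| `background_rate_hz` | 0.025 | 1.5 transients/min, sparse-firing hypothalamic neurons |
| `up_rate_multiplier` | 3 | a modest, realistic post-stimulus rate increase |
| `down_step_sigma` | 2 | sustained −2 σ step; the mechanism of downregulation is unobserved, only its classification |
| drift | 0.05·F₀, 120 s period (+10% linear) | exercises the 10-s median filter without modelling photobleaching chemistry |

The drift period equals the window length so that sinusoidal drift cancels
in window means regardless of phase; the small linear component leaves a
0.25-σ residual bias, well inside the ±σ band.

`scenario_preset` provides recovery-check scenarios for seven study
conditions: four classification presets with configured up-fractions 33.3%,
12.1%, 39.5% and 49.0% and deliberately strong effects (post-stimulus rate
multiplier 40 ⇒ ~8 σ mean uplift, down step −3 σ, 0.02 Hz background) so
every configured label is recoverable by the ±σ rule, and three bout
presets with locked fractions 13.9%, 41.9% and 27.9%, five bouts 15 s apart
from 130 s, and a near-silent 0.001 Hz background so locking dominates
chance coincidence. These presets parameterise the simulator after reported
population proportions; they are recovery checks of the pipeline, not
re-creations of the in-vivo recordings.

What the generator does **not** emulate: photon shot noise and its
intensity dependence, movement artifacts, neuropil contamination, ROI
cross-talk, monotone photobleaching, bursty (non-Poisson) firing, and
cell-to-cell kinetic heterogeneity. Passing recovery tests therefore shows
the pipeline implements its rules correctly and is well calibrated under
idealised noise — not that those rules are optimal for any particular real
recording.

# Validation and problem sizes

The test suite validates each stage against independent oracles: explicit
per-window median loops, a sample-by-sample re-implementation of the
detection scan (50 random 500-sample traces, event-for-event equality),
`stats::t.test` for the paired test (100 random pairs, 1e-10), hand-computed
peri-event means, and the interval-union chance level for the shuffle
control. Recovery checks run at 150–500 cells for detection (sensitivity
and precision ≥ 0.90 at ±0.5 s under the default scenario), 300–1,000 cells
for classification (≥ 99% correct labels, fractions within ±2 points), and
200–500 cells for bout correlation (locked fraction within ±3 points);
`scripts/acceptance.R` re-runs the full set at the upper sizes in under a
minute. Null calibrations use 300–1,000 pure-noise cells and 20 shuffle
repetitions.

A worked end-to-end example:

```{r pipeline-example}
session <- simulate_session(scenario_config(
  n_cells = 30, seed = 1,
  bout_onsets_s = c(130, 145, 160, 175, 190), bout_locked_fraction = 0.3))
result <- run_pipeline(session$traces, session$schedule)
result
glance(detection_metrics(result$events, session$truth, 0.5))
```

```{r plots, fig.width = 6, fig.height = 4, eval = FALSE}
library(ggplot2)
autoplot(result$heatmap)
plot_class_summary(result$class_summary)
```

# Known limitations

- The ±σ classifier ignores temporal autocorrelation; slow monotone drift
  biases it (by design fidelity to the rule, see above).
- Whole-series MAD slightly overestimates noise for very active cells,
  making the effective threshold conservative for them.
- Events closer together than the 2-s refractory interval are merged by
  construction; at high post-stimulus rates (≳ 0.3 Hz) this caps detection
  sensitivity, which is why the default scenario keeps rates sparse.
- Cells are never matched across sessions; all comparisons are
  within-session, and the paired test pools cells within the analysed set.
- Bout-correlation chance grows with background rate and tolerance; the
  shuffle control should accompany any reported correlated fraction.
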