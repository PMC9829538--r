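# bingetrace

Single-cell calcium trace analysis for binge-like eating imaging sessions.

`bingetrace` implements, as a tested and reusable R pipeline, the analysis
applied to head-mounted miniscope recordings of hypothalamic neurons around
the introduction of a palatable food stimulus (2 min baseline + 2 min
response at 8 frames/s):

- **ΔF/F₀ normalisation** — per cell, `(F − F₀)/F₀` with F₀ the mean raw
  fluorescence over the 2-min pre-stimulus baseline; the baseline σ of
  ΔF/F₀ is stored alongside.
- **Median-filter detrending** — slow drift estimated by a 10-s sliding
  median (81 samples at 8 fps, reflection-padded) and subtracted.
- **Transient detection** — upward excursions of the detrended trace that
  strictly exceed 6 × the raw MAD of the whole series (≈ 4 σ for Gaussian
  noise, since MAD ≈ 0.6745 σ), with a 2-s onset-to-onset refractory
  interval.
- **Response classification** — a cell is *up* if its mean ΔF/F₀ over the
  first 2 min after the stimulus exceeds baseline + σ, *down* if below
  baseline − σ, *non-response* otherwise.
- **Bout correlation** — the fraction of cells with ≥ 1 transient within
  ±1 s of an eating-bout onset during the 1.5 min after the first bout.
- **Session statistics** — Gaussian-smoothed heat maps sorted by descending
  post-stimulus response, and a two-tailed paired t test of per-cell
  post vs pre window means.

Because recordings of this kind are rarely deposited, the package includes
a synthetic GCaMP session generator (`simulate_session()`) with complete
ground truth — Poisson transients convolved with a difference-of-exponentials
kernel, slow drift, Gaussian noise, configurable up/down/non-response
subpopulations and bout-locked cells — so every stage is validated by
recovery. It is aimed at researchers analysing per-cell fluorescence time
series exported from miniscope acquisition software, and at anyone needing
a fully specified reference implementation of this analysis recipe.

## Worked example

```r
library(bingetrace)

session <- simulate_session(scenario_config(
  n_cells = 30, seed = 1,
  bout_onsets_s = c(130, 145, 160, 175, 190),
  bout_locked_fraction = 0.3))

result <- run_pipeline(session$traces, session$schedule)
result
#> <ca_analysis> 'ReHFD-1': 30 cells, 261 transients
#>   classes: up 0% / down 0% / non 100%
#>   bout-correlated: 15/30 cells (50%)
#>   paired pre/post: t_29 = 3.206, p = 0.00327
#>   config hash: 124ce0396bfa3e69a4b8f33bfceaa67b

glance(detection_metrics(result$events, session$truth, match_tol_s = 0.5))
#> # A tibble: 1 × 5
#>   sensitivity precision n_true n_detected n_matched
#>         <dbl>     <dbl>  <int>      <int>     <int>
#> 1       0.921     0.981    278        261       256
```

Reading the output: detection recovered 92% of the 278 injected transients
with 98% precision at ±0.5 s. The paired t test shows the population mean
ΔF/F₀ rose after food introduction, yet no single cell crossed the ±σ band:
the default scenario uses a deliberately modest rate increase (3×) for its
"up" cells, and per-cell classification demands a full σ of sustained
uplift (the `scenario_preset()` scenarios use strong effects and are
recovered label-for-label). 15 cells (50%) produced a transient within
±1 s of a bout onset in the 90 s after the first bout — the configured 30%
of bout-locked cells plus chance coincidences from the spontaneous
transients of the remaining cells; circularly shifting the trains with
`shuffle_events()` quantifies exactly that chance level, which is why the
shuffle control should accompany any reported correlated fraction.

Each result element is a tibble (or has `tidy()`/`glance()` methods), so
stages compose with the pipe:

```r
session$traces |>
  compute_dff(baseline_window = c(0, 120)) |>
  median_detrend(filter_width_s = 10) |>
  detect_transients(threshold_k = 6, min_interval_s = 2)
```

`autoplot(result$heatmap)`, `plot_class_summary()`, `plot_traces()` and
`plot_peri_event()` produce the standard displays. `write_report()`
persists every stage artifact (delimited text + JSON, with the config hash
embedded) byte-reproducibly, and `inst/cli/bingetrace.R` exposes
`simulate`/`analyze` subcommands for shell use.

## Package layout

- `R/` — simulator (`scenario.R`, `simulate.R`), trace processing
  (`dff.R`), event detection (`detect.R`), classification (`classify.R`),
  bout alignment (`bouts.R`), session statistics and pipeline
  (`report.R`), text/JSON I/O (`io.R`), ggplot2 helpers (`plot.R`).
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles in `helper-oracles.R`.
- `vignettes/binge-calcium-pipeline.Rmd` — the methods vignette: model,
  parameter rationale, numerical choices, what the simulator does and does
  not emulate, limitations.
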