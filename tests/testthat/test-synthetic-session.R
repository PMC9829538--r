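# Synthetic session generator: kernel shape, determinism, ground-truth
# bookkeeping and label apportionment.

test_that("transient kernel is causal, unit-peak-normalised and decaying", {
  expect_identical(transient_kernel(-1), 0)
  expect_identical(transient_kernel(c(-5, -0.001)), c(0, 0))
  expect_equal(transient_kernel(c(0.1, 0.5, 3), amplitude = 0), c(0, 0, 0))

  # numeric maximisation of the normalised kernel over a dense grid
  grid <- seq(0, 10, by = 1e-5)
  expect_equal(max(transient_kernel(grid, 0.1, 1, 1)), 1, tolerance = 1e-6)
  expect_equal(max(transient_kernel(grid, 0.05, 2, 3.5)), 3.5, tolerance = 1e-6)
  expect_lt(transient_kernel(10, 0.1, 1, 1), 1e-4)

  expect_error(transient_kernel(1, tau_rise_s = 0), class = "bingetrace_parameter_error")
  expect_error(transient_kernel(1, tau_rise_s = 2, tau_decay_s = 1),
               class = "bingetrace_parameter_error")
})

test_that("scenario validation rejects malformed configurations", {
  expect_error(scenario_config(fractions = c(up = 0.5, down = 0.4, non_response = 0.2)),
               class = "bingetrace_parameter_error")
  expect_error(scenario_config(fractions = c(up = -0.1, down = 0.5, non_response = 0.6)),
               class = "bingetrace_parameter_error")
  expect_error(scenario_config(n_cells = 0), class = "bingetrace_parameter_error")
  expect_error(scenario_config(background_rate_hz = -1), class = "bingetrace_parameter_error")
  expect_error(scenario_config(tau_rise_s = 2, tau_decay_s = 1),
               class = "bingetrace_parameter_error")
  expect_error(scenario_config(bout_onsets_s = c(130, 125)),
               class = "bingetrace_parameter_error")
  expect_error(scenario_config(bout_onsets_s = c(60)),   # before stimulus
               class = "bingetrace_parameter_error")
})

test_that("noise-free, drift-free, event-free traces are constant at F0", {
  cfg <- scenario_config(n_cells = 3, background_rate_hz = 0, noise_sigma = 0,
                         drift_amplitude = 0, f0_sd = 0, seed = 4)
  s <- simulate_session(cfg)
  per_cell <- split(s$traces$fluor, s$traces$cell_id)
  for (i in seq_along(per_cell)) {
    expect_equal(per_cell[[i]], rep(s$truth$cells$f0_true[i], 1920))
  }
  expect_identical(nrow(s$truth$events), 0L)
})

test_that("identical configuration and seed reproduce the session exactly", {
  cfg <- scenario_config(n_cells = 8, seed = 42,
                         bout_onsets_s = c(125, 150), bout_locked_fraction = 0.5)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$truth$events, s2$truth$events)
  s3 <- simulate_session(scenario_config(n_cells = 8, seed = 43,
                                         bout_onsets_s = c(125, 150),
                                         bout_locked_fraction = 0.5))
  expect_false(identical(s1$traces$fluor, s3$traces$fluor))
})

test_that("adding cells does not perturb existing cells", {
  small <- simulate_session(scenario_config(
    n_cells = 6, seed = 9, fractions = c(up = 0, down = 0, non_response = 1)))
  large <- simulate_session(scenario_config(
    n_cells = 10, seed = 9, fractions = c(up = 0, down = 0, non_response = 1)))
  for (i in 1:6) {
    a <- small$traces$fluor[small$traces$cell_id == levels(small$traces$cell_id)[i]]
    b <- large$traces$fluor[large$traces$cell_id == levels(large$traces$cell_id)[i]]
    expect_identical(a, b)
  }
})

test_that("largest-remainder apportionment recovers configured fractions", {
  cfg <- scenario_config(n_cells = 57,
                         fractions = c(up = 0.333, down = 0.053, non_response = 0.614),
                         seed = 1)
  s <- simulate_session(cfg)
  counts <- table(s$truth$cells$label)
  expect_identical(as.integer(counts[["up"]]), 19L)
  expect_identical(as.integer(counts[["non_response"]]), 35L)
  expect_identical(as.integer(counts[["down"]]), 3L)

  # property: counts always sum to n and are within 1 of the exact quota
  for (n in c(1, 7, 58, 113)) {
    fr <- c(up = 0.395, down = 0.1, non_response = 0.505)
    cnt <- bingetrace:::largest_remainder(fr, n)
    expect_identical(sum(cnt), as.integer(n))
    expect_true(all(abs(cnt - fr * n) < 1))
  }
})

test_that("session geometry and invariants hold", {
  cfg <- scenario_config(n_cells = 5, seed = 12,
                         bout_onsets_s = c(130, 140), bout_locked_fraction = 1)
  s <- simulate_session(cfg)
  expect_identical(nrow(s$traces), 5L * 1920L)
  expect_true(all(is.finite(s$traces$fluor)))
  expect_true(all(s$traces$fluor >= 0))
  expect_true(all(s$truth$events$event_time_s >= 0 &
                  s$truth$events$event_time_s < 240))
  expect_true(all(tapply(s$truth$events$event_time_s,
                         s$truth$events$cell_id,
                         function(x) !is.unsorted(x))))
  expect_identical(s$schedule$stimulus_onset_s, 120)
  expect_identical(s$schedule$session_duration_s, 240)
})

test_that("bout-locked cells emit exactly one transient near every bout", {
  cfg <- scenario_config(n_cells = 4, seed = 21, background_rate_hz = 0,
                         fractions = c(up = 0, down = 0, non_response = 1),
                         bout_onsets_s = c(130, 150, 170), bout_locked_fraction = 1,
                         bout_jitter_s = 0.5)
  s <- simulate_session(cfg)
  ev_by <- split(s$truth$events$event_time_s, s$truth$events$cell_id)
  for (ev in ev_by) {
    expect_length(ev, 3)
    expect_true(all(abs(ev - c(130, 150, 170)) <= 0.5))
  }
})

test_that("empirical noise sigma matches the configured sigma within 5%", {
  cfg <- scenario_config(n_cells = 4, background_rate_hz = 0, drift_amplitude = 0,
                         noise_sigma = 2, f0_sd = 0, seed = 33)
  s <- simulate_session(cfg)
  sds <- tapply(s$traces$fluor, s$traces$cell_id, sd)
  expect_true(all(abs(sds - 2) / 2 < 0.05))
})

test_that("true drift traces reconstruct the injected slow component", {
  cfg <- scenario_config(n_cells = 2, background_rate_hz = 0, noise_sigma = 0,
                         f0_sd = 0, drift_amplitude = 0.05, seed = 5)
  s <- simulate_session(cfg)
  d <- true_drift(s$truth, "cell_001")
  f <- s$traces$fluor[s$traces$cell_id == "cell_001"]
  expect_equal(f, 100 * (1 + d$drift))
})
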