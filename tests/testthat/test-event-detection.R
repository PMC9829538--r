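# MAD computation, threshold-scan transient detection and ground-truth scoring.

test_that("raw MAD matches hand enumeration and the Gaussian constant", {
  expect_identical(compute_mad(c(5, 5, 5)), 0)
  # median 3; |devs| = 2,1,0,1,97; median 1
  expect_identical(compute_mad(c(1, 2, 3, 4, 100)), 1)
  expect_error(compute_mad(numeric(0)), class = "bingetrace_parameter_error")
  expect_error(compute_mad(c(1, NA)), class = "bingetrace_parameter_error")

  set.seed(99)
  expect_equal(compute_mad(rnorm(1e6)), qnorm(0.75), tolerance = 0.005 / 0.6745)
})

test_that("detection follows the scan rule on designed pulse traces", {
  fs <- 8
  # all-zero residual: flat trace, zero MAD -> no events, warning
  expect_warning(ev0 <- detect_transients(toy_detrended(rep(0, 400))),
                 "zero MAD")
  expect_identical(nrow(ev0), 0L)

  # pulses 1 s apart merge under the 2-s refractory interval
  x <- pulse_trace(800, pulse_at_s = c(10, 11))
  ev <- detect_transients(toy_detrended(x))
  expect_equal(ev$event_time_s, 10)

  # pulses 3 s apart are two events
  x2 <- pulse_trace(800, pulse_at_s = c(10, 13))
  ev2 <- detect_transients(toy_detrended(x2))
  expect_equal(ev2$event_time_s, c(10, 13))

  # a peak exactly at 6 MAD does not trigger ("exceeded" is strict)
  x3 <- rep(c(1, -1), 101)
  x3[100] <- 6
  expect_identical(compute_mad(x3), 1)
  ev3 <- detect_transients(toy_detrended(x3))
  expect_identical(nrow(ev3), 0L)
  x3[100] <- 6.000001
  ev4 <- detect_transients(toy_detrended(x3))
  expect_identical(nrow(ev4), 1L)

  expect_error(detect_transients(toy_detrended(x), threshold_k = 0),
               class = "bingetrace_parameter_error")
  expect_error(detect_transients(toy_detrended(x), min_interval_s = -1),
               class = "bingetrace_parameter_error")
})

test_that("detection equals a brute-force scan oracle on random traces", {
  fs <- 8
  for (seed in 1:50) {
    set.seed(seed)
    x <- rnorm(500)
    spikes <- sample(500, 8)
    x[spikes] <- x[spikes] + runif(8, 2, 6)
    times <- (0:499) / fs
    ev <- detect_transients(toy_detrended(x, fs))
    thr <- 6 * compute_mad(x)
    expect_identical(ev$event_time_s, brute_detect(x, times, thr, 2))
  }
})

test_that("event trains respect the refractory interval on real pipeline output", {
  s <- simulate_session(scenario_config(n_cells = 40, seed = 14))
  ev <- s$traces |> compute_dff(c(0, 120)) |> median_detrend() |> detect_transients()
  gaps <- tapply(ev$event_time_s, ev$cell_id, function(x) {
    if (length(x) < 2) Inf else min(diff(x))
  })
  expect_true(all(gaps >= 2 - 1e-9))
  expect_true(all(tapply(ev$event_time_s, ev$cell_id,
                         function(x) !is.unsorted(x, strictly = TRUE))))
})

test_that("event count is non-increasing in the threshold multiple", {
  set.seed(8)
  x <- rnorm(1000)
  x[sample(1000, 20)] <- x[sample(1000, 20)] + 5
  d <- toy_detrended(x)
  counts <- vapply(c(1, 2, 4, 6, 8, 12),
                   function(k) nrow(detect_transients(d, threshold_k = k)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is invariant under positive rescaling of the residual", {
  set.seed(23)
  x <- rnorm(800)
  x[c(100, 400, 700)] <- x[c(100, 400, 700)] + 6
  ev1 <- detect_transients(toy_detrended(x))
  ev2 <- detect_transients(toy_detrended(2 * x))      # exact in floating point
  ev3 <- detect_transients(toy_detrended(0.25 * x))
  expect_identical(ev1$event_time_s, ev2$event_time_s)
  expect_identical(ev1$event_time_s, ev3$event_time_s)
})

test_that("detection metrics implement greedy one-to-one matching", {
  tr <- tibble::tibble(cell_id = "cell_001", event_time_s = c(10, 50, 90))
  same <- detection_metrics(tr, tr, 0.5)
  expect_equal(same$summary$sensitivity, 1)
  expect_equal(same$summary$precision, 1)

  none <- tibble::tibble(cell_id = character(0), event_time_s = numeric(0))
  m0 <- detection_metrics(none, tr, 0.5)
  expect_equal(m0$summary$sensitivity, 0)
  expect_true(is.na(m0$summary$precision))

  det <- tibble::tibble(cell_id = "cell_001", event_time_s = 10.4)
  tru <- tibble::tibble(cell_id = "cell_001", event_time_s = 10)
  expect_equal(detection_metrics(det, tru, 0.5)$summary$n_matched, 1L)
  expect_equal(detection_metrics(det, tru, 0.3)$summary$n_matched, 0L)

  # matching is one-to-one: two detections cannot share one true event
  det2 <- tibble::tibble(cell_id = "cell_001", event_time_s = c(9.8, 10.2))
  m2 <- detection_metrics(det2, tru, 0.5)
  expect_equal(m2$summary$n_matched, 1L)
  expect_equal(m2$summary$precision, 0.5)
})

test_that("transients are recovered from the default scenario", {
  s <- simulate_session(scenario_config(n_cells = 150, seed = 2024))
  ev <- s$traces |> compute_dff(c(0, 120)) |> median_detrend() |> detect_transients()
  m <- glance(detection_metrics(ev, s$truth, 0.5))
  expect_gte(m$sensitivity, 0.90)
  expect_gte(m$precision, 0.90)
})
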