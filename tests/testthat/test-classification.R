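# Up / down / non-response classification and population summaries.

# Raw trace with an alternating-sign baseline (known F0 = 100 and sigma) and a
# constant post-stimulus level, on a 40 s session with stimulus at 20 s.
two_level_trace <- function(post_f, base_amp = 5) {
  c(rep(c(100 + base_amp, 100 - base_amp), 80), rep(post_f, 160))
}

test_that("the +/- sigma rule forces the expected labels", {
  sig <- sd(rep(c(0.05, -0.05), 80))  # baseline sigma on the dff scale
  mat <- rbind(two_level_trace(110),                  # +0.10 >> sigma -> up
               two_level_trace(90),                   # -0.10 -> down
               two_level_trace(100))                  # 0 -> non_response
  cl <- toy_traces(mat) |>
    compute_dff(c(0, 20)) |>
    classify_cells(c(20, 40))
  expect_identical(as.character(cl$label), c("up", "down", "non_response"))
  expect_equal(cl$sigma, rep(sig, 3))
  expect_equal(cl$post_mean[1], 0.10)
  expect_equal(cl$margin[1], 0.10 / sig)
})

test_that("boundary equality at +/- sigma counts as non-response", {
  # dff object with exactly controlled baseline statistics
  make_dff <- function(post_value, sigma) {
    x <- c(rep(0, 160), rep(post_value, 160))
    d <- tibble::tibble(cell_id = factor("cell_001"),
                        time_s = (0:319) / 8, dff = x)
    attr(d, "frame_rate_hz") <- 8
    attr(d, "baseline_window") <- c(0, 20)
    attr(d, "baseline") <- tibble::tibble(
      cell_id = factor("cell_001"), f0 = 100, baseline_mean = 0, sigma = sigma)
    class(d) <- c("dff_traces", class(d))
    d
  }
  at_sigma <- classify_cells(make_dff(0.05, sigma = 0.05), c(20, 40))
  expect_identical(as.character(at_sigma$label), "non_response")
  above <- classify_cells(make_dff(0.05, sigma = 0.04), c(20, 40))
  expect_identical(as.character(above$label), "up")
  at_neg <- classify_cells(make_dff(-0.05, sigma = 0.05), c(20, 40))
  expect_identical(as.character(at_neg$label), "non_response")
  below <- classify_cells(make_dff(-0.05, sigma = 0.04), c(20, 40))
  expect_identical(as.character(below$label), "down")
})

test_that("zero-sigma cells are classified by sign with a warning", {
  mat <- rbind(c(rep(100, 160), rep(110, 160)),
               c(rep(100, 160), rep(90, 160)))
  dff <- compute_dff(toy_traces(mat), c(0, 20))
  expect_warning(cl <- classify_cells(dff, c(20, 40)), "zero baseline sigma")
  expect_identical(as.character(cl$label), c("up", "down"))
})

test_that("malformed windows are rejected", {
  dff <- compute_dff(toy_traces(matrix(100, 2, 320)), c(0, 20))
  expect_error(classify_cells(dff, c(10, 30)), class = "bingetrace_window_error")
  expect_error(classify_cells(dff, c(20, 300)), class = "bingetrace_window_error")
})

test_that("every cell gets exactly one label and proportions sum to 1", {
  s <- simulate_session(scenario_preset("elt-rehfd1", n_cells = 60, seed = 6))
  cl <- s$traces |> compute_dff(c(0, 120)) |> classify_cells(c(120, 240))
  expect_identical(nrow(cl), 60L)
  expect_false(any(is.na(cl$label)))
  sm <- summarize_classes(cl, "ELT ReHFD-1")
  expect_identical(sum(sm$n), 60L)
  expect_equal(sum(sm$prop), 1, tolerance = 1e-12)
  expect_equal(sum(sm$pct), 100)
})

test_that("summary percentages match reported-style rounding", {
  lab <- function(n_up, n_down, n_non) {
    tibble::tibble(label = rep(c("up", "down", "non_response"),
                               c(n_up, n_down, n_non)))
  }
  s1 <- summarize_classes(lab(19, 3, 35))    # 19/57
  expect_equal(s1$pct[s1$label == "up"], 33.3)
  s2 <- summarize_classes(lab(7, 5, 46))     # 7/58
  expect_equal(s2$pct[s2$label == "up"], 12.1)
  s3 <- summarize_classes(lab(10, 0, 0))
  expect_equal(s3$pct, c(100, 0, 0))
  expect_error(summarize_classes(lab(0, 0, 0)),
               class = "bingetrace_parameter_error")
})

test_that("raising the post-stimulus level never moves a label toward down", {
  rank <- c(down = 1, non_response = 2, up = 3)
  labels <- vapply(c(90, 95, 99, 100, 101, 105, 110), function(f) {
    cl <- toy_traces(rbind(two_level_trace(f))) |>
      compute_dff(c(0, 20)) |>
      classify_cells(c(20, 40))
    as.character(cl$label)
  }, character(1))
  expect_true(all(diff(rank[labels]) >= 0))
})

test_that("pure noise cells are almost never labelled up (null calibration)", {
  cfg <- scenario_config(n_cells = 300, background_rate_hz = 0,
                         drift_amplitude = 0, seed = 77)
  s <- simulate_session(cfg)
  cl <- s$traces |> compute_dff(c(0, 120)) |> classify_cells(c(120, 240))
  expect_lt(mean(cl$label == "up"), 0.01)
})

test_that("configured labels are recovered on a strong-effect scenario", {
  s <- simulate_session(scenario_preset("control-rehfd1", n_cells = 300, seed = 123))
  cl <- s$traces |> compute_dff(c(0, 120)) |> classify_cells(c(120, 240))
  truth <- s$truth$cells$label
  expect_gte(mean(as.character(cl$label) == truth), 0.99)
  sm <- summarize_classes(cl)
  expect_lt(abs(sm$prop[sm$label == "up"] - 0.333), 0.02)
})
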