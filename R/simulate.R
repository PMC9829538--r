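#' Calcium transient kernel
#'
#' Difference-of-exponentials impulse response used to inject transients into
#' synthetic traces, normalised internally so its peak equals `amplitude`.
#' With the GCaMP6f-like defaults (rise 0.1 s, decay 1 s) the kernel peaks
#' about 0.26 s after onset. It is causal: zero for `t_s < 0`, decaying to
#' zero as `t_s` grows.
#'
#' @param t_s Time since transient onset (s); any numeric vector.
#' @param tau_rise_s,tau_decay_s Positive time constants (s) with
#'   `tau_rise_s < tau_decay_s`.
#' @param amplitude Peak height (\eqn{\Delta F/F_0} units).
#' @return Numeric vector of fluorescence contributions, same length as `t_s`.
#' @examples
#' transient_kernel(c(-1, 0, 0.26, 5))
#' @export
transient_kernel <- function(t_s, tau_rise_s = 0.1, tau_decay_s = 1, amplitude = 1) {
  check_positive(tau_rise_s, "tau_rise_s")
  check_positive(tau_decay_s, "tau_decay_s")
  if (tau_rise_s >= tau_decay_s) {
    abort("`tau_rise_s` must be smaller than `tau_decay_s`.",
          class = "bingetrace_parameter_error")
  }
  t_peak <- log(tau_decay_s / tau_rise_s) * tau_rise_s * tau_decay_s /
    (tau_decay_s - tau_rise_s)
  peak <- exp(-t_peak / tau_decay_s) - exp(-t_peak / tau_rise_s)
  out <- numeric(length(t_s))
  pos <- which(t_s >= 0)
  out[pos] <- amplitude *
    (exp(-t_s[pos] / tau_decay_s) - exp(-t_s[pos] / tau_rise_s)) / peak
  out
}

# Per-cell seed derived from the session seed so that cell i's trace depends
# only on (seed, i): adding cells never perturbs existing ones.
cell_seed <- function(seed, i) {
  (as.numeric(seed) + 7919 * i) %% .Machine$integer.max
}

#' Simulate a synthetic imaging session with known ground truth
#'
#' Generates per-cell fluorescence traces for a session consisting of a
#' pre-stimulus baseline and a post-stimulus response period, following the
#' generative model
#' \deqn{F(t) = F_0 (1 + d(t) + s(t) + \sum_i K(t - t_i)) + \epsilon(t)}
#' with slow drift \eqn{d(t)}, a sustained negative step \eqn{s(t)} for
#' downregulated cells after the stimulus, unit-peak transient kernels
#' \eqn{K} ([transient_kernel()]) at Poisson event times \eqn{t_i}, and
#' i.i.d. Gaussian noise \eqn{\epsilon}. `up` cells multiply their transient
#' rate after the stimulus, `down` cells suppress it to zero, and
#' bout-locked cells emit one extra transient near every eating-bout onset.
#' All injected event times, labels and per-cell parameters are returned as
#' ground truth, so downstream detection and classification can be scored by
#' recovery.
#'
#' @param config A [scenario_config()].
#' @return A list of class `ca_session` with elements
#'   \describe{
#'     \item{traces}{long tibble `cell_id`, `time_s`, `fluor` (a.u.), with
#'       `frame_rate_hz` and `t0_s` attributes,}
#'     \item{schedule}{an `event_schedule` (stimulus onset, bout onsets,
#'       session duration, condition),}
#'     \item{truth}{a `ground_truth` list: per-cell tibble `cells`
#'       (label, bout_locked flag, F0, noise sigma, drift parameters), event
#'       tibble `events` (`cell_id`, `event_time_s`), and the scenario echo.}
#'   }
#' @examples
#' s <- simulate_session(scenario_config(n_cells = 4, seed = 7))
#' dplyr::count(s$truth$cells, label)
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  validate_scenario(config)
  cfg <- config
  fs <- cfg$frame_rate_hz
  stim <- cfg$baseline_duration_s
  dur <- cfg$baseline_duration_s + cfg$response_duration_s
  n_frames <- round(dur * fs)
  times <- frame_times(n_frames, fs)
  n <- cfg$n_cells

  counts <- largest_remainder(
    c(cfg$fractions[["up"]], cfg$fractions[["down"]], cfg$fractions[["non_response"]]), n)
  labels <- rep(c("up", "down", "non_response"), counts)
  n_locked <- round(cfg$bout_locked_fraction * n)
  locked <- seq_len(n) <= n_locked & !is.null(cfg$bout_onsets_s)
  ids <- make_cell_ids(n)

  # kernel values decay below 1e-4 of peak well before 10 decay constants
  kern_len <- min(n_frames, ceiling(10 * cfg$tau_decay_s * fs))

  cells <- vector("list", n)
  events <- vector("list", n)
  mats <- vector("list", n)
  for (i in seq_len(n)) {
    res <- with_seed(cell_seed(cfg$seed, i), {
      f0 <- max(rnorm(1, cfg$f0_mean, cfg$f0_sd), 0.05 * cfg$f0_mean)
      phase <- runif(1, 0, 2 * pi)
      n_base <- rpois(1, cfg$background_rate_hz * stim)
      t_base <- sort(runif(n_base, 0, stim))
      post_rate <- switch(labels[i],
        up = cfg$background_rate_hz * cfg$up_rate_multiplier,
        down = 0,
        non_response = cfg$background_rate_hz)
      n_post <- rpois(1, post_rate * (dur - stim))
      t_post <- sort(runif(n_post, stim, dur))
      t_bout <- if (locked[i]) {
        b <- cfg$bout_onsets_s +
          runif(length(cfg$bout_onsets_s), -cfg$bout_jitter_s, cfg$bout_jitter_s)
        pmin(pmax(b, 0), dur - 1 / fs)
      } else numeric(0)
      ev <- sort(c(t_base, t_post, t_bout))
      noise <- rnorm(n_frames, 0, cfg$noise_sigma)
      list(f0 = f0, phase = phase, ev = ev, noise = noise)
    })

    sigma_dff <- cfg$noise_sigma / res$f0
    sig <- drift_trace_values(times, dur, cfg$drift_amplitude,
                              cfg$drift_period_s, res$phase)
    if (labels[i] == "down") {
      sig[times >= stim] <- sig[times >= stim] - cfg$down_step_sigma * sigma_dff
    }
    amp <- cfg$transient_amplitude * sigma_dff
    for (e in res$ev) {
      k0 <- floor(e * fs) + 1            # first frame at/after onset frame
      if (k0 > n_frames) next
      k1 <- min(n_frames, k0 + kern_len - 1)
      idx <- k0:k1
      sig[idx] <- sig[idx] +
        transient_kernel(times[idx] - e, cfg$tau_rise_s, cfg$tau_decay_s, amp)
    }
    mats[[i]] <- pmax(res$f0 * (1 + sig) + res$noise, 0)
    cells[[i]] <- tibble(
      cell_id = ids[i], label = labels[i], bout_locked = locked[i],
      f0_true = res$f0, noise_sigma_true = cfg$noise_sigma,
      sigma_dff_true = sigma_dff, drift_phase = res$phase)
    events[[i]] <- tibble(cell_id = rep(ids[i], length(res$ev)),
                          event_time_s = res$ev)
  }

  traces <- tibble(
    cell_id = rep(ids, each = n_frames),
    time_s = rep(times, n),
    fluor = unlist(mats))
  traces <- set_trace_attrs(traces, frame_rate_hz = fs, t0_s = 0)
  class(traces) <- c("raw_traces", class(traces))

  schedule <- event_schedule(
    stimulus_onset_s = stim,
    bout_onsets_s = cfg$bout_onsets_s %||% numeric(0),
    session_duration_s = dur,
    condition = cfg$condition)

  truth <- structure(list(
    cells = bind_rows(cells),
    events = bind_rows(events),
    scenario = cfg), class = "ground_truth")

  structure(list(traces = traces, schedule = schedule, truth = truth),
            class = "ca_session")
}

drift_trace_values <- function(times, dur, amplitude, period_s, phase) {
  amplitude * sin(2 * pi * times / period_s + phase) +
    0.1 * amplitude * (2 * times / dur - 1)
}

#' True drift trace of a simulated cell
#'
#' Reconstructs the noiseless slow-drift component injected into a simulated
#' cell (sinusoid plus linear trend, on the \eqn{\Delta F/F_0} scale).
#'
#' @param truth The `truth` element of a [simulate_session()] result.
#' @param cell_id A cell id present in `truth$cells`.
#' @return Tibble `time_s`, `drift`.
#' @export
true_drift <- function(truth, cell_id) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- truth$scenario
  row <- truth$cells[as.character(truth$cells$cell_id) == as.character(cell_id), ]
  if (nrow(row) != 1) abort("unknown `cell_id`.", class = "bingetrace_parameter_error")
  dur <- cfg$baseline_duration_s + cfg$response_duration_s
  times <- frame_times(round(dur * cfg$frame_rate_hz), cfg$frame_rate_hz)
  tibble(time_s = times,
         drift = drift_trace_values(times, dur, cfg$drift_amplitude,
                                    cfg$drift_period_s, row$drift_phase))
}

#' Session event schedule
#'
#' Records when the food stimulus was introduced and when eating bouts began.
#'
#' @param stimulus_onset_s Stimulus introduction time (s from session start).
#' @param bout_onsets_s Strictly ascending bout onset times (s), all at or
#'   after `stimulus_onset_s`; may be empty.
#' @param session_duration_s Total session duration (s).
#' @param condition Free-text condition tag.
#' @return An `event_schedule` list.
#' @export
event_schedule <- function(stimulus_onset_s, bout_onsets_s = numeric(0),
                           session_duration_s, condition = "unspecified") {
  if (stimulus_onset_s < 0 || stimulus_onset_s >= session_duration_s) {
    abort("`stimulus_onset_s` must lie in [0, session_duration_s).",
          class = "bingetrace_parameter_error")
  }
  b <- as.numeric(bout_onsets_s)
  if (length(b)) {
    if (any(diff(b) <= 0)) {
      abort("`bout_onsets_s` must ascend strictly.", class = "bingetrace_parameter_error")
    }
    if (any(b < stimulus_onset_s)) {
      abort("bout onsets must not precede the stimulus onset.",
            class = "bingetrace_parameter_error")
    }
  }
  structure(list(stimulus_onset_s = stimulus_onset_s, bout_onsets_s = b,
                 session_duration_s = session_duration_s, condition = condition),
            class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("<event_schedule> '%s': %g s session, stimulus at %g s, %d bouts\n",
              x$condition, x$session_duration_s, x$stimulus_onset_s,
              length(x$bout_onsets_s)))
  invisible(x)
}

#' @export
print.ca_session <- function(x, ...) {
  n <- nlevels(x$traces$cell_id)
  cat(sprintf("<ca_session> %d cells x %d frames at %g fps\n",
              n, nrow(x$traces) / n, trace_frame_rate(x$traces)))
  print(x$schedule)
  invisible(x)
}
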