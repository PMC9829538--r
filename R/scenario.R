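#' Configure a synthetic imaging session
#'
#' Bundles every parameter of the synthetic GCaMP session generator
#' ([simulate_session()]). The defaults emulate the recording design the
#' pipeline targets: a 2-min pre-stimulus baseline followed by a 2-min
#' response period at 8 frames/s, a mixed population of upregulated,
#' downregulated and non-responsive cells, sparse spontaneous transients,
#' slow baseline drift and additive Gaussian sensor noise.
#'
#' @param n_cells Number of cells (default 57, a typical pooled group size).
#' @param frame_rate_hz Acquisition rate in frames per second (default 8).
#' @param baseline_duration_s Pre-stimulus baseline duration in seconds
#'   (default 120); the stimulus is introduced at its end.
#' @param response_duration_s Post-stimulus duration in seconds (default 120).
#' @param fractions Named numeric vector `c(up=, down=, non_response=)`,
#'   non-negative and summing to 1. Converted to integer cell counts by
#'   deterministic largest-remainder apportionment; labels are assigned to
#'   cell indices in order (all `up` cells first, then `down`, then
#'   `non_response`).
#' @param f0_mean,f0_sd Mean and s.d. (a.u.) of per-cell baseline fluorescence
#'   F0; draws are floored at 5% of `f0_mean` to keep F0 positive.
#' @param noise_sigma Additive Gaussian noise s.d. in a.u.; on the
#'   \eqn{\Delta F/F_0} scale a cell's noise s.d. is `noise_sigma / F0`.
#' @param transient_amplitude Transient peak height in multiples of the
#'   cell's \eqn{\Delta F/F_0} noise s.d. (default 8).
#' @param tau_rise_s,tau_decay_s Kernel time constants in seconds
#'   (GCaMP6f-like defaults 0.1 and 1.0); see [transient_kernel()].
#' @param background_rate_hz Poisson rate (Hz) of spontaneous transients
#'   during baseline, and post-stimulus for non-responsive cells.
#' @param up_rate_multiplier Post-stimulus rate factor for `up` cells.
#' @param down_step_sigma Size, in \eqn{\Delta F/F_0}-noise s.d. units, of the
#'   sustained negative step applied to `down` cells after the stimulus;
#'   their transient rate is additionally suppressed to zero post-stimulus.
#' @param drift_amplitude Slow-drift amplitude as a fraction of F0 (a
#'   sinusoid of period `drift_period_s` with random phase, plus a linear
#'   trend of amplitude `0.1 * drift_amplitude` across the session).
#' @param drift_period_s Drift sinusoid period in seconds.
#' @param bout_onsets_s Optional strictly ascending eating-bout onset times
#'   (s), all at or after the stimulus onset.
#' @param bout_locked_fraction Fraction of cells that additionally emit one
#'   transient within `bout_jitter_s` of every bout onset (assigned to the
#'   first `round(fraction * n_cells)` cell indices).
#' @param bout_jitter_s Half-width (s) of the uniform jitter of bout-locked
#'   transients around each bout onset.
#' @param condition Free-text session tag (e.g. `"ReHFD-1"`).
#' @param seed Integer seed. Each cell derives its own seed from it, so the
#'   same seed reproduces the session bit-for-bit and adding cells does not
#'   perturb existing ones.
#'
#' @return A `scenario_config` list.
#' @seealso [scenario_preset()] for ready-made study scenarios.
#' @export
scenario_config <- function(n_cells = 57,
                            frame_rate_hz = 8,
                            baseline_duration_s = 120,
                            response_duration_s = 120,
                            fractions = c(up = 0.333, down = 0.053, non_response = 0.614),
                            f0_mean = 100,
                            f0_sd = 10,
                            noise_sigma = 2,
                            transient_amplitude = 8,
                            tau_rise_s = 0.1,
                            tau_decay_s = 1,
                            background_rate_hz = 0.025,
                            up_rate_multiplier = 3,
                            down_step_sigma = 2,
                            drift_amplitude = 0.05,
                            drift_period_s = 120,
                            bout_onsets_s = NULL,
                            bout_locked_fraction = 0,
                            bout_jitter_s = 0.5,
                            condition = "ReHFD-1",
                            seed = 1L) {
  cfg <- list(
    n_cells = n_cells, frame_rate_hz = frame_rate_hz,
    baseline_duration_s = baseline_duration_s,
    response_duration_s = response_duration_s,
    fractions = fractions, f0_mean = f0_mean, f0_sd = f0_sd,
    noise_sigma = noise_sigma, transient_amplitude = transient_amplitude,
    tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
    background_rate_hz = background_rate_hz,
    up_rate_multiplier = up_rate_multiplier,
    down_step_sigma = down_step_sigma,
    drift_amplitude = drift_amplitude, drift_period_s = drift_period_s,
    bout_onsets_s = bout_onsets_s,
    bout_locked_fraction = bout_locked_fraction,
    bout_jitter_s = bout_jitter_s,
    condition = condition, seed = as.integer(seed)
  )
  # canonical storage types, so configs reloaded from JSON compare equal
  cfg$n_cells <- as.integer(cfg$n_cells)
  num <- setdiff(names(cfg), c("n_cells", "seed", "condition", "fractions",
                               "bout_onsets_s"))
  cfg[num] <- lapply(cfg[num], as.numeric)
  cfg$fractions <- stats::setNames(as.numeric(fractions), names(fractions))
  if (!is.null(cfg$bout_onsets_s)) cfg$bout_onsets_s <- as.numeric(cfg$bout_onsets_s)
  validate_scenario(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario <- function(cfg) {
  if (!is.numeric(cfg$n_cells) || cfg$n_cells < 1 || cfg$n_cells != round(cfg$n_cells)) {
    abort("`n_cells` must be a whole number >= 1.", class = "bingetrace_parameter_error")
  }
  for (nm in c("frame_rate_hz", "baseline_duration_s", "response_duration_s",
               "f0_mean", "tau_rise_s", "tau_decay_s",
               "drift_period_s", "bout_jitter_s")) {
    check_positive(cfg[[nm]], nm)
  }
  for (nm in c("noise_sigma", "f0_sd", "transient_amplitude", "background_rate_hz",
               "up_rate_multiplier", "down_step_sigma", "drift_amplitude",
               "bout_locked_fraction")) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || !is.finite(cfg[[nm]]) ||
        cfg[[nm]] < 0) {
      abort(sprintf("`%s` must be a single non-negative finite number.", nm),
            class = "bingetrace_parameter_error")
    }
  }
  if (cfg$tau_rise_s >= cfg$tau_decay_s) {
    abort("`tau_rise_s` must be smaller than `tau_decay_s`.",
          class = "bingetrace_parameter_error")
  }
  fr <- cfg$fractions
  if (is.null(names(fr)) || !setequal(names(fr), c("up", "down", "non_response"))) {
    abort("`fractions` must be named c(up=, down=, non_response=).",
          class = "bingetrace_parameter_error")
  }
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    abort("`fractions` must be non-negative and sum to 1 (within 1e-9).",
          class = "bingetrace_parameter_error")
  }
  if (cfg$bout_locked_fraction > 1) {
    abort("`bout_locked_fraction` must lie in [0, 1].",
          class = "bingetrace_parameter_error")
  }
  if (!is.null(cfg$bout_onsets_s)) {
    b <- cfg$bout_onsets_s
    dur <- cfg$baseline_duration_s + cfg$response_duration_s
    if (any(diff(b) <= 0)) {
      abort("`bout_onsets_s` must ascend strictly.", class = "bingetrace_parameter_error")
    }
    if (any(b < cfg$baseline_duration_s) || any(b >= dur)) {
      abort("`bout_onsets_s` must lie in [stimulus onset, session end).",
            class = "bingetrace_parameter_error")
    }
  }
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  dur <- x$baseline_duration_s + x$response_duration_s
  cat(sprintf(
    "<scenario_config> %d cells, %g fps, %g s session (stimulus at %g s), condition '%s'\n",
    x$n_cells, x$frame_rate_hz, dur, x$baseline_duration_s, x$condition))
  cat(sprintf("  fractions: up %.3f / down %.3f / non %.3f; amplitude %g sigma; rate %g Hz (x%g post, up cells)\n",
              x$fractions[["up"]], x$fractions[["down"]], x$fractions[["non_response"]],
              x$transient_amplitude, x$background_rate_hz, x$up_rate_multiplier))
  if (!is.null(x$bout_onsets_s)) {
    cat(sprintf("  bouts at %s s; bout-locked fraction %.3f (jitter +/-%g s)\n",
                paste(x$bout_onsets_s, collapse = ", "),
                x$bout_locked_fraction, x$bout_jitter_s))
  }
  invisible(x)
}

#' Ready-made study scenarios
#'
#' Returns a [scenario_config()] parameterised after one of the study
#' conditions the pipeline is validated against. The classification presets
#' (`"control-rehfd1"`, `"control-rehfd4"`, `"elt-rehfd1"`, `"elt-rehfd4"`)
#' set the configured up-cell fraction to the reported 33.3%, 12.1%, 39.5%
#' and 49.0% and use strong effects (post-stimulus rate multiplier 40, down
#' step \eqn{-3\sigma}, sparse 0.02 Hz background) so that every configured
#' label is recoverable by the \eqn{\pm\sigma} classifier — these are
#' recovery-check scenarios, not attempts to re-create the in-vivo raw data.
#' The bout presets (`"priming-bouts"`, `"rehfd1-bouts"`, `"rehfd4-bouts"`)
#' set the bout-locked cell fraction to the reported 13.9%, 41.9% and 27.9%
#' with five eating bouts starting 10 s after the stimulus and an almost
#' silent background (0.001 Hz) so bout-locking dominates chance coincidence.
#'
#' @param name Preset name (see Details).
#' @param ... Overrides forwarded to [scenario_config()] (e.g. `n_cells`,
#'   `seed`).
#' @return A `scenario_config`.
#' @export
scenario_preset <- function(name = c("control-rehfd1", "control-rehfd4",
                                     "elt-rehfd1", "elt-rehfd4",
                                     "priming-bouts", "rehfd1-bouts",
                                     "rehfd4-bouts"),
                            ...) {
  name <- match.arg(name)
  class_preset <- function(up, condition, ...) {
    down <- 0.053
    scenario_config(
      fractions = c(up = up, down = down, non_response = 1 - up - down),
      background_rate_hz = 0.02, up_rate_multiplier = 40,
      down_step_sigma = 3, condition = condition, ...)
  }
  bout_preset <- function(locked, condition, ...) {
    scenario_config(
      fractions = c(up = 0, down = 0, non_response = 1),
      background_rate_hz = 0.001,
      bout_onsets_s = c(130, 145, 160, 175, 190),
      bout_locked_fraction = locked, bout_jitter_s = 0.5,
      condition = condition, ...)
  }
  switch(name,
    "control-rehfd1" = class_preset(0.333, "control ReHFD-1", ...),
    "control-rehfd4" = class_preset(0.121, "control ReHFD-4", ...),
    "elt-rehfd1"     = class_preset(0.395, "ELT ReHFD-1", ...),
    "elt-rehfd4"     = class_preset(0.490, "ELT ReHFD-4", ...),
    "priming-bouts"  = bout_preset(0.139, "HFD-priming bouts", ...),
    "rehfd1-bouts"   = bout_preset(0.419, "ReHFD-1 bouts", ...),
    "rehfd4-bouts"   = bout_preset(0.279, "ReHFD-4 bouts", ...)
  )
}
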