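# Independent brute-force oracles and small trace builders used across tests.
# The oracles deliberately re-implement the rules as explicit loops, staying
# independent of the package's vectorised code paths.

# Long raw-trace tibble from a cells x frames matrix.
toy_traces <- function(mat, fs = 8) {
  n <- nrow(mat)
  nf <- ncol(mat)
  ids <- factor(sprintf("cell_%03d", seq_len(n)),
                levels = sprintf("cell_%03d", seq_len(n)))
  out <- tibble::tibble(
    cell_id = rep(ids, each = nf),
    time_s = rep((seq_len(nf) - 1) / fs, n),
    fluor = as.vector(t(mat)))
  attr(out, "frame_rate_hz") <- fs
  out
}

# A "detrended" tibble straight from residual vectors, bypassing the filters.
toy_detrended <- function(res_list, fs = 8) {
  if (!is.list(res_list)) res_list <- list(res_list)
  n <- length(res_list)
  ids <- factor(sprintf("cell_%03d", seq_len(n)),
                levels = sprintf("cell_%03d", seq_len(n)))
  out <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    x <- res_list[[i]]
    tibble::tibble(cell_id = ids[i], time_s = (seq_along(x) - 1) / fs,
                   dff = x, resid = x)
  }))
  attr(out, "frame_rate_hz") <- fs
  out
}

# Sliding median with mirror padding, as an explicit per-window loop.
brute_sliding_median <- function(x, w) {
  n <- length(x)
  h <- (w - 1) / 2
  xp <- c(x[(h + 1):2], x, x[(n - 1):(n - h)])
  vapply(seq_len(n), function(i) median(xp[i:(i + w - 1)]), numeric(1))
}

# Sample-by-sample re-implementation of the detection scan rule.
brute_detect <- function(x, times, threshold, min_interval_s) {
  ev <- numeric(0)
  last <- -Inf
  for (i in seq_along(x)) {
    if (x[i] > threshold && times[i] - last >= min_interval_s - 1e-9) {
      ev <- c(ev, times[i])
      last <- times[i]
    }
  }
  ev
}

# Exact chance that a train rigidly shifted by a uniform circular offset puts
# at least one event within +/-tol of any bout: measure of the union of the
# intervals (bout - tol - event, bout + tol - event) mod T, divided by T.
rigid_shift_chance <- function(events, bouts, tol, t_total) {
  if (!length(events)) return(0)
  lo <- as.vector(outer(bouts - tol, events, "-")) %% t_total
  width <- 2 * tol
  segs <- cbind(lo, lo + width)
  wrap <- segs[, 2] > t_total
  if (any(wrap)) {
    segs <- rbind(cbind(segs[wrap, 1], t_total),
                  cbind(0, segs[wrap, 2] - t_total),
                  segs[!wrap, , drop = FALSE])
  }
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  total <- 0
  cur_lo <- segs[1, 1]
  cur_hi <- segs[1, 2]
  for (r in seq_len(nrow(segs))[-1]) {
    if (segs[r, 1] <= cur_hi) {
      cur_hi <- max(cur_hi, segs[r, 2])
    } else {
      total <- total + (cur_hi - cur_lo)
      cur_lo <- segs[r, 1]
      cur_hi <- segs[r, 2]
    }
  }
  total <- total + (cur_hi - cur_lo)
  total / t_total
}

# Residual trace with alternating micro-noise (known MAD) plus square pulses.
pulse_trace <- function(n = 800, pulse_at_s = numeric(0), pulse_s = 0.5,
                        height = 1, fs = 8, base = 0.01) {
  x <- rep(c(base, -base), length.out = n)
  for (p in pulse_at_s) {
    i0 <- floor(p * fs) + 1
    i1 <- min(n, i0 + round(pulse_s * fs) - 1)
    x[i0:i1] <- height
  }
  x
}
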