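# Independent oracles used to check the fitting and estimation code paths.

# Brute-force grid-search least-squares single-exponential fit (amplitude
# profiled in closed form for each candidate tau). Independent of the
# Levenberg-Marquardt path in the package.
grid_fit_tau <- function(t_ms, y, tau_grid = seq(0.5, 80, by = 0.01)) {
  rss <- vapply(tau_grid, function(tau) {
    e <- exp(-t_ms / tau)
    A <- sum(y * e) / sum(e * e)
    sum((y - A * e)^2)
  }, numeric(1))
  tau_grid[which.min(rss)]
}

# Histogram-mode oracle for the holding current: plain mode of a fine
# histogram restricted to event-free samples (ground truth mask).
mode_oracle <- function(x) {
  h <- hist(x, breaks = 200, plot = FALSE)
  h$mids[which.max(h$counts)]
}

# Greedy matching of detected events to ground-truth events within a time
# tolerance; returns recall and precision.
match_events <- function(detected_onsets, true_times, tol_s = 0.003) {
  if (length(true_times) == 0L) {
    return(list(recall = NA_real_, precision = as.numeric(length(detected_onsets) == 0L)))
  }
  matched_true <- vapply(true_times, function(tt) {
    any(abs(detected_onsets - tt) <= tol_s)
  }, logical(1))
  matched_det <- vapply(detected_onsets, function(dt) {
    any(abs(true_times - dt) <= tol_s)
  }, logical(1))
  list(recall = mean(matched_true), precision = mean(matched_det))
}

# A voltage-clamp parameter set with events planted at known times: rates are
# zero and the ledger is bypassed by injecting events through a tiny wrapper
# around the kernel arithmetic.
plant_events_trace <- function(times, amplitude, tau_decay, duration,
                               noise_sd = 0, tau_rise = 0.7,
                               sample_rate = 20000, baseline = 0, seed = 1L) {
  n <- round(duration * sample_rate)
  values <- rep(baseline, n)
  if (noise_sd > 0) {
    values <- values + withr::with_seed(seed, rnorm(n, 0, noise_sd))
  }
  amplitude <- rep_len(amplitude, length(times))
  tau_decay <- rep_len(tau_decay, length(times))
  for (i in seq_along(times)) {
    i0 <- floor(times[i] * sample_rate) + 1L
    len <- min(n - i0 + 1L, ceiling(8 * tau_decay[i] / 1000 * sample_rate))
    t_ms <- (seq_len(len) - 1L) / sample_rate * 1000
    kern <- spinaltone:::psc_kernel(t_ms, tau_rise, tau_decay[i])
    values[i0:(i0 + len - 1L)] <- values[i0:(i0 + len - 1L)] + amplitude[i] * kern
  }
  new_trace(values, sample_rate = sample_rate, units = "pA")
}
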