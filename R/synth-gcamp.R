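#' Generate a GCaMP fluorescence trace from spike times
#'
#' Fluorescence is a linear superposition of per-spike indicator kernels on a
#' baseline: `F(t) = f0 * (1 + sum_i k(t - t_i) + noise)`, where `k` is a
#' peak-normalized difference of exponentials scaled to `unit_amplitude`
#' (fractional dF/F per spike). Defaults emulate GCaMP6f (50 ms rise, 600 ms
#' decay) imaged at 2 Hz; the unit amplitude is tuned so a ~19-spike, 500 ms
#' burst peaks near a 17.5% dF/F transient.
#'
#' @param spike_times Spike times, seconds (all within `duration`).
#' @param duration Recording length, seconds.
#' @param sample_rate Frame rate, Hz (default 2).
#' @param rise_ms,decay_ms Kernel time constants, ms.
#' @param unit_amplitude Fractional dF/F contributed by one spike at its
#'   kernel peak (0.013 = 1.3%).
#' @param noise_sd Fractional noise standard deviation.
#' @param f0 Baseline fluorescence, a.u. (must be positive).
#' @param metadata Trace metadata (e.g. `drug_epochs`).
#' @param seed Integer seed for the noise.
#' @return A fluorescence trace tibble, a.u.
#' @export
gen_gcamp_trace <- function(spike_times, duration, sample_rate = 2,
                            rise_ms = 50, decay_ms = 600,
                            unit_amplitude = 0.013, noise_sd = 0,
                            f0 = 100, metadata = list(), seed = 1L) {
  if (f0 <= 0) stop("baseline fluorescence f0 must be positive", call. = FALSE)
  if (length(spike_times) && (min(spike_times) < 0 || max(spike_times) > duration)) {
    stop("spike times must lie within the recording", call. = FALSE)
  }
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  dff <- numeric(n)
  for (ts in spike_times) {
    dff <- dff + unit_amplitude * psc_kernel((t - ts) * 1000, rise_ms, decay_ms)
  }
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(n, 0, noise_sd))
  } else numeric(n)
  new_trace(f0 * (1 + dff + noise), sample_rate = sample_rate, units = "au",
            metadata = metadata)
}

#' Simulate the paired current-injection / fluorescence calibration
#'
#' Runs the 8-step staircase (10-80 pA, 10 pA increments, 500 ms pulses,
#' 1000 ms intervals) on a model cell, converts the spikes of each step into a
#' GCaMP trace, and tabulates mean spike count and mean peak dF/F per step
#' across cells — the table [calibrate_threshold()] consumes.
#'
#' @param cell A [cell_model()] (default [preset_calibration_cell()]).
#' @param n_cells Cells in the calibration cohort.
#' @param amplitudes_pa Step amplitudes, pA.
#' @param noise_sd Fractional fluorescence noise per cell.
#' @param seed Integer seed.
#' @inheritParams gen_gcamp_trace
#' @return A calibration tibble: `current_pa`, `mean_spikes`, `sem_spikes`,
#'   `mean_dff`, `sem_dff` (dF/F in %).
#' @export
simulate_calibration <- function(cell = preset_calibration_cell(), n_cells = 10,
                                 amplitudes_pa = seq(10, 80, by = 10),
                                 noise_sd = 0.002, unit_amplitude = 0.013,
                                 rise_ms = 50, decay_ms = 600, seed = 1L) {
  pulse_s <- 0.5; gap_s <- 1
  per_cell <- purrr::map(seq_len(n_cells), function(ci) {
    # small cell-to-cell leak variability so SEMs are meaningful
    g_jit <- withr::with_seed(seed + 1000L * ci, stats::rnorm(1, 1, 0.05))
    c2 <- cell; c2$gL <- cell$gL * max(0.7, g_jit)
    purrr::map_dfr(seq_along(amplitudes_pa), function(si) {
      amp <- amplitudes_pa[si]
      sim <- gen_cc_response(c2, step_protocol(amp, pulse_s * 1000, 0))
      spikes <- sim$truth$spikes$time
      dur <- pulse_s + gap_s
      fl <- gen_gcamp_trace(spikes, duration = dur, noise_sd = noise_sd,
                            unit_amplitude = unit_amplitude,
                            rise_ms = rise_ms, decay_ms = decay_ms,
                            seed = seed + 1000L * ci + si)
      # dF/F against the step's own pre-response baseline frame
      dff_pct <- 100 * (fl$value / fl$value[1] - 1)
      tibble::tibble(cell = ci, current_pa = amp,
                     n_spikes = length(spikes), peak_dff = max(dff_pct, 0))
    })
  })
  dplyr::bind_rows(per_cell) |>
    dplyr::group_by(.data$current_pa) |>
    dplyr::summarise(
      mean_spikes = mean(.data$n_spikes),
      sem_spikes = stats::sd(.data$n_spikes) / sqrt(dplyr::n()),
      mean_dff = mean(.data$peak_dff),
      sem_dff = stats::sd(.data$peak_dff) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}
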