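#' Conductance-based leaky integrate-and-fire cell
#'
#' The membrane follows `C dV/dt = -gL (V - EL) - g_tonic (V - E_tonic) + I(t)`
#' with a hard threshold/reset spike mechanism. The tonic chloride conductance
#' `g_tonic` is switchable (see [apply_drug()]): removing it depolarizes the
#' resting potential, raises the input resistance and lowers the rheobase.
#'
#' Closed forms used throughout the tests and the preset tuning:
#' resting potential `(gL*EL + g_tonic*E_tonic) / (gL + g_tonic)`, input
#' resistance `1/(gL + g_tonic)` (GOhm when conductances are in nS), and
#' steady-state rheobase `(V_th - V_rest) * (gL + g_tonic)`.
#'
#' @param gL Leak conductance, nS.
#' @param EL Leak reversal, mV.
#' @param g_tonic Tonic inhibitory conductance, nS.
#' @param E_tonic Tonic (chloride) reversal, mV.
#' @param C Capacitance, pF.
#' @param V_th Spike threshold, mV.
#' @param V_reset Post-spike reset potential, mV.
#' @param refractory Absolute refractory period, ms.
#' @param tonic_glycine_share Fraction of `g_tonic` that is glycinergic (used
#'   by [apply_drug()] to remove one share at a time).
#' @return A list of class `cell_model`.
#' @export
cell_model <- function(gL, EL, g_tonic = 0, E_tonic = -70, C = 15,
                       V_th = -20, V_reset = -50, refractory = 2,
                       tonic_glycine_share = 0.5) {
  if (gL <= 0) stop("gL must be positive", call. = FALSE)
  if (C <= 0) stop("C must be positive", call. = FALSE)
  if (g_tonic < 0) stop("g_tonic must be non-negative", call. = FALSE)
  if (V_th <= EL) stop("V_th must exceed EL", call. = FALSE)
  structure(
    list(gL = gL, EL = EL, g_tonic = g_tonic, E_tonic = E_tonic, C = C,
         V_th = V_th, V_reset = V_reset, refractory = refractory,
         tonic_glycine_share = tonic_glycine_share),
    class = "cell_model"
  )
}

#' @rdname cell_model
#' @param cell A `cell_model`.
#' @export
lif_resting_potential <- function(cell) {
  with(cell, (gL * EL + g_tonic * E_tonic) / (gL + g_tonic))
}

#' @rdname cell_model
#' @export
lif_input_resistance <- function(cell) {
  1000 / (cell$gL + cell$g_tonic)  # MOhm from nS
}

#' @rdname cell_model
#' @export
lif_rheobase <- function(cell) {
  (cell$V_th - lif_resting_potential(cell)) * (cell$gL + cell$g_tonic)
}

#' @rdname cell_model
#' @export
lif_tonic_current_at_threshold <- function(cell) {
  cell$g_tonic * (cell$V_th - cell$E_tonic)
}

#' Simulate a current-clamp protocol
#'
#' Integrates the LIF equation with fixed-step exponential Euler at the trace
#' sampling rate (exact for piecewise-constant input, hence stable at 20 kHz
#' with tens-of-ms membrane time constants). Each protocol row delivers a
#' rectangular current step followed by a recovery interval; the run starts at
#' the resting potential.
#'
#' @param cell A [cell_model()].
#' @param protocol Data frame with columns `amplitude_pa`, `duration_ms` and
#'   `interval_ms` (recovery gap after the step).
#' @param sample_rate Integration/sampling rate, Hz.
#' @return A list with `trace` (membrane potential tibble, mV; metadata carries
#'   the injected-current step table) and `truth` with `spikes` (tibble of
#'   `step`, `time`), the per-step spike counts, and the cell's closed-form
#'   resting potential, input resistance, rheobase and tonic current at
#'   threshold.
#' @export
gen_cc_response <- function(cell, protocol, sample_rate = 20000) {
  stopifnot(inherits(cell, "cell_model"))
  if (!is.data.frame(protocol) || nrow(protocol) == 0L ||
      !all(c("amplitude_pa", "duration_ms") %in% names(protocol))) {
    stop("protocol must be a non-empty data frame with amplitude_pa, duration_ms",
         call. = FALSE)
  }
  if (is.null(protocol$interval_ms)) protocol$interval_ms <- 0
  dt_ms <- 1000 / sample_rate
  g_total <- cell$gL + cell$g_tonic
  tau_ms <- cell$C / g_total  # pF / nS = ms
  if (tau_ms < 2 * dt_ms) {
    stop("integration step too coarse for the membrane time constant", call. = FALSE)
  }
  decay <- exp(-dt_ms / tau_ms)
  v_rest <- lif_resting_potential(cell)

  step_samples <- round(protocol$duration_ms / dt_ms)
  gap_samples <- round(protocol$interval_ms / dt_ms)
  n_total <- sum(step_samples + gap_samples)
  current <- numeric(n_total)
  step_id <- integer(n_total)
  pos <- 0L
  for (s in seq_len(nrow(protocol))) {
    if (step_samples[s] > 0) {
      idx <- pos + seq_len(step_samples[s])
      current[idx] <- protocol$amplitude_pa[s]
      step_id[idx] <- s
    }
    pos <- pos + step_samples[s] + gap_samples[s]
  }

  v <- numeric(n_total)
  V <- v_rest
  refr_left <- 0
  spike_t <- numeric(0)
  spike_step <- integer(0)
  v_inf_base <- (cell$gL * cell$EL + cell$g_tonic * cell$E_tonic) / g_total
  for (i in seq_len(n_total)) {
    if (refr_left > 0) {
      refr_left <- refr_left - dt_ms
      V <- cell$V_reset
    } else {
      v_inf <- v_inf_base + current[i] / g_total
      V <- v_inf + (V - v_inf) * decay
      if (V >= cell$V_th) {
        spike_t <- c(spike_t, i * dt_ms / 1000)
        spike_step <- c(spike_step, step_id[i])
        v[i] <- 20  # drawn action-potential peak, so traces show the spike
        V <- cell$V_reset
        refr_left <- cell$refractory
        next
      }
    }
    v[i] <- V
  }

  trace <- new_trace(
    v, sample_rate = sample_rate, units = "mV",
    metadata = list(protocol = protocol)
  )
  spikes <- tibble::tibble(step = spike_step, time = spike_t)
  counts <- tibble::tibble(
    step = seq_len(nrow(protocol)),
    amplitude_pa = protocol$amplitude_pa,
    n_spikes = purrr::map_int(seq_len(nrow(protocol)), ~ sum(spike_step == .x))
  )
  list(
    trace = trace,
    truth = list(
      spikes = spikes,
      spike_counts = counts,
      v_rest = v_rest,
      input_resistance_mohm = lif_input_resistance(cell),
      rheobase_pa = lif_rheobase(cell),
      tonic_current_at_threshold_pa = lif_tonic_current_at_threshold(cell),
      cell = cell
    )
  )
}

#' Step-protocol constructor
#'
#' Convenience builder for ascending current-step protocols, e.g. the
#' viability ramp (0 to 150 pA in 10 pA steps, 500 ms pulses) or the 8-step
#' calibration staircase (10-80 pA, 500 ms pulses, 1000 ms intervals).
#'
#' @param amplitudes_pa Step amplitudes, pA.
#' @param duration_ms Pulse duration, ms.
#' @param interval_ms Recovery interval after each pulse, ms.
#' @return A tibble protocol accepted by [gen_cc_response()].
#' @export
step_protocol <- function(amplitudes_pa, duration_ms = 500, interval_ms = 500) {
  tibble::tibble(
    amplitude_pa = amplitudes_pa,
    duration_ms = duration_ms,
    interval_ms = interval_ms
  )
}
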