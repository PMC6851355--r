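#' Spike times from a current-clamp voltage trace
#'
#' Upward crossings of a fixed criterion voltage (default -20 mV), which is
#' unambiguous for integrate-and-fire traces and configurable for recorded
#' data.
#'
#' @param trace Voltage trace, mV.
#' @param criterion_mv Crossing criterion, mV.
#' @return Spike times, seconds.
#' @export
detect_spikes <- function(trace, criterion_mv = -20) {
  assert_trace(trace)
  v <- trace$value
  up <- which(v[-1] >= criterion_mv & v[-length(v)] < criterion_mv)
  trace$time[up + 1L]
}

#' Rheobase by ascending current steps
#'
#' Delivers 500 ms pulses of increasing amplitude (the protocol used on the
#' recorded cells: 1 pA increments) and returns the smallest amplitude that
#' elicits at least one spike. The search ascends linearly rather than
#' bisecting, mirroring the acquisition protocol.
#'
#' @param cell A [cell_model()].
#' @param increment_pa Step increment, pA.
#' @param pulse_ms Pulse duration, ms.
#' @param max_pa Search ceiling, pA.
#' @param sample_rate Integration rate, Hz.
#' @return Rheobase in pA, or `NA` with attribute `not_reached = TRUE` if no
#'   spike occurs up to `max_pa`.
#' @examples
#' find_rheobase(preset_cell())
#' @export
find_rheobase <- function(cell, increment_pa = 1, pulse_ms = 500,
                          max_pa = 150, sample_rate = 20000) {
  stopifnot(inherits(cell, "cell_model"))
  # start the linear search just below the analytic floor to keep runtime
  # proportional to the protocol, not to the ceiling
  spikes_at <- function(amp) {
    sim <- gen_cc_response(cell, step_protocol(amp, pulse_ms, 0), sample_rate)
    nrow(sim$truth$spikes) >= 1L
  }
  analytic <- lif_rheobase(cell)
  start <- min(max_pa, max(0, floor(analytic - 3 * increment_pa)))
  while (start > 0 && spikes_at(start)) {
    start <- max(0, start - 10 * increment_pa)
  }
  for (amp in seq(start, max_pa, by = increment_pa)) {
    if (spikes_at(amp)) return(amp)
  }
  structure(NA_real_, not_reached = TRUE)
}

#' Input resistance from a subthreshold step response
#'
#' Steady-state voltage deflection divided by the injected current. The
#' steady state is the mean over the last 20% of the pulse (the pulse is long
#' relative to the membrane time constant, so the plateau criterion is
#' checked: plateau drift must be small against the deflection).
#'
#' @param response Voltage trace from a single-step protocol, mV (metadata
#'   must carry the protocol, as produced by [gen_cc_response()]).
#' @param step_pa Injected current, pA (non-zero, subthreshold).
#' @param spike_criterion_mv Spikes in the response raise an error.
#' @return Input resistance, MOhm.
#' @export
measure_input_resistance <- function(response, step_pa, spike_criterion_mv = -20) {
  assert_trace(response)
  if (step_pa == 0) stop("step amplitude must be non-zero", call. = FALSE)
  if (length(detect_spikes(response, spike_criterion_mv)) > 0L) {
    stop("step evoked spikes; use a subthreshold amplitude", call. = FALSE)
  }
  md <- trace_metadata(response)
  proto <- md$protocol
  if (is.null(proto)) stop("response metadata lacks the protocol", call. = FALSE)
  pulse_s <- proto$duration_ms[1] / 1000
  baseline <- response$value[1]
  idx <- epoch_index(response, c(0.8 * pulse_s, pulse_s))
  plateau <- response$value[idx]
  dv <- mean(plateau) - baseline
  drift <- abs(plateau[length(plateau)] - plateau[1])
  if (abs(dv) > 0 && drift > 0.05 * abs(dv)) {
    warning("plateau not reached; lengthen the pulse", call. = FALSE)
  }
  1000 * dv / step_pa  # mV/pA = GOhm; report MOhm
}

#' Resting membrane potential over a zero-current epoch
#'
#' @param trace Voltage trace, mV.
#' @param epoch `(start_s, end_s)`; default is the whole trace.
#' @param spike_criterion_mv Spikes inside the epoch raise an error.
#' @return Mean voltage, mV.
#' @export
measure_resting_potential <- function(trace, epoch = NULL, spike_criterion_mv = -20) {
  assert_trace(trace)
  if (is.null(epoch)) epoch <- c(trace$time[1], trace$time[nrow(trace)] + 1e-9)
  idx <- epoch_index(trace, epoch)
  spikes <- detect_spikes(trace, spike_criterion_mv)
  if (any(spikes >= epoch[1] & spikes < epoch[2])) {
    stop("epoch contains spikes; resting potential undefined", call. = FALSE)
  }
  mean(trace$value[idx])
}

#' Compare two measurement groups
#'
#' Two-tailed Student's t-test (the test used for the electrophysiological
#' means) or Mann-Whitney U (used for the dF/F cohorts), with group means and
#' standard errors.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param test `"t_two_tailed"` or `"mann_whitney"`.
#' @return A tibble of class `group_comparison`: means, SEMs, `statistic`,
#'   `p_value`, `test`, `n_a`, `n_b`.
#' @examples
#' compare_groups(c(39, 41, 40), c(7, 8, 7.5))
#' @export
compare_groups <- function(a, b, test = c("t_two_tailed", "mann_whitney")) {
  test <- match.arg(test)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  ht <- if (test == "t_two_tailed") {
    stats::t.test(a, b, alternative = "two.sided", var.equal = FALSE)
  } else {
    stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE, correct = TRUE)
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  out <- tibble::tibble(
    mean_a = mean(a), mean_b = mean(b),
    sem_a = sem(a), sem_b = sem(b),
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    test = test,
    n_a = length(a), n_b = length(b)
  )
  class(out) <- c("group_comparison", class(out))
  out
}

#' Excitability measures for a model cell under a condition
#'
#' Convenience wrapper returning rheobase, input resistance and resting
#' potential of a cell, measured from simulated protocols (not from the
#' closed forms).
#'
#' @param cell A [cell_model()].
#' @param condition Label stored alongside the measures.
#' @param probe_step_pa Subthreshold step for the input-resistance protocol,
#'   pA (negative steps cannot spike).
#' @param sample_rate Integration rate, Hz.
#' @return A one-row tibble: `condition`, `rheobase_pa`,
#'   `input_resistance_mohm`, `resting_potential_mv`.
#' @export
measure_excitability <- function(cell, condition = "control", probe_step_pa = -5,
                                 sample_rate = 20000) {
  rheo <- find_rheobase(cell, sample_rate = sample_rate)
  sub <- gen_cc_response(cell, step_protocol(probe_step_pa, 500, 0), sample_rate)
  rin <- measure_input_resistance(sub$trace, probe_step_pa)
  rest <- gen_cc_response(cell, step_protocol(0, 200, 0), sample_rate)
  vm <- measure_resting_potential(rest$trace)
  tibble::tibble(
    condition = condition,
    rheobase_pa = as.numeric(rheo),
    input_resistance_mohm = rin,
    resting_potential_mv = vm
  )
}
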