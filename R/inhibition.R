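#' Decay-kinetics class boundaries
#'
#' IPSCs are classified by their fitted decay constant: fast glycinergic
#' events below the intermediate band, slow GABAergic events above it, and
#' glycine/GABA co-release events inside the closed interval
#' `[mixed_low, mixed_high]` (defaults 16.8-35.7 ms).
#'
#' @param mixed_low,mixed_high Band edges, ms.
#' @return A list of class `class_boundaries`.
#' @export
class_boundaries <- function(mixed_low = 16.8, mixed_high = 35.7) {
  if (!(0 < mixed_low && mixed_low < mixed_high)) {
    stop("need 0 < mixed_low < mixed_high", call. = FALSE)
  }
  structure(list(mixed_low = mixed_low, mixed_high = mixed_high),
            class = "class_boundaries")
}

#' Classify events by decay time constant
#'
#' @param tau_decay Fitted decay constants, ms (vectorized). `NA` stays
#'   unclassified.
#' @param boundaries A [class_boundaries()].
#' @return Character vector: `"glycinergic"`, `"mixed"`, `"gabaergic"` or
#'   `"unclassified"`.
#' @examples
#' classify_event_class(c(6.2, 16.8, 42))
#' @export
classify_event_class <- function(tau_decay, boundaries = class_boundaries()) {
  if (any(tau_decay <= 0, na.rm = TRUE)) {
    stop("decay constants must be positive", call. = FALSE)
  }
  dplyr::case_when(
    is.na(tau_decay) ~ "unclassified",
    tau_decay < boundaries$mixed_low ~ "glycinergic",
    tau_decay <= boundaries$mixed_high ~ "mixed",
    TRUE ~ "gabaergic"
  )
}

#' @rdname classify_event_class
#' @param events Event tibble with fitted `tau_decay`.
#' @return `classify_events()` returns the tibble with `class` filled in.
#' @export
classify_events <- function(events, boundaries = class_boundaries()) {
  events$class <- classify_event_class(events$tau_decay, boundaries)
  events
}

#' Kinetic mixture proportions
#'
#' Fraction of classified events in each decay-kinetics class. Unclassified
#' events (failed fits) are excluded from the denominator.
#'
#' @param events Event tibble with a `class` column.
#' @return A tibble with columns `class`, `n`, `fraction`; fractions sum to 1
#'   over the three classes.
#' @export
mixture_proportions <- function(events) {
  cls <- events$class[events$class %in% c("glycinergic", "mixed", "gabaergic")]
  if (length(cls) == 0L) stop("no classified events", call. = FALSE)
  lv <- c("glycinergic", "gabaergic", "mixed")
  n <- vapply(lv, function(l) sum(cls == l), integer(1))
  tibble::tibble(class = lv, n = unname(n), fraction = unname(n) / length(cls))
}

#' Holding current from the all-points histogram
#'
#' Builds the all-points histogram of a trace epoch (Freedman-Diaconis bins),
#' locates its dominant peak and fits a Gaussian to the bins around it; the
#' fitted mean is the holding current. Because synaptic events deflect the
#' trace to one side only, the histogram mode is far more robust to event
#' contamination than the epoch mean.
#'
#' @param trace Current trace, pA.
#' @param epoch `(start_s, end_s)`, at least 5 s.
#' @param min_peak_mass If the fraction of samples within the fitted peak
#'   region falls below this, the estimate is flagged (attribute `flagged`).
#' @return Holding current, pA (scalar, with attribute `flagged`).
#' @export
estimate_holding_current <- function(trace, epoch = NULL, min_peak_mass = 0.25) {
  assert_trace(trace)
  if (is.null(epoch)) epoch <- range(trace$time) + c(0, 1 / trace_sample_rate(trace))
  if (diff(epoch) < 5) stop("holding-current epoch must be at least 5 s", call. = FALSE)
  x <- trace$value[epoch_index(trace, epoch)]
  if (length(x) < 100L) stop("epoch too short for an all-points histogram", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(structure(x[1], flagged = FALSE))
  }
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  mode_i <- which.max(counts)
  # contiguous bins around the mode above half its height
  lo <- mode_i
  while (lo > 1L && counts[lo - 1L] >= counts[mode_i] / 2) lo <- lo - 1L
  hi <- mode_i
  while (hi < length(counts) && counts[hi + 1L] >= counts[mode_i] / 2) hi <- hi + 1L
  lo <- max(1L, lo - 2L); hi <- min(length(counts), hi + 2L)
  sel <- lo:hi
  df <- data.frame(m = mids[sel], c = counts[sel])
  sd0 <- max(diff(mids[c(lo, hi)]) / 2.355, diff(mids[1:2]))
  fit <- tryCatch(
    stats::nls(c ~ k * exp(-(m - mu)^2 / (2 * s^2)), data = df,
               start = list(k = counts[mode_i], mu = mids[mode_i], s = sd0),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL
  )
  mu <- if (is.null(fit)) mids[mode_i] else stats::coef(fit)[["mu"]]
  peak_mass <- sum(counts[sel]) / length(x)
  structure(mu, flagged = peak_mass < min_peak_mass)
}

#' Tonic current from a holding-current shift
#'
#' The tonic current revealed by an antagonist is the change in holding
#' current between a pre-drug and a post-drug epoch: holding(post) minus
#' holding(pre), signed. At a 0 mV hold, blocking a tonic chloride conductance
#' removes outward current, so the shift is negative and its magnitude is the
#' tonic current the paper's figures report.
#'
#' @param trace Current trace spanning both epochs, pA.
#' @param epoch_pre,epoch_post Non-overlapping `(start_s, end_s)` epochs.
#' @return A tibble with `shift_pa` (signed) and `tonic_pa` (magnitude).
#' @export
measure_tonic_shift <- function(trace, epoch_pre, epoch_post) {
  if (max(epoch_pre[1], epoch_post[1]) < min(epoch_pre[2], epoch_post[2])) {
    stop("epochs must not overlap", call. = FALSE)
  }
  pre <- estimate_holding_current(trace, epoch_pre)
  post <- estimate_holding_current(trace, epoch_post)
  shift <- as.numeric(post) - as.numeric(pre)
  tibble::tibble(
    holding_pre_pa = as.numeric(pre),
    holding_post_pa = as.numeric(post),
    shift_pa = shift,
    tonic_pa = abs(shift)
  )
}

#' Fractional blockade of event frequency
#'
#' @param freq_pre,freq_post Event frequencies before/after the drug, Hz.
#' @return `(freq_pre - freq_post) / freq_pre`.
#' @export
blockade_fraction <- function(freq_pre, freq_post) {
  if (any(freq_pre <= 0)) stop("pre-drug frequency must be positive", call. = FALSE)
  (freq_pre - freq_post) / freq_pre
}

#' End-to-end inhibition profile of a synthetic IPSC experiment
#'
#' Runs the full phasic/tonic decomposition the way the recordings were
#' analyzed: detect and fit sIPSCs in a control recording, classify the
#' kinetic mixture, then apply strychnine and strychnine+bicuculline in
#' sequence and measure the frequency blockade and the tonic holding-current
#' shift each step reveals.
#'
#' @param params Control-condition [vc_params()] (e.g. [preset_vc_ipsc()]).
#' @param boundaries [class_boundaries()].
#' @param threshold_k,min_separation_ms Detection settings.
#' @return A list of class `inhibition_profile`: `mixture` (tibble),
#'   `fractions` (named kinetic fractions), `tonic_glycine_pa`,
#'   `tonic_gaba_pa`, `strychnine_block_fraction`,
#'   `bicuculline_block_fraction`, `frequency_hz`, and the per-stage event
#'   tibbles.
#' @export
inhibition_profile <- function(params, boundaries = class_boundaries(),
                               threshold_k = 4, min_separation_ms = 5) {
  stopifnot(inherits(params, "vc_params"))
  run <- function(p) {
    sim <- gen_vc_trace(p)
    ev <- detect_events(sim$trace, "outward", threshold_k, min_separation_ms)
    ev <- fit_event_decay(sim$trace, ev)
    ev <- classify_events(ev, boundaries)
    list(sim = sim, events = ev,
         freq = event_frequency(ev, c(0, p$duration)),
         hold = as.numeric(estimate_holding_current(sim$trace)))
  }
  p_str <- apply_drug(params, "strychnine")
  p_str$seed <- params$seed + 1L
  p_both <- apply_drug(p_str, "bicuculline")
  p_both$seed <- params$seed + 2L

  ctrl <- run(params)
  str <- run(p_str)
  both <- run(p_both)

  mix <- mixture_proportions(ctrl$events)
  fr <- stats::setNames(mix$fraction, mix$class)
  structure(
    list(
      mixture = mix,
      fractions = fr,
      tonic_glycine_pa = abs(str$hold - ctrl$hold),
      tonic_gaba_pa = abs(both$hold - str$hold),
      strychnine_block_fraction = blockade_fraction(ctrl$freq, str$freq),
      bicuculline_block_fraction = blockade_fraction(str$freq, both$freq),
      frequency_hz = c(control = ctrl$freq, strychnine = str$freq,
                       strychnine_bicuculline = both$freq),
      events = list(control = ctrl$events, strychnine = str$events,
                    strychnine_bicuculline = both$events)
    ),
    class = "inhibition_profile"
  )
}
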