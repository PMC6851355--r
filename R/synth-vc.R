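#' Parameters for synthetic voltage-clamp recordings
#'
#' Describes a voltage-clamp recording as a Poisson mixture of synaptic event
#' classes riding on a tonic chloride conductance plus Gaussian noise. Event
#' classes are `ampa` (glutamatergic, reversal 0 mV), `glycine`, `gaba` and
#' `mixed` (glycine/GABA co-release; reversal of all three is
#' `chloride_reversal`). Decay constants are drawn per event from truncated
#' normal distributions; the glycinergic default is 6.2 +/- 2.2 ms and the
#' GABAergic default 42 +/- 6 ms. Mixed events are the sum of a glycine-kernel
#' and a gaba-kernel component.
#'
#' Holding current bookkeeping: the tonic conductance contributes
#' `g * (V_hold - E_tonic)` pA to the trace (nS times mV gives pA), so at a
#' 0 mV hold with a -70 mV reversal the default glycine/GABA shares carry
#' 10.25 and 22.5 pA of outward current.
#'
#' @param duration Recording length, seconds.
#' @param sample_rate Sampling rate, Hz (default 20000).
#' @param hold_voltage Holding potential, mV (-70 for EPSC runs, 0 for IPSC
#'   runs).
#' @param event_rate Named numeric vector of per-class Poisson rates, Hz.
#' @param amp_mean,amp_sd Named vectors: per-class amplitude magnitude
#'   distribution, pA.
#' @param tau_rise Kernel rise time constant, ms.
#' @param tau_decay_mean,tau_decay_sd Named vectors: per-class decay constant
#'   distribution, ms (`mixed` entries are ignored; mixed events use the
#'   glycine and gaba distributions).
#' @param mixed_weights Length-2 weights of the glycine and gaba components of
#'   a mixed event.
#' @param tonic_glycine_pa,tonic_gaba_pa Tonic current carried by each share at
#'   a 0 mV hold with the chloride reversal below, pA. Internally converted to
#'   conductances.
#' @param chloride_reversal Reversal potential of glycine/GABA currents, mV.
#' @param baseline_current Electrode/leak offset, pA.
#' @param noise_sd Gaussian noise standard deviation, pA.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A list of class `vc_params`.
#' @export
vc_params <- function(duration = 60,
                      sample_rate = 20000,
                      hold_voltage = 0,
                      event_rate = c(ampa = 0, glycine = 0, gaba = 0, mixed = 0),
                      amp_mean = c(ampa = 25, glycine = 30, gaba = 30, mixed = 30),
                      amp_sd = c(ampa = 8, glycine = 10, gaba = 10, mixed = 10),
                      tau_rise = 0.7,
                      tau_decay_mean = c(ampa = 3, glycine = 6.2, gaba = 42, mixed = NA),
                      tau_decay_sd = c(ampa = 1, glycine = 2.2, gaba = 6, mixed = NA),
                      mixed_weights = c(0.5, 0.5),
                      tonic_glycine_pa = 0,
                      tonic_gaba_pa = 0,
                      chloride_reversal = -70,
                      baseline_current = 0,
                      noise_sd = 2,
                      seed = 1L) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (sample_rate <= 0) stop("sample_rate must be positive", call. = FALSE)
  if (any(event_rate < 0)) stop("event rates must be non-negative", call. = FALSE)
  if (any(amp_sd < 0, na.rm = TRUE) || any(tau_decay_sd < 0, na.rm = TRUE)) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (tau_rise <= 0 || any(tau_decay_mean <= 0, na.rm = TRUE)) {
    stop("time constants must be positive", call. = FALSE)
  }
  if (tonic_glycine_pa < 0 || tonic_gaba_pa < 0) {
    stop("tonic shares are magnitudes at a 0 mV hold and must be >= 0", call. = FALSE)
  }
  classes <- c("ampa", "glycine", "gaba", "mixed")
  for (v in c("event_rate", "amp_mean", "amp_sd", "tau_decay_mean", "tau_decay_sd")) {
    x <- get(v)
    if (!all(classes %in% names(x))) stop(v, " must name all classes", call. = FALSE)
  }
  structure(
    list(
      duration = duration, sample_rate = sample_rate, hold_voltage = hold_voltage,
      event_rate = event_rate[classes], amp_mean = amp_mean[classes],
      amp_sd = amp_sd[classes], tau_rise = tau_rise,
      tau_decay_mean = tau_decay_mean[classes], tau_decay_sd = tau_decay_sd[classes],
      mixed_weights = mixed_weights / sum(mixed_weights),
      tonic_glycine_pa = tonic_glycine_pa, tonic_gaba_pa = tonic_gaba_pa,
      chloride_reversal = chloride_reversal, baseline_current = baseline_current,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "vc_params"
  )
}

class_reversal <- function(class, chloride_reversal) {
  ifelse(class == "ampa", 0, chloride_reversal)
}

# Difference-of-exponentials kernel normalized so its peak equals 1.
# Peak time of exp(-t/td) - exp(-t/tr) is td*tr/(td-tr)*log(td/tr).
psc_kernel <- function(t_ms, tau_rise, tau_decay) {
  tpk <- tau_decay * tau_rise / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  norm <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  out <- numeric(length(t_ms))
  pos <- t_ms >= 0
  out[pos] <- (exp(-t_ms[pos] / tau_decay) - exp(-t_ms[pos] / tau_rise)) / norm
  out
}

rtnorm_pos <- function(n, mean, sd, lower = 0.5) {
  if (n == 0L) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Generate a synthetic voltage-clamp trace with ground truth
#'
#' Simulates `baseline + tonic + sum of event kernels + Gaussian noise` at the
#' requested sampling rate. Each event kernel is
#' `A * (exp(-t/tau_decay) - exp(-t/tau_rise))`, normalized so its peak equals
#' the drawn amplitude `A`; the sign of `A` follows the driving force at the
#' holding potential (inward/negative for AMPA events at -70 mV, outward/
#' positive for chloride events at 0 mV). Mixed events superpose a glycine and
#' a gaba kernel with weights `mixed_weights`.
#'
#' @param params A [vc_params()] object.
#' @return A list with `trace` (tibble, pA) and `truth`, a list holding the
#'   per-event ledger (`events`: tibble of time, class, amplitude, tau_decay),
#'   the tonic current at the holding potential (`tonic_current_pa`, signed) and
#'   the noise-free holding current (`holding_current_pa`).
#' @examples
#' p <- vc_params(duration = 2, event_rate = c(ampa = 0, glycine = 5, gaba = 0, mixed = 0))
#' sim <- gen_vc_trace(p)
#' nrow(sim$truth$events)
#' @export
gen_vc_trace <- function(params) {
  stopifnot(inherits(params, "vc_params"))
  p <- params
  n <- round(p$duration * p$sample_rate)
  withr::with_seed(p$seed, {
    classes <- names(p$event_rate)
    counts <- stats::rpois(length(classes), p$event_rate * p$duration)
    names(counts) <- classes
    events <- purrr::map_dfr(classes, function(cl) {
      k <- counts[[cl]]
      if (k == 0L) return(NULL)
      tibble::tibble(
        time = sort(stats::runif(k, 0, p$duration)),
        class = cl,
        amplitude = rtnorm_pos(k, p$amp_mean[[cl]], p$amp_sd[[cl]], lower = 1),
        tau_decay = if (cl == "mixed") NA_real_ else
          rtnorm_pos(k, p$tau_decay_mean[[cl]], p$tau_decay_sd[[cl]], lower = 0.5),
        tau_gly = if (cl == "mixed")
          rtnorm_pos(k, p$tau_decay_mean[["glycine"]], p$tau_decay_sd[["glycine"]], lower = 0.5)
          else NA_real_,
        tau_gaba = if (cl == "mixed")
          rtnorm_pos(k, p$tau_decay_mean[["gaba"]], p$tau_decay_sd[["gaba"]], lower = 0.5)
          else NA_real_
      )
    })
    noise <- if (p$noise_sd > 0) stats::rnorm(n, 0, p$noise_sd) else numeric(n)
  })
  g_tonic <- (p$tonic_glycine_pa + p$tonic_gaba_pa) / (0 - p$chloride_reversal)
  tonic_current <- g_tonic * (p$hold_voltage - p$chloride_reversal)
  values <- rep(p$baseline_current + tonic_current, n) + noise

  if (nrow(events) > 0L) {
    events <- dplyr::arrange(events, .data$time)
    sr_ms <- p$sample_rate / 1000
    e_time <- events$time; e_class <- events$class
    e_amp <- events$amplitude; e_tau <- events$tau_decay
    e_gly <- events$tau_gly; e_gaba <- events$tau_gaba
    for (i in seq_along(e_time)) {
      sgn <- sign(p$hold_voltage - class_reversal(e_class[i], p$chloride_reversal))
      if (sgn == 0) sgn <- 1
      i0 <- floor(e_time[i] * p$sample_rate) + 1L
      mixed <- e_class[i] == "mixed"
      tau_ref <- if (mixed) max(e_gly[i], e_gaba[i]) else e_tau[i]
      len <- min(n - i0 + 1L, ceiling(8 * tau_ref * sr_ms))
      if (len <= 0L) next
      t_ms <- (seq_len(len) - 1L) / sr_ms
      if (mixed) {
        # component peaks stay at their weight, so a drug that removes one
        # component leaves a genuinely smaller residual event
        kern <- p$mixed_weights[1] * psc_kernel(t_ms, p$tau_rise, e_gly[i]) +
          p$mixed_weights[2] * psc_kernel(t_ms, p$tau_rise, e_gaba[i])
      } else {
        kern <- psc_kernel(t_ms, p$tau_rise, e_tau[i])
      }
      idx <- i0:(i0 + len - 1L)
      values[idx] <- values[idx] + sgn * e_amp[i] * kern
    }
  } else {
    events <- tibble::tibble(
      time = numeric(0), class = character(0), amplitude = numeric(0),
      tau_decay = numeric(0), tau_gly = numeric(0), tau_gaba = numeric(0)
    )
  }

  trace <- new_trace(
    values, sample_rate = p$sample_rate, units = "pA",
    metadata = list(hold_voltage_mv = p$hold_voltage, drug_epochs = list())
  )
  list(
    trace = trace,
    truth = list(
      events = events,
      tonic_current_pa = tonic_current,
      holding_current_pa = p$baseline_current + tonic_current,
      params = p
    )
  )
}

#' Apply a pharmacological agent to generator parameters
#'
#' Transforms [vc_params()] (or a [cell_model()]) the way the corresponding
#' bath-applied drug transforms the recording: strychnine removes the
#' glycinergic phasic events, the glycine component of co-release events and
#' the glycine share of the tonic conductance; bicuculline does the same for
#' GABA; CNQX and NBQX block 90% of AMPA events by default, with CNQX
#' additionally shifting the baseline by +11.5 pA (a depolarizing current it
#' produces independently of its AMPA block) while NBQX shifts nothing; GRP
#' depolarizes only cells that express its receptor (`responsive = TRUE`).
#'
#' @param params A `vc_params` or `cell_model` object.
#' @param drug One of `"strychnine"`, `"bicuculline"`, `"cnqx"`, `"nbqx"`,
#'   `"grp"`.
#' @param responsive Does the cell respond to GRP? Ignored for other drugs.
#' @param block_fraction Fraction of AMPA events removed by CNQX/NBQX.
#' @param cnqx_shift_pa Baseline shift added by CNQX, pA.
#' @param grp_shift_pa Baseline shift added by GRP in responsive cells, pA.
#' @return The transformed parameter object (same class as the input).
#' @export
apply_drug <- function(params, drug, responsive = TRUE,
                       block_fraction = 0.9, cnqx_shift_pa = 11.5,
                       grp_shift_pa = 8) {
  drug <- match.arg(drug, c("strychnine", "bicuculline", "cnqx", "nbqx", "grp"))
  if (inherits(params, "cell_model")) {
    if (drug %in% c("strychnine", "bicuculline")) {
      gly <- params$g_tonic * params$tonic_glycine_share
      gaba <- params$g_tonic - gly
      if (drug == "strychnine") gly <- 0 else gaba <- 0
      params$g_tonic <- gly + gaba
      params$tonic_glycine_share <- if (params$g_tonic > 0) gly / params$g_tonic else 0
    }
    return(params)
  }
  stopifnot(inherits(params, "vc_params"))
  p <- params
  switch(drug,
    strychnine = {
      p$event_rate[["glycine"]] <- 0
      p$mixed_weights <- c(0, p$mixed_weights[2])
      p$tonic_glycine_pa <- 0
    },
    bicuculline = {
      p$event_rate[["gaba"]] <- 0
      p$mixed_weights <- c(p$mixed_weights[1], 0)
      p$tonic_gaba_pa <- 0
    },
    cnqx = {
      p$event_rate[["ampa"]] <- p$event_rate[["ampa"]] * (1 - block_fraction)
      p$baseline_current <- p$baseline_current + cnqx_shift_pa
    },
    nbqx = {
      p$event_rate[["ampa"]] <- p$event_rate[["ampa"]] * (1 - block_fraction)
    },
    grp = {
      if (isTRUE(responsive)) p$baseline_current <- p$baseline_current + grp_shift_pa
    }
  )
  # a drug that removed both co-release components leaves no mixed events
  if (sum(p$mixed_weights) == 0) p$event_rate[["mixed"]] <- 0
  p
}
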