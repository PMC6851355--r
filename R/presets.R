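#' Generator presets anchored to the published cohort means
#'
#' `preset_vc_ipsc()` describes a spontaneous-IPSC recording at a 0 mV hold:
#' kinetic mixture 34% glycinergic / 25% GABAergic / 41% co-release, decay
#' constants 6.2 +/- 2.2 ms (glycine) and 42 +/- 6 ms (GABA), and tonic
#' glycine/GABA shares carrying 10.25 and 22.5 pA at the 0 mV hold.
#'
#' `preset_cell()` solves a LIF cell exactly from the printed excitability
#' anchors: input resistance 911.9 MOhm (control) / 2920 MOhm (antagonist),
#' rheobase 39.8 / 7.4 pA and resting potential -56.96 mV. The solve gives
#' `gL = 0.342 nS`, `g_tonic = 0.754 nS`, `EL = -42.3 mV`,
#' `E_tonic = -63.6 mV`, `V_th = -20.7 mV`, and makes the rheobase drop on
#' removing the tonic conductance equal `g_tonic * (V_th - E_tonic) = 32.4 pA`
#' exactly — the tonic current the cell carries at its spike threshold.
#'
#' `preset_calibration_cell()` is the cell used for the simulated
#' spike/fluorescence calibration staircase: rheobase ~20 pA so the 10 pA step
#' is silent and spike count rises monotonically across the 8 steps.
#'
#' @param event_rate_total Total sIPSC rate, Hz, split across classes by the
#'   kinetic mixture.
#' @param mixture Length-3 kinetic mixture (glycinergic, gabaergic, mixed).
#' @param duration,noise_sd,seed Passed to [vc_params()].
#' @return `preset_vc_ipsc()` a [vc_params()]; the cell presets a
#'   [cell_model()].
#' @export
preset_vc_ipsc <- function(event_rate_total = 5,
                           mixture = c(glycine = 0.34, gaba = 0.25, mixed = 0.41),
                           duration = 60, noise_sd = 2, seed = 1L) {
  vc_params(
    duration = duration,
    hold_voltage = 0,
    event_rate = c(
      ampa = 0,
      glycine = event_rate_total * mixture[["glycine"]],
      gaba = event_rate_total * mixture[["gaba"]],
      mixed = event_rate_total * mixture[["mixed"]]
    ),
    tonic_glycine_pa = 10.25,
    tonic_gaba_pa = 22.5,
    chloride_reversal = -70,
    baseline_current = 15,
    noise_sd = noise_sd,
    seed = seed
  )
}

#' @rdname preset_vc_ipsc
#' @param rin_control_mohm,rin_blocked_mohm Input resistance anchors, MOhm.
#' @param rheobase_control_pa,rheobase_blocked_pa Rheobase anchors, pA.
#' @param v_rest_control_mv Resting-potential anchor, mV.
#' @param C Capacitance, pF.
#' @export
preset_cell <- function(rin_control_mohm = 911.9, rin_blocked_mohm = 2920,
                        rheobase_control_pa = 39.8, rheobase_blocked_pa = 7.4,
                        v_rest_control_mv = -56.96, C = 15) {
  g_total <- 1000 / rin_control_mohm      # nS
  gL <- 1000 / rin_blocked_mohm
  g_tonic <- g_total - gL
  V_th <- v_rest_control_mv + rheobase_control_pa / g_total
  EL <- V_th - rheobase_blocked_pa / gL
  E_tonic <- (v_rest_control_mv * g_total - gL * EL) / g_tonic
  cell_model(
    gL = gL, EL = EL, g_tonic = g_tonic, E_tonic = E_tonic, C = C,
    V_th = V_th, V_reset = EL - 5, refractory = 2,
    tonic_glycine_share = 10.25 / 32.75
  )
}

#' @rdname preset_vc_ipsc
#' @export
preset_calibration_cell <- function() {
  # rheobase (V_th - EL) * gL = 28 pA: silent at 10-20 pA, ~8 spikes at the
  # 30 pA step and ~18 at 80 pA over a 500 ms pulse (deep AHP reset plus a
  # 20 ms refractory period flatten the f-I curve toward the recorded range)
  cell_model(
    gL = 1.4, EL = -60, g_tonic = 0, E_tonic = -70, C = 20,
    V_th = -40, V_reset = -70, refractory = 20,
    tonic_glycine_share = 0
  )
}
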