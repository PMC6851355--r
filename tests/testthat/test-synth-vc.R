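test_that("a rate-free, noise-free run is a constant baseline", {
  p <- vc_params(duration = 2, noise_sd = 0, baseline_current = -20)
  sim <- gen_vc_trace(p)
  expect_equal(unique(sim$trace$value), -20)
  expect_equal(nrow(sim$truth$events), 0)
  expect_equal(nrow(sim$trace), 2 * 20000)
})

test_that("the ground-truth ledger lists every generated event", {
  p <- vc_params(duration = 20, noise_sd = 1,
                 event_rate = c(ampa = 0, glycine = 2, gaba = 1, mixed = 1),
                 seed = 11L)
  sim <- gen_vc_trace(p)
  tr <- sim$truth$events
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$time >= 0 & tr$time <= 20))
  expect_true(!is.unsorted(tr$time))
  expect_true(all(tr$class %in% c("glycine", "gaba", "mixed")))
  expect_true(all(tr$amplitude > 0))
  # non-mixed events carry their own tau; mixed carry both components
  expect_true(all(!is.na(tr$tau_decay[tr$class != "mixed"])))
  expect_true(all(!is.na(tr$tau_gly[tr$class == "mixed"])))
  expect_true(all(!is.na(tr$tau_gaba[tr$class == "mixed"])))
})

test_that("tonic conductance shifts the trace by g * (V_hold - E_rev)", {
  # 0.5 nS at 0 mV hold against a -70 mV reversal carries 35 pA
  mk <- function(gly_pa, gaba_pa) {
    vc_params(duration = 1, noise_sd = 0, hold_voltage = 0,
              tonic_glycine_pa = gly_pa, tonic_gaba_pa = gaba_pa,
              chloride_reversal = -70)
  }
  off <- gen_vc_trace(mk(0, 0))$trace$value[1]
  on <- gen_vc_trace(mk(15, 20))$trace$value[1]
  expect_equal(on - off, 35)

  # at a different hold the offset follows the driving force
  p <- vc_params(duration = 1, noise_sd = 0, hold_voltage = -35,
                 tonic_glycine_pa = 35, tonic_gaba_pa = 35,
                 chloride_reversal = -70)
  g <- (35 + 35) / 70  # nS
  expect_equal(gen_vc_trace(p)$trace$value[1], g * (-35 - -70))
  expect_equal(gen_vc_trace(p)$truth$tonic_current_pa, 35)
})

test_that("event polarity follows the driving force at the holding potential", {
  ipsc <- gen_vc_trace(vc_params(duration = 5, noise_sd = 0, hold_voltage = 0,
                                 event_rate = c(ampa = 0, glycine = 3, gaba = 0, mixed = 0),
                                 seed = 2L))
  expect_gt(max(ipsc$trace$value), 0)  # outward at 0 mV
  epsc <- gen_vc_trace(vc_params(duration = 5, noise_sd = 0, hold_voltage = -70,
                                 event_rate = c(ampa = 3, glycine = 0, gaba = 0, mixed = 0),
                                 seed = 2L))
  expect_lt(min(epsc$trace$value), 0)  # inward at -70 mV
})

test_that("generation is bit-reproducible for a fixed seed", {
  p <- preset_vc_ipsc(duration = 3, seed = 21L)
  a <- gen_vc_trace(p)
  b <- gen_vc_trace(p)
  expect_identical(a$trace$value, b$trace$value)
  expect_identical(a$truth$events, b$truth$events)
  p2 <- preset_vc_ipsc(duration = 3, seed = 22L)
  expect_false(identical(gen_vc_trace(p2)$trace$value, a$trace$value))
})

test_that("invalid generator parameters are rejected", {
  expect_error(vc_params(duration = 0), "duration")
  expect_error(vc_params(event_rate = c(ampa = -1, glycine = 0, gaba = 0, mixed = 0)),
               "non-negative")
  expect_error(vc_params(tau_rise = 0), "positive")
  expect_error(vc_params(tonic_glycine_pa = -2), "magnitude")
})

test_that("drugs transform parameters the way the antagonists act", {
  p <- preset_vc_ipsc(seed = 1L)

  s <- apply_drug(p, "strychnine")
  expect_equal(s$event_rate[["glycine"]], 0)
  expect_equal(s$tonic_glycine_pa, 0)
  expect_equal(s$mixed_weights[1], 0)
  expect_equal(s$tonic_gaba_pa, p$tonic_gaba_pa)

  sb <- apply_drug(s, "bicuculline")
  expect_equal(sb$tonic_glycine_pa + sb$tonic_gaba_pa, 0)
  expect_equal(sb$event_rate[["mixed"]], 0)  # both components gone

  # strychnine on a gaba-only configuration changes nothing but the (zero)
  # glycine tonic share
  g_only <- vc_params(duration = 1, event_rate = c(ampa = 0, glycine = 0, gaba = 2, mixed = 0),
                      tonic_gaba_pa = 20)
  g_str <- apply_drug(g_only, "strychnine")
  expect_equal(g_str$event_rate, g_only$event_rate)
  expect_equal(g_str$tonic_gaba_pa, 20)

  # CNQX depolarizes by 11.5 pA, NBQX by none; both block ~90% of AMPA events
  e <- vc_params(duration = 1, hold_voltage = -70,
                 event_rate = c(ampa = 10, glycine = 0, gaba = 0, mixed = 0))
  cn <- apply_drug(e, "cnqx")
  nb <- apply_drug(e, "nbqx")
  expect_equal(cn$baseline_current - e$baseline_current, 11.5)
  expect_equal(nb$baseline_current, e$baseline_current)
  expect_equal(cn$event_rate[["ampa"]], 1)
  expect_equal(nb$event_rate[["ampa"]], 1)

  # GRP depolarizes only responsive cells
  expect_gt(apply_drug(e, "grp", responsive = TRUE)$baseline_current,
            e$baseline_current)
  expect_equal(apply_drug(e, "grp", responsive = FALSE)$baseline_current,
               e$baseline_current)

  expect_error(apply_drug(e, "tetrodotoxin"))
})

test_that("removing both tonic shares removes the full holding-current offset", {
  p <- preset_vc_ipsc(duration = 1, seed = 1L)
  p$noise_sd <- 0
  p$event_rate[] <- 0
  both <- apply_drug(apply_drug(p, "strychnine"), "bicuculline")
  v_ctrl <- gen_vc_trace(p)$trace$value[1]
  v_block <- gen_vc_trace(both)$trace$value[1]
  expect_equal(v_ctrl - v_block, 10.25 + 22.5)
})
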