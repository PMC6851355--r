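test_that("decay-constant classification follows the closed intermediate band", {
  expect_equal(classify_event_class(6.2), "glycinergic")
  expect_equal(classify_event_class(42), "gabaergic")
  expect_equal(classify_event_class(16.8), "mixed")   # closed lower edge
  expect_equal(classify_event_class(35.7), "mixed")   # closed upper edge
  expect_equal(classify_event_class(16.799), "glycinergic")
  expect_equal(classify_event_class(35.701), "gabaergic")
  expect_equal(classify_event_class(NA_real_), "unclassified")
  expect_error(classify_event_class(0), "positive")
  expect_error(class_boundaries(20, 10), "mixed_low")
})

test_that("mixture proportions are per-class counts over classified events", {
  ev <- tibble::tibble(class = c(rep("glycinergic", 4), "gabaergic"))
  mx <- mixture_proportions(ev)
  expect_equal(mx$fraction[mx$class == "glycinergic"], 0.8)
  expect_equal(mx$fraction[mx$class == "gabaergic"], 0.2)
  expect_equal(mx$fraction[mx$class == "mixed"], 0)
  expect_equal(sum(mx$fraction), 1)

  ev2 <- tibble::tibble(class = c(rep("glycinergic", 3), "unclassified"))
  expect_equal(sum(mixture_proportions(ev2)$fraction), 1)  # excludes failed fits
  expect_error(mixture_proportions(tibble::tibble(class = "unclassified")),
               "classified")
})

test_that("holding current is the all-points-histogram peak", {
  const <- new_trace(rep(-20, 200000), sample_rate = 20000, units = "pA")
  expect_equal(as.numeric(estimate_holding_current(const)), -20)

  # Gaussian noise around -20 pA with ~10% of samples inside events
  tr <- plant_events_trace(seq(0.2, 9.8, by = 0.45), amplitude = 30,
                           tau_decay = 8, duration = 10, noise_sd = 5,
                           baseline = -20, seed = 3L)
  est <- as.numeric(estimate_holding_current(tr))
  expect_lt(abs(est - -20), 0.5)
  # cross-check against the independent histogram-mode oracle on the
  # event-free samples
  free <- tr$value[rep(c(TRUE, FALSE), c(2000, 7000))[seq_len(nrow(tr))]]
  expect_lt(abs(est - mode_oracle(free)), 1)

  expect_error(estimate_holding_current(const, c(0, 2)), "5 s")
})

test_that("tonic shift recovers a planted conductance in closed form", {
  mk <- function(gly, gaba, seed) {
    p <- vc_params(duration = 10, noise_sd = 2, hold_voltage = 0,
                   tonic_glycine_pa = gly, tonic_gaba_pa = gaba,
                   event_rate = c(ampa = 0, glycine = 1, gaba = 1, mixed = 0),
                   seed = seed)
    gen_vc_trace(p)$trace
  }
  pre <- mk(10.25, 22.5, 31L)
  post <- mk(0, 22.5, 32L)  # strychnine removed the glycine share
  joined <- new_trace(c(pre$value, post$value), sample_rate = 20000, units = "pA")
  sh <- measure_tonic_shift(joined, c(0, 10), c(10, 20))
  expect_lt(abs(sh$tonic_pa - 10.25), 1)
  expect_lt(sh$shift_pa, 0)  # losing outward current

  # identical epochs shift nothing
  same <- measure_tonic_shift(joined, c(0, 8), c(10, 18))
  sh0 <- measure_tonic_shift(new_trace(rep(5, 200000), 20000, "pA"),
                             c(0, 5), c(5, 10))
  expect_equal(sh0$shift_pa, 0)
  expect_error(measure_tonic_shift(joined, c(0, 10), c(5, 15)), "overlap")
})

test_that("tonic-shift measurement is linear in the planted conductance", {
  shift_for <- function(g_pa) {
    p0 <- vc_params(duration = 8, noise_sd = 2, hold_voltage = 0,
                    tonic_glycine_pa = g_pa, tonic_gaba_pa = 0, seed = 41L)
    p1 <- p0; p1$tonic_glycine_pa <- 0; p1$seed <- 42L
    a <- gen_vc_trace(p0)$trace
    b <- gen_vc_trace(p1)$trace
    joined <- new_trace(c(a$value, b$value), sample_rate = 20000, units = "pA")
    measure_tonic_shift(joined, c(0, 8), c(8, 16))$tonic_pa
  }
  s1 <- shift_for(12)
  s2 <- shift_for(24)
  expect_lt(abs(s1 - 12), 0.5)
  expect_lt(abs(s2 - 24), 0.5)
  expect_lt(abs(s2 - 2 * s1), 1)
})

test_that("blockade fraction is the relative frequency loss", {
  expect_equal(blockade_fraction(1, 1), 0)
  expect_equal(blockade_fraction(1, 0.38), 0.62)
  expect_equal(blockade_fraction(2, 0), 1)
  expect_error(blockade_fraction(0, 1), "positive")
})

test_that("sequential antagonist blockade decomposes the tonic current additively", {
  p <- preset_vc_ipsc(duration = 12, seed = 51L)
  p$event_rate[] <- c(0, 1, 1, 0.5)
  p_str <- apply_drug(p, "strychnine"); p_str$seed <- 52L
  p_both <- apply_drug(p_str, "bicuculline"); p_both$seed <- 53L
  h <- function(pp) as.numeric(estimate_holding_current(gen_vc_trace(pp)$trace))
  h0 <- h(p); h1 <- h(p_str); h2 <- h(p_both)
  step_sum <- (h0 - h1) + (h1 - h2)
  expect_lt(abs((h0 - h2) - 32.75), 1)
  expect_equal(step_sum, h0 - h2)
  expect_lt(abs((h0 - h1) - 10.25), 1)
  expect_lt(abs((h1 - h2) - 22.5), 1)
})

test_that("the end-to-end inhibition profile recovers the planted physiology", {
  prof <- inhibition_profile(preset_vc_ipsc(duration = 40, seed = 61L))
  g <- glance(prof)
  expect_equal(sum(prof$mixture$fraction), 1)
  expect_lt(abs(g$tonic_glycine_pa - 10.25), 1.5)
  expect_lt(abs(g$tonic_gaba_pa - 22.5), 1.5)
  # strychnine removes glycinergic and (whole) mixed events above threshold:
  # a majority of the control frequency
  expect_gt(g$strychnine_block_fraction, 0.4)
  expect_gt(g$bicuculline_block_fraction, 0.6)
  # after both antagonists essentially nothing remains
  expect_lt(prof$frequency_hz[["strychnine_bicuculline"]],
            0.05 * prof$frequency_hz[["control"]])
})
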