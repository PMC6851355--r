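test_that("a flat trace yields no events and noisy traces no spurious ones", {
  flat <- new_trace(rep(-20, 20000), sample_rate = 20000, units = "pA")
  expect_equal(nrow(detect_events(flat, "outward")), 0)
  noisy <- new_trace(withr::with_seed(1L, rnorm(200000, -20, 2)),
                     sample_rate = 20000, units = "pA")
  expect_lte(nrow(detect_events(noisy, "outward")), 2)
})

test_that("planted events are recovered with accurate onsets", {
  times <- seq(0.5, 19.5, by = 1)  # 20 events, well separated
  tr <- plant_events_trace(times, amplitude = 20, tau_decay = 8,
                           duration = 20, noise_sd = 2, seed = 4L)
  ev <- detect_events(tr, "outward")
  expect_equal(nrow(ev), 20)
  expect_true(all(abs(ev$onset - times) < 0.001))
  expect_true(all(abs(ev$amplitude - 20) < 6))
})

test_that("detection is invariant under constant baseline shifts", {
  times <- seq(0.4, 9.6, by = 0.8)
  tr <- plant_events_trace(times, amplitude = 25, tau_decay = 10,
                           duration = 10, noise_sd = 2, seed = 6L)
  shifted <- new_trace(tr$value + 137, sample_rate = 20000, units = "pA")
  a <- detect_events(tr, "outward")
  b <- detect_events(shifted, "outward")
  expect_equal(b$onset, a$onset)
  expect_equal(b$peak_time, a$peak_time)
  expect_equal(b$amplitude, a$amplitude, tolerance = 1e-6)
})

test_that("recall and precision reach 0.95 for events at 5x noise sd", {
  for (seed in c(2L, 9L, 17L)) {
    p <- vc_params(duration = 40, noise_sd = 2,
                   event_rate = c(ampa = 0, glycine = 1.5, gaba = 1, mixed = 0.5),
                   amp_mean = c(ampa = 25, glycine = 25, gaba = 25, mixed = 25),
                   amp_sd = c(ampa = 0, glycine = 0, gaba = 0, mixed = 0),
                   seed = seed)
    sim <- gen_vc_trace(p)
    ev <- detect_events(sim$trace, "outward")
    m <- match_events(ev$onset, sim$truth$events$time, tol_s = 0.004)
    expect_gte(m$recall, 0.95)
    expect_gte(m$precision, 0.95)
  }
})

test_that("a noiseless exponential decay is recovered to within 1%", {
  # instant-onset pure exponential: exactly the fitted model class
  sr <- 20000
  n <- 5 * sr
  values <- numeric(n)
  i0 <- 2 * sr + 1L
  values[i0:n] <- 30 * exp(-((seq_len(n - i0 + 1L) - 1L) / sr * 1000) / 10)
  tr <- new_trace(values, sample_rate = sr, units = "pA")
  ev <- fit_event_decay(tr, detect_events(tr, "outward"))
  expect_equal(ev$tau_decay, 10, tolerance = 0.01)
  expect_equal(abs(ev$amplitude), 30, tolerance = 0.02)
})

test_that("fitted tau is invariant under amplitude rescaling", {
  mk <- function(a) plant_events_trace(c(1, 3), amplitude = a, tau_decay = 12,
                                       duration = 5, noise_sd = 0)
  t1 <- fit_event_decay(mk(10), detect_events(mk(10), "outward"))$tau_decay
  t2 <- fit_event_decay(mk(80), detect_events(mk(80), "outward"))$tau_decay
  expect_equal(t1, t2, tolerance = 1e-4)
})

test_that("a biexponential co-release event fits to the grid-search oracle value", {
  # equal glycine (6.2 ms) and gaba (42 ms) components
  sr <- 20000
  n <- 5 * sr
  values <- numeric(n)
  i0 <- sr + 1L  # event at 1 s
  t_ms <- (seq_len(n - i0 + 1L) - 1L) / sr * 1000
  kern <- 0.5 * spinaltone:::psc_kernel(t_ms, 0.7, 6.2) +
    0.5 * spinaltone:::psc_kernel(t_ms, 0.7, 42)
  values[i0:n] <- 30 * kern
  tr <- new_trace(values, sample_rate = sr, units = "pA")
  ev <- fit_event_decay(tr, detect_events(tr, "outward"))
  expect_equal(nrow(ev), 1)

  # oracle: brute-force grid fit over the same window definition
  # (peak to 10% of peak)
  pk <- which.max(values)
  peak_val <- values[pk]
  end <- pk
  while (values[end] > 0.1 * peak_val) end <- end + 1L
  idx <- pk:end
  tau_oracle <- grid_fit_tau((idx - pk) / sr * 1000, values[idx])

  expect_gt(ev$tau_decay, 6.2)
  expect_lt(ev$tau_decay, 42)
  expect_equal(ev$tau_decay, tau_oracle, tolerance = 0.05)
})

test_that("glycinergic preset events fit inside the published tau envelope", {
  p <- vc_params(duration = 40, noise_sd = 2,
                 event_rate = c(ampa = 0, glycine = 4, gaba = 0, mixed = 0),
                 seed = 8L)
  sim <- gen_vc_trace(p)
  ev <- fit_event_decay(sim$trace, detect_events(sim$trace, "outward"))
  taus <- ev$tau_decay[!is.na(ev$tau_decay)]
  expect_gt(length(taus), 100)
  expect_gt(mean(taus), 6.2 - 2.2)
  expect_lt(mean(taus), 6.2 + 2.2)
})

test_that("event frequency is count over epoch length", {
  ev <- tibble::tibble(onset = c(0.5, 1.5, 2.5))
  expect_equal(event_frequency(ev, c(0, 3)), 1)
  expect_equal(event_frequency(ev, c(0, 1)), 1)
  expect_equal(event_frequency(tibble::tibble(onset = numeric(0)), c(0, 10)), 0)
  expect_error(event_frequency(ev, c(1, 1)), "epoch")

  # a generated recording recovers the Poisson rate within counting error
  p <- vc_params(duration = 60, event_rate = c(ampa = 0, glycine = 3, gaba = 0, mixed = 0),
                 seed = 12L)
  sim <- gen_vc_trace(p)
  f <- event_frequency(detect_events(sim$trace, "outward"), c(0, 60))
  expect_lt(abs(f - 3), 3 * sqrt(3 / 60))
})
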