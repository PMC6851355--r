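test_that("dF/F is zero for a constant trace and exact for a known excursion", {
  const <- new_trace(rep(100, 120), sample_rate = 2, units = "au")
  expect_true(all(compute_dff(const)$value == 0))

  v <- rep(100, 120); v[80] <- 103.5
  tr <- new_trace(v, sample_rate = 2, units = "au")
  dff <- compute_dff(tr, c(0, 30))
  expect_equal(max(dff$value), 3.5)
  expect_equal(trace_units(dff), "dff_percent")

  bad <- new_trace(rep(0, 120), sample_rate = 2, units = "au")
  expect_error(compute_dff(bad), "positive")
})

test_that("dF/F is invariant under multiplicative rescaling", {
  tr <- gen_gcamp_trace(c(20, 60), duration = 120, noise_sd = 0.005, seed = 5L)
  dff1 <- compute_dff(tr, c(0, 10))
  tr2 <- new_trace(tr$value * 7.3, sample_rate = 2, units = "au")
  dff2 <- compute_dff(tr2, c(0, 10))
  expect_equal(dff1$value, dff2$value, tolerance = 1e-10)
})

test_that("baseline window must precede the drug epoch", {
  md <- list(drug_epochs = list(list(name = "somatostatin", start_s = 60, end_s = 900)))
  tr <- gen_gcamp_trace(numeric(0), duration = 900, metadata = md)
  expect_silent(compute_dff(tr))  # default first-60 s window is legal
  expect_error(compute_dff(tr, c(0, 120)), "precede")
})

test_that("peak detection is strictly above threshold with separation", {
  v <- rep(0, 600)
  v[c(100, 300, 500)] <- c(10, 8, 12)
  dff <- new_trace(v, sample_rate = 2, units = "dff_percent")
  expect_equal(length(detect_calcium_peaks(dff, 3.5)), 3)

  # a peak at exactly the threshold is noise by convention
  v2 <- rep(0, 600); v2[200] <- 3.5
  expect_equal(length(detect_calcium_peaks(
    new_trace(v2, sample_rate = 2, units = "dff_percent"), 3.5)), 0)
  v2[200] <- 3.50001
  expect_equal(length(detect_calcium_peaks(
    new_trace(v2, sample_rate = 2, units = "dff_percent"), 3.5)), 1)

  # all-subthreshold trace yields an empty list
  expect_equal(length(detect_calcium_peaks(
    new_trace(rep(1, 600), sample_rate = 2, units = "dff_percent"), 3.5)), 0)
})

test_that("raising the threshold never increases the peak count", {
  tr <- gen_gcamp_trace(c(30, 90, 150, 210), duration = 300,
                        noise_sd = 0.01, seed = 9L)
  dff <- compute_dff(tr, c(0, 10))
  counts <- vapply(c(1, 2, 3.5, 5, 10, 20),
                   function(th) length(detect_calcium_peaks(dff, th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("threshold calibration picks the lowest step reaching the spike criterion", {
  pts <- tibble::tibble(current_pa = c(10, 30, 80),
                        mean_spikes = c(0.2, 6.6, 19.3),
                        mean_dff = c(0.6, 3.5, 17.5))
  expect_equal(calibrate_threshold(pts), 3.5)
  expect_equal(calibrate_threshold(pts, spike_criterion = 10), 17.5)

  first <- tibble::tibble(current_pa = c(10, 30), mean_spikes = c(2, 9),
                          mean_dff = c(1.2, 4))
  expect_equal(calibrate_threshold(first), 1.2)

  silent <- tibble::tibble(current_pa = c(10, 30), mean_spikes = c(0, 0.5),
                           mean_dff = c(0.5, 1))
  expect_error(calibrate_threshold(silent), "criterion")
  expect_error(calibrate_threshold(pts[1, ]), "2 calibration")
})

test_that("activity labels follow the peak-count and bursting rules", {
  expect_equal(classify_cell_activity(numeric(0)), "inactive")
  expect_equal(classify_cell_activity(c(10, 200)), "active")
  expect_equal(classify_cell_activity(c(10, 100, 250)), "repeated_bursting")
  # three peaks spread wider than the 5-minute window are active only
  expect_equal(classify_cell_activity(c(10, 400, 800)), "active")
  # but any 300 s sub-span with three peaks qualifies
  expect_equal(classify_cell_activity(c(10, 500, 600, 700)), "repeated_bursting")
})

test_that("reaction time is measured from bath arrival", {
  expect_equal(measure_reaction_time(6.8 * 60, drug_arrival_s = 60), 5.8)
  expect_true(is.na(measure_reaction_time(numeric(0))))
  rt <- measure_reaction_time(c(30, 400), drug_arrival_s = 60)
  expect_true(is.na(rt))
  expect_true(attr(rt, "spontaneous"))
})

test_that("cohort summaries reproduce proportion arithmetic", {
  rec <- function(n_active, n_total) {
    tibble::tibble(label = rep(c("active", "inactive"),
                               c(n_active, n_total - n_active)))
  }
  expect_equal(summarize_cohort(rec(10, 181))$percent_active, 100 * 10 / 181)
  expect_equal(summarize_cohort(rec(25, 74))$percent_active, 100 * 25 / 74)
  expect_equal(summarize_cohort(rec(0, 50))$percent_active, 0)
  expect_error(summarize_cohort(rec(1, 2), condition = "somatostatin"), "empty")
})

test_that("a synthetic somatostatin cohort recovers its planted responders and latency", {
  coh <- gen_calcium_cohort(n_cells = 74, responder_fraction = 0.338,
                            latency_mean_min = 5.8, latency_sd_min = 0.8,
                            seed = 14L)
  rec <- coh$records
  expect_equal(nrow(rec), 74)
  expect_equal(sum(rec$label != "inactive"), sum(coh$truth$responder))
  # measured reaction times sit on the planted latencies (within one frame
  # plus kernel rise)
  got <- rec$reaction_time_min[!is.na(rec$reaction_time_min)]
  planted <- coh$truth$latency_min[coh$truth$responder]
  expect_equal(length(got), length(planted))
  expect_lt(abs(mean(got) - mean(planted)), 0.05)
  # responders burst repeatedly by construction
  expect_true(all(rec$label[coh$truth$responder] == "repeated_bursting"))
})
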