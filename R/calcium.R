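#' Convert a fluorescence trace to dF/F (%)
#'
#' `100 * (F - F0) / F0` with `F0` the mean fluorescence over the baseline
#' window, which must precede any drug epoch. The result is invariant under
#' multiplicative rescaling of the raw trace.
#'
#' @param trace Fluorescence trace, a.u.
#' @param baseline_window `(start_s, end_s)` of the baseline. Default: the
#'   first 60 s when the metadata carries drug epochs (bath arrival is at
#'   1 minute), else the first 30 s (or the whole trace if shorter).
#' @return A dF/F trace tibble in percent.
#' @examples
#' fl <- gen_gcamp_trace(c(5), duration = 20, f0 = 100)
#' dff <- compute_dff(fl, c(0, 2))
#' @export
compute_dff <- function(trace, baseline_window = NULL) {
  assert_trace(trace)
  md <- trace_metadata(trace)
  if (is.null(baseline_window)) {
    dur <- trace_duration(trace)
    base_len <- if (length(md$drug_epochs)) 60 else 30
    baseline_window <- c(0, min(base_len, dur))
  }
  if (length(md$drug_epochs)) {
    first_drug <- min(purrr::map_dbl(md$drug_epochs, "start_s"))
    if (baseline_window[2] > first_drug) {
      stop("baseline window must precede the first drug epoch", call. = FALSE)
    }
  }
  f0 <- mean(trace$value[epoch_index(trace, baseline_window)])
  if (!is.finite(f0) || f0 <= 0) stop("baseline fluorescence must be positive", call. = FALSE)
  new_trace(100 * (trace$value - f0) / f0,
            sample_rate = trace_sample_rate(trace),
            units = "dff_percent", t0 = trace$time[1], metadata = md)
}

#' Detect suprathreshold calcium peaks
#'
#' Local maxima of the dF/F trace strictly above the threshold (signals at or
#' below it are treated as noise), separated by at least `min_separation_s`.
#'
#' @param dff dF/F trace in percent.
#' @param threshold Detection threshold, % dF/F (default 3.5).
#' @param min_separation_s Minimum peak separation, s (default 2, i.e. 4
#'   frames at 2 Hz).
#' @return Peak times, seconds (possibly empty).
#' @export
detect_calcium_peaks <- function(dff, threshold = 3.5, min_separation_s = 2) {
  assert_trace(dff)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  v <- dff$value
  n <- length(v)
  if (n < 3L) return(numeric(0))
  is_peak <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE) &
    v > threshold
  peaks <- which(is_peak)
  if (length(peaks) > 1L) {
    sr <- trace_sample_rate(dff)
    min_gap <- min_separation_s * sr
    ord <- order(v[peaks], decreasing = TRUE)
    kept <- logical(length(peaks))
    taken <- numeric(0)
    for (j in ord) {
      if (all(abs(peaks[j] - taken) >= min_gap)) {
        kept[j] <- TRUE
        taken <- c(taken, peaks[j])
      }
    }
    peaks <- sort(peaks[kept])
  }
  dff$time[peaks]
}

#' Calibrate the spiking threshold from paired recordings
#'
#' Given the calibration table of mean spike count and mean dF/F per injected
#' current step, the threshold is the mean dF/F of the lowest-current step
#' whose mean spike count reaches `spike_criterion`. On the published table
#' (10 pA: 0.2 spikes, 0.6%; 30 pA: 6.6 spikes, 3.5%; 80 pA: 19.3 spikes,
#' 17.5%) this yields 3.5%.
#'
#' @param points Calibration tibble with columns `current_pa`, `mean_spikes`,
#'   `mean_dff` (%), sorted by current (at least 2 rows).
#' @param spike_criterion Minimum mean spike count, default 1.
#' @return Threshold in % dF/F.
#' @examples
#' pts <- tibble::tibble(current_pa = c(10, 30, 80),
#'                       mean_spikes = c(0.2, 6.6, 19.3),
#'                       mean_dff = c(0.6, 3.5, 17.5))
#' calibrate_threshold(pts)
#' @export
calibrate_threshold <- function(points, spike_criterion = 1) {
  if (!is.data.frame(points) || nrow(points) < 2L ||
      !all(c("current_pa", "mean_spikes", "mean_dff") %in% names(points))) {
    stop("need >= 2 calibration points with current_pa, mean_spikes, mean_dff",
         call. = FALSE)
  }
  if (is.unsorted(points$current_pa)) {
    stop("calibration points must be sorted by current", call. = FALSE)
  }
  hit <- which(points$mean_spikes >= spike_criterion)
  if (length(hit) == 0L) {
    stop("no calibration point reaches the spike criterion", call. = FALSE)
  }
  points$mean_dff[hit[1]]
}

#' Classify a cell's calcium activity
#'
#' No suprathreshold peak: `inactive`. At least one: `active`. At least
#' `burst_min_peaks` peaks within any `window_s` span (sliding window over the
#' whole recording): `repeated_bursting`.
#'
#' @param peak_times Suprathreshold peak times, seconds.
#' @param window_s Bursting window, s (default 300 = 5 minutes).
#' @param burst_min_peaks Peaks required inside the window (default 3).
#' @return `"inactive"`, `"active"` or `"repeated_bursting"`.
#' @export
classify_cell_activity <- function(peak_times, window_s = 300, burst_min_peaks = 3) {
  k <- length(peak_times)
  if (k == 0L) return("inactive")
  if (k >= burst_min_peaks) {
    pt <- sort(peak_times)
    spans <- pt[seq_len(k - burst_min_peaks + 1L) + burst_min_peaks - 1L] -
      pt[seq_len(k - burst_min_peaks + 1L)]
    if (any(spans <= window_s)) return("repeated_bursting")
  }
  "active"
}

#' Reaction time to an agonist
#'
#' Time from bath arrival of the drug to the first suprathreshold peak, in
#' minutes. A peak before arrival marks the cell spontaneously active (it is
#' excluded from the responder set); no peak at all returns `NA`.
#'
#' @param peak_times Suprathreshold peak times, seconds.
#' @param drug_arrival_s Bath arrival time, seconds (default 60: the drug
#'   reaches the chamber one minute into the recording).
#' @return Reaction time in minutes, `NA` if no peak, with attribute
#'   `spontaneous = TRUE` if a pre-arrival peak exists.
#' @export
measure_reaction_time <- function(peak_times, drug_arrival_s = 60) {
  if (length(peak_times) == 0L) return(NA_real_)
  if (any(peak_times < drug_arrival_s)) {
    return(structure(NA_real_, spontaneous = TRUE))
  }
  (min(peak_times) - drug_arrival_s) / 60
}

#' Analyze one ROI's fluorescence recording
#'
#' Full per-cell pipeline: dF/F conversion, peak detection, activity label,
#' and (for agonist runs) reaction time.
#'
#' @param trace Raw fluorescence trace, a.u.
#' @param condition `"control"` or `"somatostatin"`.
#' @param threshold Peak threshold, % dF/F.
#' @param drug_arrival_s Bath arrival for agonist runs, s.
#' @param ... Passed to [detect_calcium_peaks()].
#' @return A one-row tibble: `condition`, `n_peaks`, `label`, `max_dff`,
#'   `reaction_time_min`, `spontaneous`.
#' @export
analyze_calcium_cell <- function(trace, condition = c("control", "somatostatin"),
                                 threshold = 3.5, drug_arrival_s = 60, ...) {
  condition <- match.arg(condition)
  dff <- compute_dff(trace)
  peaks <- detect_calcium_peaks(dff, threshold, ...)
  rt <- NA_real_
  spont <- FALSE
  if (condition == "somatostatin") {
    rt <- measure_reaction_time(peaks, drug_arrival_s)
    spont <- isTRUE(attr(rt, "spontaneous"))
  } else {
    spont <- length(peaks) > 0L
  }
  tibble::tibble(
    condition = condition,
    n_peaks = length(peaks),
    label = classify_cell_activity(peaks),
    max_dff = max(dff$value, 0),
    reaction_time_min = as.numeric(rt),
    spontaneous = spont
  )
}

#' Summarize a cohort of calcium recordings
#'
#' Computes the fraction of active cells, mean/SEM of the per-cell maximal
#' dF/F, and the mean/SEM reaction time of responders. A cell is counted
#' active if its label is not `"inactive"`.
#'
#' @param records Tibble with one row per cell, columns `label` and optionally
#'   `max_dff`, `reaction_time_min`, `condition`.
#' @param condition If given, filter `records$condition` first.
#' @return A one-row tibble: `n_total`, `n_active`, `percent_active`,
#'   `mean_dff`, `sem_dff`, `mean_reaction_time_min`, `sem_reaction_time_min`.
#' @examples
#' summarize_cohort(tibble::tibble(label = rep(c("active", "inactive"), c(10, 171))))
#' @export
summarize_cohort <- function(records, condition = NULL) {
  if (!is.null(condition)) {
    keep <- if ("condition" %in% names(records)) records$condition == condition
            else rep(FALSE, nrow(records))
    records <- records[keep, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("empty cohort", call. = FALSE)
  active <- records$label != "inactive"
  sem <- function(x) if (sum(!is.na(x)) > 1) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))) else NA_real_
  dff <- if ("max_dff" %in% names(records)) records$max_dff else NA_real_
  rt <- if ("reaction_time_min" %in% names(records)) records$reaction_time_min else NA_real_
  tibble::tibble(
    n_total = nrow(records),
    n_active = sum(active),
    percent_active = 100 * sum(active) / nrow(records),
    mean_dff = mean(dff, na.rm = TRUE),
    sem_dff = sem(dff),
    mean_reaction_time_min = if (all(is.na(rt))) NA_real_ else mean(rt, na.rm = TRUE),
    sem_reaction_time_min = sem(rt)
  )
}

#' Generate a synthetic somatostatin-imaging cohort
#'
#' Emulates the disinhibition experiment: each cell is a 15-minute, 2 Hz ROI
#' trace; responders start bursting at a lognormal latency after the 1-minute
#' bath arrival, non-responders stay silent, and a configurable fraction is
#' spontaneously active before arrival. Ground truth retains the planted
#' labels and latencies.
#'
#' @param n_cells Cohort size.
#' @param responder_fraction Fraction of non-spontaneous cells that respond.
#' @param spontaneous_fraction Fraction of cells with pre-arrival activity.
#' @param latency_mean_min,latency_sd_min Reaction-time distribution of
#'   responders, minutes.
#' @param burst_amp_dff Fractional dF/F amplitude of response transients.
#' @param duration_s,drug_arrival_s,sample_rate Recording geometry.
#' @param noise_sd Fractional fluorescence noise.
#' @param seed Integer seed.
#' @return A list with `records` (per-cell analysis tibble from
#'   [analyze_calcium_cell()]), `traces` and `truth` (planted labels and
#'   latencies).
#' @export
gen_calcium_cohort <- function(n_cells = 74, responder_fraction = 0.338,
                               spontaneous_fraction = 0,
                               latency_mean_min = 5.8, latency_sd_min = 0.8,
                               burst_amp_dff = 0.15,
                               duration_s = 900, drug_arrival_s = 60,
                               sample_rate = 2, noise_sd = 0.003, seed = 1L) {
  truth <- withr::with_seed(seed, {
    spont <- stats::runif(n_cells) < spontaneous_fraction
    resp <- !spont & stats::runif(n_cells) < responder_fraction
    lat <- ifelse(
      resp,
      pmax(0.5, stats::rnorm(n_cells, latency_mean_min, latency_sd_min)),
      NA_real_
    )
    tibble::tibble(cell = seq_len(n_cells), spontaneous = spont,
                   responder = resp, latency_min = lat)
  })
  md <- list(drug_epochs = list(list(name = "somatostatin",
                                     start_s = drug_arrival_s,
                                     end_s = duration_s)))
  traces <- purrr::map(seq_len(n_cells), function(i) {
    spikes <- numeric(0)
    if (truth$spontaneous[i]) {
      spikes <- c(spikes, withr::with_seed(seed + 7L * i, stats::runif(3, 5, drug_arrival_s - 5)))
    }
    if (truth$responder[i]) {
      onset <- drug_arrival_s + truth$latency_min[i] * 60
      # repeated bursting: a few transients after onset
      burst_times <- onset + c(0, 40, 80, 150)
      spikes <- c(spikes, burst_times[burst_times < duration_s - 2])
    }
    gen_gcamp_trace(sort(spikes), duration = duration_s, sample_rate = sample_rate,
                    unit_amplitude = burst_amp_dff, noise_sd = noise_sd,
                    metadata = md, seed = seed + 13L * i)
  })
  records <- purrr::map_dfr(traces, analyze_calcium_cell, condition = "somatostatin",
                            drug_arrival_s = drug_arrival_s)
  records$cell <- seq_len(n_cells)
  list(records = records, traces = traces, truth = truth)
}
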