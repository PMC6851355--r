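#' Robust noise estimate for a current trace
#'
#' Noise is estimated as 1.4826 times the median absolute deviation of the
#' high-pass residual (trace minus a running-median baseline), which is
#' insensitive to contamination by synaptic events.
#'
#' @param trace A current trace tibble, pA.
#' @param baseline_window_ms Running-median window, ms.
#' @return Noise standard deviation, pA.
#' @export
estimate_noise_sd <- function(trace, baseline_window_ms = 200) {
  assert_trace(trace)
  stats::mad(trace$value - running_baseline(trace$value,
                                            trace_sample_rate(trace),
                                            baseline_window_ms))
}

running_baseline <- function(values, sample_rate, window_ms) {
  k <- round(window_ms / 1000 * sample_rate)
  k <- max(3L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= length(values)) return(rep(stats::median(values), length(values)))
  stats::runmed(values, k, endrule = "median")
}

# Two-pass baseline: a first-pass running median flags event-occupied samples;
# the baseline is then a running median over event-free samples only,
# interpolated across the masked gaps. This keeps long decay tails out of the
# baseline, which would otherwise ride up under them and steepen fitted decays.
masked_baseline <- function(values, sample_rate, window_ms, iterations = 2L) {
  n <- length(values)
  kbox <- max(1L, as.integer(round(sample_rate * 1e-3)))
  grow <- max(1L, as.integer(round(sample_rate * 2e-3)))
  k <- round(window_ms / 1000 * sample_rate)
  k <- max(3L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  baseline <- running_baseline(values, sample_rate, window_ms)
  for (it in seq_len(iterations)) {
    resid <- values - baseline
    sm <- if (kbox > 1L) {
      as.numeric(stats::filter(resid, rep(1 / kbox, kbox), sides = 2))
    } else resid
    sm[is.na(sm)] <- 0
    s <- stats::mad(sm)
    # noiseless trace: mask any deviation at all
    mask <- if (s == 0) abs(sm) > 1e-12 else
      # tighter on the refined pass: the first mask must tolerate the
      # event-contaminated running median, the second need not
      abs(sm) > (if (it == 1L) 1.25 else 0.75) * s
    mask <- as.numeric(stats::filter(mask, rep(1, 2 * grow + 1), sides = 2))
    mask[is.na(mask)] <- 0
    good <- which(mask == 0)
    if (length(good) < 10L) return(baseline)
    bm <- if (k >= length(good)) {
      rep(stats::median(values[good]), length(good))
    } else {
      stats::runmed(values[good], k, endrule = "median")
    }
    baseline <- stats::approx(good, bm, xout = seq_len(n), rule = 2)$y
  }
  baseline
}

#' Detect postsynaptic-current events in a voltage-clamp trace
#'
#' Events are local extrema of the baseline-subtracted trace exceeding
#' `threshold_k` times the robust noise standard deviation, separated by at
#' least `min_separation_ms` (the larger event wins a conflict). The baseline
#' is a running median, so detection is invariant under constant baseline
#' shifts and insensitive to slow drift (including tonic-current steps).
#' Onset is the last sub-20%-of-peak sample before the peak.
#'
#' @param trace A current trace tibble, pA.
#' @param polarity `"outward"` (positive events; IPSCs at a 0 mV hold) or
#'   `"inward"` (negative events; EPSCs at -70 mV).
#' @param threshold_k Detection threshold in multiples of the noise sd.
#' @param min_separation_ms Minimum peak separation, ms.
#' @param baseline_window_ms Running-median baseline window, ms.
#' @return An event tibble with columns `onset`, `peak_time` (s), `amplitude`
#'   (signed, pA), `tau_decay` (ms, `NA` until fitted), `fit_rss`, `class`
#'   (`"unclassified"` until classified); attributes `polarity`,
#'   `trace_duration`, `noise_sd`.
#' @examples
#' sim <- gen_vc_trace(vc_params(duration = 5,
#'   event_rate = c(ampa = 0, glycine = 4, gaba = 0, mixed = 0)))
#' ev <- detect_events(sim$trace, "outward")
#' @export
detect_events <- function(trace, polarity = c("outward", "inward"),
                          threshold_k = 4, min_separation_ms = 5,
                          baseline_window_ms = 200) {
  assert_trace(trace)
  polarity <- match.arg(polarity)
  sr <- trace_sample_rate(trace)
  sgn <- if (polarity == "outward") 1 else -1
  resid <- sgn * (trace$value - running_baseline(trace$value, sr, baseline_window_ms))
  noise_sd <- stats::mad(resid)

  # short boxcar (0.5 ms) for thresholding only; amplitudes are read from the
  # unsmoothed residual
  kbox <- max(1L, as.integer(round(sr * 5e-4)))
  sm <- if (kbox > 1L) {
    as.numeric(stats::filter(resid, rep(1 / kbox, kbox), sides = 2))
  } else resid
  sm[is.na(sm)] <- 0
  # threshold in units of the raw robust noise sd (the smoothing only guards
  # run-splitting; an event peak passes it nearly unattenuated)
  thr <- threshold_k * noise_sd

  above <- sm > thr
  peaks <- integer(0)
  if (any(above)) {
    d <- diff(c(FALSE, above, FALSE))
    starts <- which(d == 1L)
    ends <- which(d == -1L) - 1L
    cand <- purrr::map2_int(starts, ends, function(a, b) {
      a + which.max(sm[a:b]) - 1L
    })
    # chronological merge: a candidate on the decay tail of the previous kept
    # event must re-rise by at least the threshold above the minimum between
    # them (prominence), and respect the minimum separation
    min_gap <- min_separation_ms / 1000 * sr
    rise_min <- max(thr, .Machine$double.eps)
    # a tail can hold the signal up for at most ~0.5 s; beyond that a new
    # crossing is always a new event, so the prominence scan is bounded
    prom_win <- as.integer(0.5 * sr)
    kept <- integer(0)
    for (pk in cand) {
      if (length(kept) == 0L) {
        kept <- pk
        next
      }
      last <- kept[length(kept)]
      if (pk - last < min_gap) {
        if (sm[pk] > sm[last]) kept[length(kept)] <- pk
      } else if (pk - last > prom_win ||
                 sm[pk] - min(sm[max(last, pk - prom_win):pk]) >= rise_min) {
        kept <- c(kept, pk)
      }
    }
    # snap each smoothed peak to the unsmoothed local maximum for timing;
    # amplitudes are read from the smoothed residual, which avoids the
    # extreme-value bias of picking the largest raw noise sample
    half <- max(1L, kbox)
    peaks <- vapply(kept, function(pk) {
      a <- max(1L, pk - half); b <- min(length(resid), pk + half)
      a + which.max(resid[a:b]) - 1L
    }, integer(1))
    amp_at <- sm[kept]
  }

  onset_of <- function(pk) {
    lim <- 0.2 * resid[pk]
    i <- pk
    lo <- max(1L, pk - as.integer(0.05 * sr))  # search at most 50 ms back
    while (i > lo && resid[i - 1L] > lim) i <- i - 1L
    i
  }
  onsets <- vapply(peaks, onset_of, integer(1))

  if (length(peaks) == 0L) amp_at <- numeric(0)
  out <- tibble::tibble(
    onset = trace$time[onsets],
    peak_time = trace$time[peaks],
    amplitude = sgn * amp_at,
    tau_decay = NA_real_,
    fit_rss = NA_real_,
    class = rep("unclassified", length(peaks))
  )
  attr(out, "polarity") <- polarity
  attr(out, "trace_duration") <- trace_duration(trace)
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Fit single-exponential decays to detected events
#'
#' For each event, a single exponential `A * exp(-(t - t_peak)/tau)` is
#' least-squares fitted to the baseline-subtracted trace from the peak until
#' the signal first falls to `fit_window_fraction` of the peak, until
#' `5 * tau` of a data-driven initial guess, or until the next event's onset,
#' whichever comes first. When an earlier event's fitted tail overlaps the
#' window it is subtracted before fitting, so high-rate trains remain
#' fittable. Non-convergence (or a window shorter than 3 samples) leaves the
#' event `unclassified` with `tau_decay = NA` rather than raising an error.
#'
#' @param trace The trace the events were detected in.
#' @param events Event tibble from [detect_events()].
#' @param fit_window_fraction Fit from peak down to this fraction of the peak.
#' @param baseline_window_ms Running-median baseline window, ms.
#' @return The event tibble with `tau_decay` (ms), `amplitude` (refined, pA)
#'   and `fit_rss` filled in.
#' @export
fit_event_decay <- function(trace, events, fit_window_fraction = 0.1,
                            baseline_window_ms = 200) {
  assert_trace(trace)
  if (nrow(events) == 0L) return(events)
  sr <- trace_sample_rate(trace)
  sgn <- if (identical(attr(events, "polarity"), "inward")) -1 else 1
  resid <- sgn * (trace$value - masked_baseline(trace$value, sr, baseline_window_ms))
  n <- length(resid)
  # 1 ms boxcar copy: the fit-window and tau-guess crossings are read from the
  # smoothed residual so single noise samples cannot truncate the window
  kbox <- max(1L, as.integer(round(sr * 1e-3)))
  sm <- if (kbox > 1L) {
    as.numeric(stats::filter(resid, rep(1 / kbox, kbox), sides = 2))
  } else resid
  sm[is.na(sm)] <- 0
  ord <- order(events$peak_time)
  taus <- events$tau_decay
  amps <- events$amplitude
  rsss <- events$fit_rss

  t0 <- trace$time[1]
  idx_of <- function(t) min(n, max(1L, as.integer(round((t - t0) * sr)) + 1L))
  prev_tail <- NULL  # list(start_idx, A, tau_samples)
  for (j in ord) {
    pk <- idx_of(events$peak_time[j])
    peak_val <- resid[pk]
    if (!is.null(prev_tail)) {
      off <- pk - prev_tail$start
      if (off > 0) peak_val <- peak_val - prev_tail$A * exp(-off / prev_tail$tau)
    }
    if (!is.finite(peak_val) || peak_val <= 0) next

    stop_i <- n
    nxt <- ord[match(j, ord) + 1L]
    if (!is.na(nxt)) stop_i <- min(stop_i, idx_of(events$onset[nxt]) - 1L)
    stop_i <- max(stop_i, pk + 2L)

    # data-driven initial guess: time for the smoothed residual to fall to 1/e
    lim_e <- peak_val / exp(1)
    i <- pk
    while (i < stop_i && sm[i] > lim_e) i <- i + 1L
    tau_guess <- max((i - pk) / sr * 1000, 2000 / sr)  # ms, at least 2 samples

    lim <- fit_window_fraction * peak_val
    end_frac <- pk
    while (end_frac < stop_i && sm[end_frac] > lim) end_frac <- end_frac + 1L
    end_i <- min(stop_i, pk + ceiling(5 * tau_guess / 1000 * sr), end_frac)
    if (end_i - pk + 1L < 3L) next

    idx <- pk:end_i
    y <- resid[idx]
    if (!is.null(prev_tail)) {
      off <- idx - prev_tail$start
      y <- y - ifelse(off > 0, prev_tail$A * exp(-off / prev_tail$tau), 0)
    }
    t_ms <- (idx - pk) / sr * 1000
    fit <- fit_single_exponential(t_ms, y, a0 = peak_val, tau0 = tau_guess)
    if (is.null(fit)) next
    taus[j] <- fit$tau
    amps[j] <- sgn * fit$A
    rsss[j] <- fit$rss
    prev_tail <- list(start = pk, A = fit$A, tau = fit$tau / 1000 * sr)
  }
  events$tau_decay <- taus
  events$amplitude <- amps
  events$fit_rss <- rsss
  events
}

# Levenberg-Marquardt single-exponential fit with a profiled-amplitude
# fallback: for fixed tau the least-squares amplitude is linear, so a 1-D
# optimize over log-tau cannot fail to converge.
fit_single_exponential <- function(t_ms, y, a0, tau0) {
  # beyond ~5x the window span a decay is indistinguishable from a constant
  tau_max <- 5 * max(t_ms)
  df <- data.frame(t = t_ms, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = df,
                      start = list(A = a0, tau = min(tau0, tau_max)),
                      lower = c(A = 0, tau = 1e-3),
                      upper = c(A = 10 * a0, tau = tau_max),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (cf[["tau"]] > 0 && cf[["A"]] > 0 && cf[["tau"]] < tau_max * 0.999) {
      return(list(A = cf[["A"]], tau = cf[["tau"]],
                  rss = sum(stats::resid(fit)^2)))
    }
  }
  # fallback: profile the amplitude (linear for fixed tau), optimize over
  # log-tau in 1-D; cannot fail to converge
  prof_rss <- function(log_tau) {
    e <- exp(-t_ms / exp(log_tau))
    A <- sum(y * e) / sum(e * e)
    sum((y - A * e)^2)
  }
  opt <- tryCatch(
    stats::optimize(prof_rss, interval = log(c(max(t_ms[2], 0.05) / 4, tau_max))),
    error = function(e) NULL
  )
  if (is.null(opt)) return(NULL)
  tau <- exp(opt$minimum)
  e <- exp(-t_ms / tau)
  A <- sum(y * e) / sum(e * e)
  if (!is.finite(A) || A <= 0 || tau >= tau_max * 0.999) return(NULL)
  list(A = A, tau = tau, rss = opt$objective)
}

#' Event frequency over an epoch
#'
#' @param events Event tibble.
#' @param epoch `(start_s, end_s)`.
#' @return Events per second (Hz), counting events whose onset falls in
#'   `[start, end)`.
#' @export
event_frequency <- function(events, epoch) {
  if (length(epoch) != 2L || epoch[2] <= epoch[1]) {
    stop("epoch must be (start_s, end_s) with positive length", call. = FALSE)
  }
  sum(events$onset >= epoch[1] & events$onset < epoch[2]) / (epoch[2] - epoch[1])
}
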