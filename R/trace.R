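#' Build a uniformly sampled recording trace
#'
#' A trace is a tibble with columns `time` (seconds) and `value`, carrying the
#' sampling rate, physical units and free-form metadata as attributes. All
#' analysis functions in the package accept these tibbles; if the attributes
#' have been stripped (e.g. by row filtering), the sampling rate is recovered
#' from the time column.
#'
#' @param values Numeric vector of samples (pA, mV or fluorescence a.u.).
#' @param sample_rate Sampling rate in Hz.
#' @param units One of `"pA"`, `"mV"`, `"au"`, `"dff_percent"`.
#' @param t0 Time of the first sample, seconds.
#' @param metadata Named list of annotations (e.g. `hold_voltage_mv`,
#'   `drug_epochs`).
#' @return A tibble of class `tone_trace` with columns `time`, `value`.
#' @examples
#' tr <- new_trace(rnorm(100), sample_rate = 100, units = "pA")
#' trace_sample_rate(tr)
#' @export
new_trace <- function(values, sample_rate, units = c("pA", "mV", "au", "dff_percent"),
                      t0 = 0, metadata = list()) {
  units <- match.arg(units)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    stop("trace values must be finite numerics", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a single positive number", call. = FALSE)
  }
  out <- tibble::tibble(
    time = t0 + (seq_along(values) - 1) / sample_rate,
    value = as.numeric(values)
  )
  attr(out, "sample_rate") <- sample_rate
  attr(out, "units") <- units
  attr(out, "t0") <- t0
  attr(out, "metadata") <- metadata
  class(out) <- c("tone_trace", class(out))
  out
}

#' @rdname new_trace
#' @param trace A trace tibble.
#' @export
trace_sample_rate <- function(trace) {
  sr <- attr(trace, "sample_rate")
  if (!is.null(sr)) return(sr)
  dt <- stats::median(diff(trace$time))
  if (!is.finite(dt) || dt <= 0) stop("cannot infer sample rate from trace", call. = FALSE)
  1 / dt
}

#' @rdname new_trace
#' @export
trace_units <- function(trace) {
  u <- attr(trace, "units")
  if (is.null(u)) NA_character_ else u
}

#' @rdname new_trace
#' @export
trace_metadata <- function(trace) {
  md <- attr(trace, "metadata")
  if (is.null(md)) list() else md
}

trace_duration <- function(trace) nrow(trace) / trace_sample_rate(trace)

assert_trace <- function(trace) {
  if (!is.data.frame(trace) || !all(c("time", "value") %in% names(trace)) ||
      nrow(trace) == 0L) {
    stop("expected a non-empty trace tibble with columns time, value", call. = FALSE)
  }
  invisible(trace)
}

epoch_index <- function(trace, epoch) {
  if (length(epoch) != 2L || epoch[2] <= epoch[1]) {
    stop("epoch must be (start_s, end_s) with end > start", call. = FALSE)
  }
  which(trace$time >= epoch[1] & trace$time < epoch[2])
}

#' Read and write traces as delimited text with a JSON sidecar
#'
#' The on-disk form is a two-column tab-separated file (`time_s`, `value`)
#' plus `<path>.json` holding `{units, sample_rate_hz, t0_s, metadata}`.
#' A write-then-read round trip preserves samples to at least 1e-9 and all
#' metadata.
#'
#' @param trace A trace tibble (see [new_trace()]).
#' @param path File path for the sample table; the sidecar is `<path>.json`.
#' @return `read_trace()` returns the trace; `write_trace()` returns `path`
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  assert_trace(trace)
  utils::write.table(
    data.frame(time_s = trace$time, value = trace$value),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  sidecar <- list(
    units = trace_units(trace),
    sample_rate_hz = trace_sample_rate(trace),
    t0_s = attr(trace, "t0") %||% trace$time[1],
    metadata = trace_metadata(trace)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing JSON sidecar: ", sidecar_path, call. = FALSE)
  }
  # no simplification: drug-epoch lists must survive as lists, not data frames
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = FALSE)
  for (field in c("units", "sample_rate_hz")) {
    if (is.null(sidecar[[field]])) {
      stop("malformed sidecar: missing field '", field, "'", call. = FALSE)
    }
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  new_trace(
    tab$value,
    sample_rate = sidecar$sample_rate_hz,
    units = sidecar$units,
    t0 = sidecar$t0_s %||% tab$time_s[1],
    metadata = if (is.null(sidecar$metadata)) list() else as.list(sidecar$metadata)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
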