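#' Construct an electrophysiology trace
#'
#' A trace is a uniformly sampled time series stored as a tibble with columns
#' `time_ms` and `value`, carrying its sampling interval, signal kind and
#' units as attributes. Voltage traces are in mV, current traces in pA; time
#' is always milliseconds.
#'
#' @param value Numeric vector of samples.
#' @param dt_ms Sampling interval in ms (e.g. 0.01 for 100 kHz).
#' @param kind `"voltage"` or `"current"`.
#' @param units `"mV"` for voltage, `"pA"` for current. Defaults to the unit
#'   implied by `kind`.
#' @param t0_ms Time of the first sample relative to protocol start (ms).
#'
#' @return A tibble of class `ephys_trace` with columns `time_ms`, `value`.
#' @examples
#' tr <- new_trace(sin(seq(0, 2 * pi, length.out = 100)), dt_ms = 0.01, kind = "voltage")
#' trace_dt(tr)
#' @export
new_trace <- function(value, dt_ms, kind = c("voltage", "current"),
                      units = NULL, t0_ms = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(value) || length(value) == 0L) {
    stop("`value` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(dt_ms) || length(dt_ms) != 1L || dt_ms <= 0) {
    stop("`dt_ms` must be a single positive number", call. = FALSE)
  }
  if (is.null(units)) units <- if (kind == "voltage") "mV" else "pA"
  expected <- if (kind == "voltage") "mV" else "pA"
  if (!identical(units, expected)) {
    stop(sprintf("units `%s` inconsistent with kind `%s` (expected `%s`)",
                 units, kind, expected), call. = FALSE)
  }
  out <- tibble::tibble(
    time_ms = t0_ms + dt_ms * (seq_along(value) - 1L),
    value = as.numeric(value)
  )
  structure(out,
            class = c("ephys_trace", class(out)),
            dt_ms = dt_ms, kind = kind, units = units, t0_ms = t0_ms,
            ljp_corrected = FALSE)
}

#' @rdname new_trace
#' @param x Object to test or query.
#' @export
is_trace <- function(x) inherits(x, "ephys_trace")

#' @rdname new_trace
#' @export
trace_dt <- function(x) attr(x, "dt_ms")

#' @rdname new_trace
#' @export
trace_kind <- function(x) attr(x, "kind")

assert_trace <- function(x, kind = NULL, arg = deparse(substitute(x))) {
  if (!is_trace(x)) stop(sprintf("`%s` must be an ephys_trace", arg), call. = FALSE)
  if (!is.null(kind) && trace_kind(x) != kind) {
    stop(sprintf("`%s` must be a %s trace", arg, kind), call. = FALSE)
  }
  invisible(x)
}

# rebuild a trace from an existing one with new samples, keeping metadata
trace_like <- function(template, value) {
  out <- new_trace(value,
                   dt_ms = attr(template, "dt_ms"),
                   kind = attr(template, "kind"),
                   units = attr(template, "units"),
                   t0_ms = attr(template, "t0_ms"))
  attr(out, "ljp_corrected") <- attr(template, "ljp_corrected")
  out
}

#' Write / read a trace as two-column delimited text with a JSON sidecar
#'
#' The text file holds `time_ms` and `value`; the sidecar (`<path>.json`)
#' records units, kind, sampling rate and any extra metadata so the trace can
#' be reconstructed exactly.
#'
#' @param trace An `ephys_trace`.
#' @param path Output path for the delimited file.
#' @param metadata Named list of extra fields to store in the sidecar.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   the reconstructed `ephys_trace` with the sidecar's extra metadata in the
#'   `"metadata"` attribute.
#' @export
write_trace <- function(trace, path, metadata = list()) {
  assert_trace(trace)
  readr::write_tsv(tibble::as_tibble(trace)[, c("time_ms", "value")], path)
  side <- c(list(
    kind = trace_kind(trace),
    units = attr(trace, "units"),
    dt_ms = trace_dt(trace),
    t0_ms = attr(trace, "t0_ms"),
    sampling_rate_khz = 1 / trace_dt(trace),
    ljp_corrected = attr(trace, "ljp_corrected")
  ), metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- new_trace(tab$value, dt_ms = side$dt_ms, kind = side$kind,
                   t0_ms = side$t0_ms %||% 0)
  attr(out, "ljp_corrected") <- isTRUE(side$ljp_corrected)
  attr(out, "metadata") <- side[setdiff(names(side), c(
    "kind", "units", "dt_ms", "t0_ms", "sampling_rate_khz", "ljp_corrected"))]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
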