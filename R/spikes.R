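#' Spike-analysis configuration
#'
#' Holds the constants of the spike-feature definitions: the dV/dt fraction
#' defining threshold (5% of the maximal dV/dt), the liquid junction
#' potential correction (+10 mV for a K-gluconate internal), peak detection
#' settings and the offline filter cutoff.
#'
#' @param dvdt_threshold_fraction Fraction of the maximal dV/dt defining
#'   spike threshold; strictly between 0 and 1.
#' @param ljp_mv Liquid junction potential (mV); recorded voltages are
#'   corrected by subtracting this amount.
#' @param min_peak_prominence_mv Minimum peak prominence for detection (mV).
#' @param refractory_ms Minimum separation between detected peaks (ms).
#' @param filter_cutoff_khz Offline low-pass cutoff the trace is assumed to
#'   carry (kHz); used by [filter_trace()] when preparing raw traces.
#' @return A list of class `spike_config`.
#' @export
spike_config <- function(dvdt_threshold_fraction = 0.05, ljp_mv = 10,
                         min_peak_prominence_mv = 20, refractory_ms = 2,
                         filter_cutoff_khz = 5) {
  if (dvdt_threshold_fraction <= 0 || dvdt_threshold_fraction >= 1) {
    stop("`dvdt_threshold_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (ljp_mv == 0) warning("ljp_mv = 0: no junction-potential correction will be applied")
  structure(list(dvdt_threshold_fraction = dvdt_threshold_fraction,
                 ljp_mv = ljp_mv,
                 min_peak_prominence_mv = min_peak_prominence_mv,
                 refractory_ms = refractory_ms,
                 filter_cutoff_khz = filter_cutoff_khz),
            class = "spike_config")
}

#' Correct a voltage trace for the liquid junction potential
#'
#' Shifts every sample by `-ljp_mv`: the true membrane potential is more
#' negative than the pipette reading for a K-gluconate internal solution.
#' The trace carries a flag so the correction cannot be applied twice.
#'
#' @param trace A voltage `ephys_trace`.
#' @param cfg A [spike_config()]; `cfg$ljp_mv` is the correction magnitude.
#' @return The corrected trace with attribute `ljp_corrected = TRUE`.
#' @export
ljp_correct <- function(trace, cfg = spike_config()) {
  assert_trace(trace, kind = "voltage")
  if (isTRUE(attr(trace, "ljp_corrected"))) {
    stop("trace is already junction-potential corrected", call. = FALSE)
  }
  out <- trace_like(trace, trace$value - cfg$ljp_mv)
  attr(out, "ljp_corrected") <- TRUE
  out
}

#' Detect spikes in a current-clamp trace
#'
#' Finds local maxima with prominence at least `min_peak_prominence_mv`,
#' enforces the refractory separation (of two peaks closer than
#' `refractory_ms`, the taller survives), and cuts the trace into
#' non-overlapping windows, one spike each, bounded by the minima between
#' neighbouring peaks. The trace is assumed already low-pass filtered.
#'
#' @param trace A voltage `ephys_trace`.
#' @param cfg A [spike_config()].
#' @return A tibble with one row per spike: `spike`, `t_peak_ms`,
#'   `v_peak_mv`, `i_peak`, `i_start`, `i_end`, and a `window` list-column of
#'   `ephys_trace` windows. Empty (zero rows) when no spikes are found.
#' @export
detect_spikes <- function(trace, cfg = spike_config()) {
  assert_trace(trace, kind = "voltage")
  v <- trace$value
  n <- length(v)
  dt <- trace_dt(trace)
  empty <- tibble::tibble(spike = integer(), t_peak_ms = numeric(),
                          v_peak_mv = numeric(), i_peak = integer(),
                          i_start = integer(), i_end = integer(),
                          window = list())
  if (n < 3L) return(empty)

  d <- diff(v)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L # local maxima
  if (length(cand) == 0L) return(empty)

  # prominence: drop to the highest of the deepest minima on either side,
  # bounded by the nearest higher point (or trace edge)
  prom <- purrr::map_dbl(cand, function(i) {
    higher_l <- which(v[seq_len(i - 1L)] > v[i])
    lo <- if (length(higher_l)) max(higher_l) else 1L
    higher_r <- which(v[seq.int(i + 1L, n)] > v[i])
    hi <- if (length(higher_r)) i + min(higher_r) else n
    v[i] - max(min(v[lo:i]), min(v[i:hi]))
  })
  cand <- cand[prom >= cfg$min_peak_prominence_mv]
  if (length(cand) == 0L) return(empty)

  # refractory merge: greedy by height
  keep <- logical(length(cand))
  for (j in order(v[cand], decreasing = TRUE)) {
    if (!any(keep & abs(trace$time_ms[cand] - trace$time_ms[cand[j]]) < cfg$refractory_ms)) {
      keep[j] <- TRUE
    }
  }
  peaks <- sort(cand[keep])

  # window boundaries at the minima between neighbouring peaks
  bounds <- if (length(peaks) > 1L) {
    purrr::map_int(seq_len(length(peaks) - 1L), function(k) {
      rng <- peaks[k]:peaks[k + 1L]
      rng[which.min(v[rng])]
    })
  } else integer()
  starts <- c(1L, bounds)
  ends <- c(bounds, n)

  tibble::tibble(
    spike = seq_along(peaks),
    t_peak_ms = trace$time_ms[peaks],
    v_peak_mv = v[peaks],
    i_peak = peaks,
    i_start = starts,
    i_end = ends,
    window = purrr::map2(starts, ends, function(a, b) {
      w <- new_trace(v[a:b], dt_ms = dt, kind = "voltage",
                     t0_ms = trace$time_ms[a])
      attr(w, "ljp_corrected") <- attr(trace, "ljp_corrected")
      w
    })
  )
}

# central-difference dV/dt in mV/ms
dvdt_central <- function(window) {
  v <- window$value
  dt <- trace_dt(window)
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

#' Spike threshold from the dV/dt criterion
#'
#' Threshold is the earliest sample before the peak at which dV/dt reaches
#' the configured fraction (default 5%) of the maximal dV/dt in the window,
#' with dV/dt computed by central differences.
#'
#' @param window A single-spike voltage window (from [detect_spikes()]).
#' @param cfg A [spike_config()].
#' @return A list with `t_threshold_ms` and `v_threshold_mv`.
#' @export
spike_threshold <- function(window, cfg = spike_config()) {
  assert_trace(window, kind = "voltage")
  d <- dvdt_central(window)
  i_peak <- which.max(window$value)
  dmax <- max(d[seq_len(i_peak)])
  if (dmax <= 0) stop("no upstroke in window (max dV/dt <= 0)", call. = FALSE)
  crossed <- which(d[seq_len(i_peak)] >= cfg$dvdt_threshold_fraction * dmax)
  # earliest sample of the contiguous run of supra-criterion dV/dt ending at
  # the peak (earlier isolated noise crossings are not the upstroke)
  runs <- split(crossed, cumsum(c(1L, diff(crossed) != 1L)))
  i_thr <- min(runs[[length(runs)]])
  list(t_threshold_ms = window$time_ms[i_thr],
       v_threshold_mv = window$value[i_thr])
}

#' Spike half-width
#'
#' Width at half the distance between threshold (5% of maximal dV/dt) and
#' peak: the time between the first upward and the first subsequent downward
#' crossing of (v_threshold + v_peak)/2, with linear interpolation between
#' samples.
#'
#' @param window A single-spike voltage window.
#' @param cfg A [spike_config()].
#' @return Half-width in ms; `NA` (flagged via a warning) when the falling
#'   phase never crosses the half level inside the window.
#' @export
spike_half_width <- function(window, cfg = spike_config()) {
  assert_trace(window, kind = "voltage")
  thr <- spike_threshold(window, cfg)
  v <- window$value
  tt <- window$time_ms
  v_half <- (thr$v_threshold_mv + max(v)) / 2

  cross_t <- function(i) { # linear interpolation between samples i, i+1
    tt[i] + (v_half - v[i]) / (v[i + 1] - v[i]) * (tt[i + 1] - tt[i])
  }
  up <- which(v[-length(v)] < v_half & v[-1] >= v_half)
  if (length(up) == 0L) up <- which(v >= v_half)[1] - 1L # starts above? guard
  i_up <- up[1]
  t_up <- if (i_up >= 1L) cross_t(i_up) else tt[1]
  down <- which(v[-length(v)] >= v_half & v[-1] < v_half)
  down <- down[down > i_up]
  if (length(down) == 0L) {
    warning("no downward half-level crossing before window end; half-width missing")
    return(NA_real_)
  }
  cross_t(down[1]) - t_up
}

#' Per-spike amplitudes and their mean over a trace
#'
#' Amplitude is the difference between the peak and anti-peak membrane
#' potentials of each spike, the anti-peak being the minimum between that
#' peak and the next spike's threshold (or the window end for the last
#' spike). The mean over all spikes in the first `duration_ms` of the trace
#' is the per-cell summary.
#'
#' @param trace A voltage `ephys_trace` (already filtered).
#' @param cfg A [spike_config()].
#' @param duration_ms Analysis span from trace start (ms); default 10000
#'   (the standard 10 s trace).
#' @return A list with `mean_amplitude_mv` (NA when no spikes) and
#'   `per_spike`, a tibble with `spike`, `t_peak_ms`, `v_peak_mv`,
#'   `v_antipeak_mv`, `amplitude_mv`.
#' @export
trace_amplitude_stats <- function(trace, cfg = spike_config(),
                                  duration_ms = 10000) {
  assert_trace(trace, kind = "voltage")
  spikes <- detect_spikes(trace, cfg)
  spikes <- spikes[spikes$t_peak_ms <= trace$time_ms[1] + duration_ms, ]
  if (nrow(spikes) == 0L) {
    warning("no spikes detected; amplitude missing")
    return(list(mean_amplitude_mv = NA_real_,
                per_spike = tibble::tibble(spike = integer(),
                                           t_peak_ms = numeric(),
                                           v_peak_mv = numeric(),
                                           v_antipeak_mv = numeric(),
                                           amplitude_mv = numeric())))
  }
  v <- trace$value
  n_sp <- nrow(spikes)
  anti <- purrr::map_dbl(seq_len(n_sp), function(k) {
    from <- spikes$i_peak[k]
    to <- if (k < n_sp) {
      # up to the next spike's threshold crossing
      thr_next <- spike_threshold(spikes$window[[k + 1L]], cfg)
      which.min(abs(trace$time_ms - thr_next$t_threshold_ms))
    } else spikes$i_end[k]
    min(v[from:to])
  })
  per <- tibble::tibble(
    spike = spikes$spike, t_peak_ms = spikes$t_peak_ms,
    v_peak_mv = spikes$v_peak_mv, v_antipeak_mv = anti,
    amplitude_mv = spikes$v_peak_mv - anti
  )
  list(mean_amplitude_mv = mean(per$amplitude_mv), per_spike = per)
}

#' Mean half-width of the first n consecutive spikes
#'
#' The per-cell half-width summary: the mean over the first `n` (default 5)
#' consecutive detected spikes.
#'
#' @param trace A voltage `ephys_trace`.
#' @param cfg A [spike_config()].
#' @param n Number of consecutive spikes to average.
#' @return A list with `mean_halfwidth_ms` (NA when fewer than `n` spikes)
#'   and `per_spike`, a tibble of the individual half-widths.
#' @export
first_n_spike_halfwidths <- function(trace, cfg = spike_config(), n = 5) {
  assert_trace(trace, kind = "voltage")
  spikes <- detect_spikes(trace, cfg)
  if (nrow(spikes) < n) {
    warning(sprintf("only %d spikes detected (need %d); half-width missing",
                    nrow(spikes), n))
    return(list(mean_halfwidth_ms = NA_real_,
                per_spike = tibble::tibble(spike = integer(),
                                           half_width_ms = numeric())))
  }
  hw <- purrr::map_dbl(spikes$window[seq_len(n)], spike_half_width, cfg = cfg)
  list(mean_halfwidth_ms = mean(hw),
       per_spike = tibble::tibble(spike = seq_len(n), half_width_ms = hw))
}
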