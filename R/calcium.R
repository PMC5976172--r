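#' Detect a dendritic calcium spike in a current-step response
#'
#' A calcium spike is called when the voltage response exceeds the passive
#' (scaled ohmic) prediction by at least `min_amp_mv` for at least
#' `min_dur_ms` of contiguous time. Both criteria are package defaults
#' (20 mV, 2 ms) and configurable.
#'
#' @param response Voltage `ephys_trace` at the step of interest.
#' @param passive Congruent voltage `ephys_trace` predicting the passive
#'   response at the same injected current.
#' @param min_amp_mv Detection amplitude criterion (mV above passive).
#' @param min_dur_ms Minimum contiguous duration above criterion (ms).
#' @return A list of class `calcium_spike_call`: `present`, `onset_ms`
#'   (first crossing; NA when absent), `peak_amplitude_above_passive_mv`.
#' @export
detect_calcium_spike <- function(response, passive, min_amp_mv = 20,
                                 min_dur_ms = 2) {
  assert_trace(response, kind = "voltage")
  assert_trace(passive, kind = "voltage")
  if (nrow(response) != nrow(passive) ||
      !isTRUE(all.equal(trace_dt(response), trace_dt(passive)))) {
    stop("response and passive prediction are incongruent", call. = FALSE)
  }
  excess <- response$value - passive$value
  above <- excess >= min_amp_mv
  dt <- trace_dt(response)
  need <- ceiling(min_dur_ms / dt)

  runs <- rle(above)
  present <- any(runs$values & runs$lengths >= need)
  onset <- NA_real_
  if (present) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    hit <- which(runs$values & runs$lengths >= need)[1]
    onset <- response$time_ms[starts[hit]]
  }
  structure(list(present = present, onset_ms = onset,
                 peak_amplitude_above_passive_mv = max(excess)),
            class = "calcium_spike_call")
}

# passive prediction for current i_pa by ohmic scaling of a reference
# subthreshold response
scale_passive <- function(reference, i_ref_pa, i_pa, baseline_vm_mv) {
  trace_like(reference,
             baseline_vm_mv + (reference$value - baseline_vm_mv) * (i_pa / i_ref_pa))
}

#' Calcium-spike threshold current of a step family
#'
#' Scans the ascending current steps and reports the smallest injected
#' current whose response contains a calcium spike, using the smallest step
#' as the reference for the scaled-ohmic passive prediction. If a spike is
#' seen at some step but not at a larger one (noise), the smallest spiking
#' step is still reported and the result flagged non-monotonic.
#'
#' @param family A `current_step_family` (see [simulate_castep_family()]).
#' @param min_amp_mv,min_dur_ms Detection criteria, passed to
#'   [detect_calcium_spike()].
#' @return A list of class `ca_threshold`: `threshold_pa` (NA when no step
#'   spikes), `reached`, `non_monotonic`, and `calls`, a tibble of per-step
#'   detection results.
#' @export
threshold_current <- function(family, min_amp_mv = 20, min_dur_ms = 2) {
  if (!inherits(family, "current_step_family")) {
    stop("`family` must be a current_step_family", call. = FALSE)
  }
  if (nrow(family) < 2L) stop("need at least 2 steps", call. = FALSE)
  base_vm <- attr(family, "baseline_vm_mv")
  ref <- family$trace[[1]]
  i_ref <- family$step_pa[[1]]

  calls <- purrr::map2(family$step_pa, family$trace, function(i_pa, tr) {
    passive <- scale_passive(ref, i_ref, i_pa, base_vm)
    detect_calcium_spike(tr, passive, min_amp_mv, min_dur_ms)
  })
  spiking <- purrr::map_lgl(calls, "present")
  call_tab <- tibble::tibble(step_pa = family$step_pa, spike = spiking,
                             onset_ms = purrr::map_dbl(calls, "onset_ms"))
  if (!any(spiking)) {
    return(structure(list(threshold_pa = NA_real_, reached = FALSE,
                          non_monotonic = FALSE, calls = call_tab),
                     class = "ca_threshold"))
  }
  first <- which(spiking)[1]
  non_mono <- any(!spiking[seq(first, length(spiking))])
  structure(list(threshold_pa = family$step_pa[[first]], reached = TRUE,
                 non_monotonic = non_mono, calls = call_tab),
            class = "ca_threshold")
}

#' Windowed input resistance from a current-step family
#'
#' Slope of the least-squares line of steady-state membrane potential versus
#' injected current, restricted to steps whose steady state lies inside the
#' voltage window (default -80 to -75 mV) to minimise the influence of
#' active conductances. Steady state is the mean over the final 20% of the
#' step.
#'
#' @param family A `current_step_family`.
#' @param window_mv Length-2 voltage window (mV), default `c(-80, -75)`.
#' @param include_baseline Include the (0 pA, resting Vm) point when the
#'   baseline lies inside the window (default TRUE).
#' @return A list of class `rin_estimate`: `rin_mohm` (NA when fewer than 2
#'   in-window points), `n_points`, `points` (the I-V table used).
#' @export
input_resistance <- function(family, window_mv = c(-80, -75),
                             include_baseline = TRUE) {
  if (!inherits(family, "current_step_family")) {
    stop("`family` must be a current_step_family", call. = FALSE)
  }
  on_ms <- attr(family, "step_onset_ms")
  dur_ms <- attr(family, "step_duration_ms")
  ss <- purrr::map_dbl(family$trace, function(tr) {
    sel <- tr$time_ms >= on_ms + 0.8 * dur_ms & tr$time_ms <= on_ms + dur_ms
    mean(tr$value[sel])
  })
  iv <- tibble::tibble(i_pa = family$step_pa, v_mv = ss)
  if (include_baseline) {
    base_vm <- attr(family, "baseline_vm_mv")
    iv <- dplyr::bind_rows(tibble::tibble(i_pa = 0, v_mv = base_vm), iv)
  }
  inw <- iv$v_mv >= window_mv[[1]] & iv$v_mv <= window_mv[[2]]
  pts <- iv[inw, ]
  if (nrow(pts) < 2L) {
    warning("fewer than 2 steady-state points inside the voltage window; input resistance missing")
    return(structure(list(rin_mohm = NA_real_, n_points = nrow(pts), points = pts),
                     class = "rin_estimate"))
  }
  slope <- stats::coef(stats::lm(v_mv ~ i_pa, data = pts))[[2]] # mV/pA = GOhm
  structure(list(rin_mohm = slope * 1000, n_points = nrow(pts), points = pts),
            class = "rin_estimate")
}

#' Usability of a cell for calcium-spike analysis
#'
#' Firing cells are always usable. Non-firing cells (depolarization block is
#' common in the mutant at five weeks) are usable only when the recording
#' began more depolarized than -45 mV AND the membrane potential fell below
#' -55 mV on exposure to TTX + CdCl2 -- evidence the depolarized state is
#' channel-mediated rather than slicing injury. Inequalities are strict,
#' following the wording "more depolarized than -45 mV" / "more
#' hyperpolarized than -55 mV". A non-firing cell without the post-blocker
#' measurement is `pending`, never silently defaulted.
#'
#' @param firing Logical: does the cell fire spontaneously?
#' @param vm_baseline_mv Membrane potential at the start of recording (mV).
#' @param vm_after_blockers_mv Membrane potential after TTX + CdCl2 (mV);
#'   may be NA when not measured.
#' @return A tibble row of class `cell_usability`: `firing`,
#'   `vm_baseline_mv`, `vm_after_blockers_mv`, `verdict`
#'   (`"usable"`/`"excluded"`/`"pending"`), `reason`.
#' @export
classify_cell_usability <- function(firing, vm_baseline_mv,
                                    vm_after_blockers_mv = NA_real_) {
  stopifnot(is.logical(firing), length(firing) == 1L, !is.na(firing))
  if (firing) {
    verdict <- "usable"; reason <- "firing cell"
  } else if (!is.finite(vm_baseline_mv)) {
    verdict <- "pending"; reason <- "non-firing cell without baseline Vm"
  } else if (vm_baseline_mv <= -45) {
    verdict <- "excluded"
    reason <- "non-firing and not depolarized beyond -45 mV; likely slicing injury"
  } else if (!is.finite(vm_after_blockers_mv)) {
    verdict <- "pending"
    reason <- "non-firing depolarized cell awaiting TTX/CdCl2 response"
  } else if (vm_after_blockers_mv < -55) {
    verdict <- "usable"
    reason <- "depolarization block reversed below -55 mV by TTX/CdCl2"
  } else {
    verdict <- "excluded"
    reason <- "no hyperpolarization below -55 mV under TTX/CdCl2; likely slicing injury"
  }
  out <- tibble::tibble(firing = firing, vm_baseline_mv = vm_baseline_mv,
                        vm_after_blockers_mv = vm_after_blockers_mv,
                        verdict = verdict, reason = reason)
  class(out) <- c("cell_usability", class(out))
  out
}

#' @export
print.ca_threshold <- function(x, ...) {
  if (x$reached) {
    cat(sprintf("Calcium-spike threshold: %g pA%s\n", x$threshold_pa,
                if (x$non_monotonic) " (non-monotonic spike sequence)" else ""))
  } else {
    cat("Calcium-spike threshold: not reached within the step family\n")
  }
  invisible(x)
}
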