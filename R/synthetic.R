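#' Specification of a synthetic two-compartment cell
#'
#' Ground-truth circuit for the capacitative-transient simulator: somatic and
#' distal capacitances, access/coupling resistances, leak input resistance,
#' current noise and sweep count. Defaults describe a healthy Purkinje
#' neuron-sized cell that passes the 100 MOhm input-resistance QC.
#'
#' @param c1_pf Somatic + proximal capacitance (pF).
#' @param c2_pf Distal dendritic capacitance (pF).
#' @param r1_mohm Access + somatic internal resistance (MOhm).
#' @param r2_mohm Dendritic coupling resistance (MOhm).
#' @param r_input_mohm Leak input resistance (MOhm); >= 100 so the cell
#'   passes QC by default.
#' @param noise_sd_pa Gaussian current-noise SD per sample (pA).
#' @param n_sweeps Number of repeated sweeps.
#' @param seed Integer seed; the generator is a pure function of (spec, seed).
#' @return A list of class `sim_circuit_spec`.
#' @export
sim_circuit_spec <- function(c1_pf = 112.5, c2_pf = 500, r1_mohm = 20 / 3,
                             r2_mohm = 40 / 3, r_input_mohm = 150,
                             noise_sd_pa = 5, n_sweeps = 10, seed = 1L) {
  chk <- function(val, nm, min = 0, strict = TRUE) {
    bad <- !is.numeric(val) || length(val) != 1L || !is.finite(val) ||
      (if (strict) val <= min else val < min)
    if (bad) stop(sprintf("invalid `%s`: must be a single number %s %g",
                          nm, if (strict) ">" else ">=", min), call. = FALSE)
  }
  chk(c1_pf, "c1_pf"); chk(c2_pf, "c2_pf")
  chk(r1_mohm, "r1_mohm"); chk(r2_mohm, "r2_mohm")
  chk(r_input_mohm, "r_input_mohm")
  chk(noise_sd_pa, "noise_sd_pa", strict = FALSE)
  chk(n_sweeps, "n_sweeps", min = 1, strict = FALSE)
  structure(list(c1_pf = c1_pf, c2_pf = c2_pf, r1_mohm = r1_mohm,
                 r2_mohm = r2_mohm, r_input_mohm = r_input_mohm,
                 noise_sd_pa = noise_sd_pa, n_sweeps = as.integer(n_sweeps),
                 seed = as.integer(seed)),
            class = "sim_circuit_spec")
}

#' Simulate capacitative-transient sweeps from a known circuit
#'
#' Each sweep is the noiseless biexponential-plus-leak current the circuit
#' produces under the voltage step, I(t) = A1 e^(-t/tau1) + A2 e^(-t/tau2) +
#' delta_v / R_input, with (A1, tau1, A2, tau2) obtained from
#' [compartments_to_biexponential()], plus i.i.d. Gaussian noise.
#'
#' @param spec A [sim_circuit_spec()].
#' @param protocol A [voltage_step_protocol()].
#' @return A [new_sweep_set()]; attribute `ground_truth` holds the planted
#'   circuit and its biexponential coefficients.
#' @export
simulate_capacitance_sweeps <- function(spec, protocol = voltage_step_protocol()) {
  stopifnot(inherits(spec, "sim_circuit_spec"),
            inherits(protocol, "voltage_step_protocol"))
  truth <- compartments_to_biexponential(list(
    c1_pf = spec$c1_pf, c2_pf = spec$c2_pf, r1_mohm = spec$r1_mohm,
    r2_mohm = spec$r2_mohm, delta_v_mv = protocol$delta_v_mv))
  dt <- protocol$dt_ms
  step_end <- protocol$step_onset_ms + protocol$step_duration_ms
  time <- seq(0, step_end + 50, by = dt) # 50 ms past step end: off-relaxation
  ts <- time - protocol$step_onset_ms # time from step onset
  in_step <- ts >= 0 & time <= step_end
  post <- time > step_end
  leak <- protocol$delta_v_mv / (spec$r_input_mohm / 1000) # pA
  clean <- numeric(length(time))
  clean[in_step] <- truth$a1 * exp(-ts[in_step] / truth$tau1) +
    truth$a2 * exp(-ts[in_step] / truth$tau2) + leak
  tp <- time[post] - step_end # opposite transient as the cell discharges
  clean[post] <- -truth$a1 * exp(-tp / truth$tau1) -
    truth$a2 * exp(-tp / truth$tau2)

  traces <- with_local_seed(spec$seed, {
    purrr::map(seq_len(spec$n_sweeps), function(i) {
      noisy <- clean + stats::rnorm(length(clean), sd = spec$noise_sd_pa)
      new_trace(noisy, dt_ms = dt, kind = "current")
    })
  })
  out <- new_sweep_set(traces, protocol)
  attr(out, "ground_truth") <- list(circuit = spec, biexp = truth, leak_pa = leak)
  out
}

#' Specification of a synthetic bAP attenuation cohort
#'
#' One recording per cell at a known soma-to-patch distance, with amplitude
#' decaying and half-width growing exponentially with distance. Defaults
#' follow the wild-type five-week best fit (A = 72.86 mV, b = 0.0376 per um)
#' with 2 mV amplitude noise over twelve cells spanning 10-120 um.
#'
#' @param a0_mv Amplitude at the soma (mV).
#' @param b_amp Amplitude decay rate (per um); >= 0.
#' @param hw0_ms Half-width at the soma (ms).
#' @param b_hw Half-width growth rate (per um); >= 0.
#' @param distances_um Soma-to-patch distances (um), one cell each.
#' @param noise_sd_amp_mv,noise_sd_hw_ms Gaussian noise SDs.
#' @param seed Integer seed.
#' @return A list of class `sim_bap_spec`.
#' @export
sim_bap_spec <- function(a0_mv = 72.86, b_amp = 0.0376, hw0_ms = 0.35,
                         b_hw = 0.004, distances_um = seq(10, 120, by = 10),
                         noise_sd_amp_mv = 2, noise_sd_hw_ms = 0.02,
                         seed = 1L) {
  if (a0_mv <= 0) stop("invalid `a0_mv`: must be > 0", call. = FALSE)
  if (b_amp < 0) stop("invalid `b_amp`: must be >= 0", call. = FALSE)
  if (b_hw < 0) stop("invalid `b_hw`: must be >= 0", call. = FALSE)
  if (any(distances_um < 0)) stop("invalid `distances_um`: must be >= 0", call. = FALSE)
  if (length(unique(distances_um)) < 2L) {
    stop("need at least 2 distinct distances (fit would be undetermined)", call. = FALSE)
  }
  structure(list(a0_mv = a0_mv, b_amp = b_amp, hw0_ms = hw0_ms, b_hw = b_hw,
                 distances_um = distances_um,
                 noise_sd_amp_mv = noise_sd_amp_mv,
                 noise_sd_hw_ms = noise_sd_hw_ms, seed = as.integer(seed)),
            class = "sim_bap_spec")
}

#' Simulate a per-cell bAP attenuation dataset
#'
#' @param spec A [sim_bap_spec()].
#' @param group Optional group label attached to every record.
#' @return A tibble with columns `cell_id`, `group`, `distance_um`,
#'   `amplitude_mv`, `halfwidth_ms`; amplitudes are clipped below at 0.
#' @export
simulate_bap_dataset <- function(spec, group = "synthetic") {
  stopifnot(inherits(spec, "sim_bap_spec"))
  x <- spec$distances_um
  with_local_seed(spec$seed, {
    amp <- spec$a0_mv * exp(-spec$b_amp * x) +
      stats::rnorm(length(x), sd = spec$noise_sd_amp_mv)
    hw <- spec$hw0_ms * exp(spec$b_hw * x) +
      stats::rnorm(length(x), sd = spec$noise_sd_hw_ms)
    tibble::tibble(
      cell_id = sprintf("%s_cell%02d", group, seq_along(x)),
      group = group,
      distance_um = x,
      amplitude_mv = pmax(amp, 0),
      halfwidth_ms = hw
    )
  })
}

#' Stereotyped spike waveform parameters
#'
#' Piecewise-linear spike used by [simulate_spike_trace()]: rise from
#' baseline to peak, fall to the anti-peak, linear recovery to baseline.
#' Triangular geometry makes every ground-truth feature exact.
#'
#' @param baseline_mv Resting potential between spikes (mV).
#' @param peak_mv Spike peak (mV); must exceed `baseline_mv`.
#' @param antipeak_mv Post-spike minimum (mV); at or below `baseline_mv`.
#' @param rise_ms,fall_ms,recover_ms Segment durations (ms).
#' @return A list of class `spike_shape` carrying the analytic ground-truth
#'   `amplitude_mv` and `half_width_ms`.
#' @export
spike_shape <- function(baseline_mv = -60, peak_mv = 10, antipeak_mv = -65,
                        rise_ms = 0.4, fall_ms = 0.4, recover_ms = 2) {
  if (peak_mv <= baseline_mv) stop("`peak_mv` must exceed `baseline_mv`", call. = FALSE)
  if (antipeak_mv > baseline_mv) stop("`antipeak_mv` must not exceed `baseline_mv`", call. = FALSE)
  half <- (baseline_mv + peak_mv) / 2 # threshold of a linear rise = its onset
  hw <- rise_ms * (peak_mv - half) / (peak_mv - baseline_mv) +
    fall_ms * (peak_mv - half) / (peak_mv - antipeak_mv)
  structure(list(baseline_mv = baseline_mv, peak_mv = peak_mv,
                 antipeak_mv = antipeak_mv, rise_ms = rise_ms,
                 fall_ms = fall_ms, recover_ms = recover_ms,
                 amplitude_mv = peak_mv - antipeak_mv, half_width_ms = hw),
            class = "spike_shape")
}

#' Simulate a current-clamp trace of stereotyped spikes
#'
#' Places `n_spikes` copies of the waveform at a regular rate and adds
#' Gaussian noise. Spike onsets are aligned to sample times so the planted
#' features are exact on the noiseless trace.
#'
#' @param shape A [spike_shape()].
#' @param n_spikes Number of spikes.
#' @param duration_ms Trace length (ms); must hold all spikes at `rate_hz`.
#' @param rate_hz Firing rate (Hz).
#' @param noise_sd_mv Gaussian voltage noise SD (mV).
#' @param seed Integer seed.
#' @param dt_ms Sampling interval (ms); default 0.01 (100 kHz).
#' @return A list with `trace` (an `ephys_trace`) and `truth` (a tibble of
#'   per-spike planted features: onset, peak time, peak, anti-peak,
#'   amplitude, half-width).
#' @export
simulate_spike_trace <- function(shape, n_spikes = 10, duration_ms = 1000,
                                 rate_hz = 20, noise_sd_mv = 0, seed = 1L,
                                 dt_ms = 0.01) {
  stopifnot(inherits(shape, "spike_shape"))
  isi <- 1000 / rate_hz
  width <- shape$rise_ms + shape$fall_ms + shape$recover_ms
  if (width >= isi) stop("spikes would overlap: waveform wider than inter-spike interval", call. = FALSE)
  if (duration_ms < n_spikes * isi) {
    stop("`duration_ms` too short for `n_spikes` at `rate_hz`", call. = FALSE)
  }
  n <- round(duration_ms / dt_ms) + 1L
  time <- dt_ms * (seq_len(n) - 1L)
  v <- rep(shape$baseline_mv, n)
  # snap onsets to the sample grid so planted geometry is exact
  onsets <- round((isi / 2 + isi * (seq_len(n_spikes) - 1L)) / dt_ms) * dt_ms
  for (on in onsets) {
    tl <- time - on
    seg1 <- tl >= 0 & tl < shape$rise_ms
    seg2 <- tl >= shape$rise_ms & tl < shape$rise_ms + shape$fall_ms
    seg3 <- tl >= shape$rise_ms + shape$fall_ms & tl < width
    v[seg1] <- shape$baseline_mv +
      (shape$peak_mv - shape$baseline_mv) * tl[seg1] / shape$rise_ms
    v[seg2] <- shape$peak_mv -
      (shape$peak_mv - shape$antipeak_mv) * (tl[seg2] - shape$rise_ms) / shape$fall_ms
    v[seg3] <- shape$antipeak_mv +
      (shape$baseline_mv - shape$antipeak_mv) *
      (tl[seg3] - shape$rise_ms - shape$fall_ms) / shape$recover_ms
  }
  # force vertices onto exact sample values where they land on the grid
  v <- with_local_seed(seed, v + stats::rnorm(n, sd = noise_sd_mv))
  truth <- tibble::tibble(
    spike = seq_len(n_spikes),
    t_onset_ms = onsets,
    t_peak_ms = onsets + shape$rise_ms,
    v_peak_mv = shape$peak_mv,
    v_antipeak_mv = shape$antipeak_mv,
    amplitude_mv = shape$amplitude_mv,
    half_width_ms = shape$half_width_ms
  )
  list(trace = new_trace(v, dt_ms = dt_ms, kind = "voltage"), truth = truth)
}

#' Specification of a synthetic calcium-spike current-step family
#'
#' Ascending somatic current steps with a planted all-or-none dendritic
#' calcium spike above a known threshold current, on top of a passive
#' membrane response consistent with the planted input resistance.
#'
#' @param threshold_pa Planted calcium-spike threshold current (pA); may lie
#'   above `max(step_levels_pa)` to model a never-spiking family.
#' @param r_input_mohm Planted input resistance (MOhm).
#' @param step_levels_pa Strictly increasing injected currents (pA).
#' @param step_duration_ms Step length (ms).
#' @param baseline_vm_mv Resting potential (mV).
#' @param tau_m_ms Passive membrane time constant (ms).
#' @param spike_amp_mv,spike_tau_ms Alpha-function bump amplitude (mV above
#'   passive) and time-to-peak (ms); defaults give a 30 mV, ~10 ms wide event.
#' @param spike_onset_frac Onset of the regenerative event as a fraction of
#'   the step duration.
#' @param noise_sd_mv Gaussian voltage noise SD (mV).
#' @param seed Integer seed.
#' @param dt_ms Sampling interval (ms).
#' @return A list of class `sim_ca_spec`.
#' @export
sim_ca_spec <- function(threshold_pa = 600, r_input_mohm = 100,
                        step_levels_pa = seq(100, 1000, by = 100),
                        step_duration_ms = 200, baseline_vm_mv = -80,
                        tau_m_ms = 15, spike_amp_mv = 30, spike_tau_ms = 4,
                        spike_onset_frac = 0.4, noise_sd_mv = 0, seed = 1L,
                        dt_ms = 0.02) {
  if (any(diff(step_levels_pa) <= 0)) {
    stop("invalid `step_levels_pa`: must be strictly increasing", call. = FALSE)
  }
  if (threshold_pa < min(step_levels_pa)) {
    stop("invalid `threshold_pa`: below the smallest step level", call. = FALSE)
  }
  if (r_input_mohm <= 0) stop("invalid `r_input_mohm`: must be > 0", call. = FALSE)
  structure(list(threshold_pa = threshold_pa, r_input_mohm = r_input_mohm,
                 step_levels_pa = step_levels_pa,
                 step_duration_ms = step_duration_ms,
                 baseline_vm_mv = baseline_vm_mv, tau_m_ms = tau_m_ms,
                 spike_amp_mv = spike_amp_mv, spike_tau_ms = spike_tau_ms,
                 spike_onset_frac = spike_onset_frac,
                 noise_sd_mv = noise_sd_mv, seed = as.integer(seed),
                 dt_ms = dt_ms),
            class = "sim_ca_spec")
}

#' Simulate a calcium-spike current-step family
#'
#' @param spec A [sim_ca_spec()].
#' @return A tibble of class `current_step_family` with columns `step_pa` and
#'   a `trace` list-column of voltage responses; attributes carry baseline
#'   Vm and the planted ground truth.
#' @export
simulate_castep_family <- function(spec) {
  stopifnot(inherits(spec, "sim_ca_spec"))
  dt <- spec$dt_ms
  pre <- 20 # ms of baseline before the step
  n <- round((pre + spec$step_duration_ms + 50) / dt) + 1L
  time <- dt * (seq_len(n) - 1L)
  ts <- time - pre
  in_step <- ts >= 0 & ts <= spec$step_duration_ms
  post <- ts > spec$step_duration_ms
  t_on <- spec$spike_onset_frac * spec$step_duration_ms

  traces <- with_local_seed(spec$seed, {
    purrr::map(spec$step_levels_pa, function(i_pa) {
      dv_ss <- i_pa * spec$r_input_mohm / 1000 # pA * MOhm -> mV
      v <- rep(spec$baseline_vm_mv, n)
      v[in_step] <- spec$baseline_vm_mv + dv_ss * (1 - exp(-ts[in_step] / spec$tau_m_ms))
      v_end <- spec$baseline_vm_mv + dv_ss *
        (1 - exp(-spec$step_duration_ms / spec$tau_m_ms))
      v[post] <- spec$baseline_vm_mv +
        (v_end - spec$baseline_vm_mv) *
        exp(-(ts[post] - spec$step_duration_ms) / spec$tau_m_ms)
      if (i_pa >= spec$threshold_pa) {
        ta <- ts - t_on
        bump <- ifelse(ta > 0 & in_step,
                       spec$spike_amp_mv * (ta / spec$spike_tau_ms) *
                         exp(1 - ta / spec$spike_tau_ms), 0)
        v <- v + bump
      }
      if (spec$noise_sd_mv > 0) v <- v + stats::rnorm(n, sd = spec$noise_sd_mv)
      new_trace(v, dt_ms = dt, kind = "voltage")
    })
  })
  out <- tibble::tibble(step_pa = spec$step_levels_pa, trace = traces)
  structure(out, class = c("current_step_family", class(out)),
            baseline_vm_mv = spec$baseline_vm_mv,
            step_onset_ms = pre, step_duration_ms = spec$step_duration_ms,
            ground_truth = spec)
}

#' Simulate a differential-expression gene table with planted channel hits
#'
#' Builds a gene table shaped like a cerebellar RNA-seq screen: gene symbol,
#' fold change (mutant relative to wild-type), p-value and q-value, with
#' exactly `n_signif_channels` of the channel genes planted as significant
#' (q <= 0.05) with log-uniform fold changes, and everything else near a
#' fold change of 1 with q > 0.05.
#'
#' @param n_genes Total genes in the table (channel genes included).
#' @param channel_list Tibble with columns `gene`, `subfamily` (see
#'   [channel_gene_list()]) or a character vector of symbols.
#' @param n_signif_channels Number of channel genes planted significant.
#' @param lfc_range Magnitude range of the planted |log2 fold change|.
#' @param n_signif_other Non-channel genes planted significant (default 0).
#' @param signif_channel_genes Optional character vector naming the exact
#'   channel genes to plant significant (overrides `n_signif_channels`);
#'   used to plant a persistent set across timepoints.
#' @param timepoint Label stored on the table (e.g. "5wk").
#' @param seed Integer seed.
#' @return A tibble of class `gene_table` with columns `gene`, `fold_change`,
#'   `p_value`, `q_value`, `is_channel`, `subfamily`; attribute `timepoint`.
#' @export
simulate_expression_table <- function(n_genes = 2000,
                                      channel_list = channel_gene_list(),
                                      n_signif_channels = 12,
                                      lfc_range = c(0.5, 2),
                                      n_signif_other = 0,
                                      signif_channel_genes = NULL,
                                      timepoint = "5wk", seed = 1L) {
  if (is.character(channel_list)) {
    channel_list <- tibble::tibble(gene = channel_list, subfamily = NA_character_)
  }
  n_chan <- nrow(channel_list)
  if (!is.null(signif_channel_genes)) {
    if (!all(signif_channel_genes %in% channel_list$gene)) {
      stop("`signif_channel_genes` must all be in `channel_list`", call. = FALSE)
    }
    n_signif_channels <- length(signif_channel_genes)
  }
  if (n_signif_channels > n_chan) {
    stop("`n_signif_channels` exceeds the channel list size", call. = FALSE)
  }
  if (n_chan > n_genes) stop("`n_genes` smaller than the channel list", call. = FALSE)

  with_local_seed(seed, {
    n_other <- n_genes - n_chan
    genes <- c(channel_list$gene,
               sprintf("Gm%05d", seq_len(n_other)))
    subfam <- c(channel_list$subfamily, rep(NA_character_, n_other))
    is_chan <- c(rep(TRUE, n_chan), rep(FALSE, n_other))

    sig_chan <- if (is.null(signif_channel_genes)) {
      sample(which(is_chan), n_signif_channels)
    } else {
      match(signif_channel_genes, genes)
    }
    sig <- c(sig_chan,
             if (n_signif_other > 0) sample(which(!is_chan), n_signif_other))
    lfc <- stats::rnorm(n_genes, 0, 0.1) # null genes hover near fold change 1
    lfc[sig] <- sample(c(-1, 1), length(sig), replace = TRUE) *
      stats::runif(length(sig), lfc_range[[1]], lfc_range[[2]])
    q <- stats::runif(n_genes, 0.0500001, 1)
    q[sig] <- stats::runif(length(sig), 1e-6, 0.05)
    p <- q * stats::runif(n_genes, 0.05, 1) # p never exceeds its BH q

    out <- tibble::tibble(
      gene = genes, fold_change = 2^lfc, p_value = p, q_value = q,
      is_channel = is_chan, subfamily = subfam
    )
    structure(out, class = c("gene_table", class(out)), timepoint = timepoint)
  })
}

# run code under a local RNG seed without touching the global stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}
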