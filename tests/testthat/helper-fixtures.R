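# shared fixture builders; everything is generated in code

# the worked two-compartment example: hand-inverted circuit whose transient
# has A1 = 1000 pA, tau1 = 0.5 ms, A2 = 500 pA, tau2 = 10 ms at dV = 10 mV
example_circuit <- function() {
  list(c1_pf = 112.5, c2_pf = 500, r1_mohm = 20 / 3, r2_mohm = 40 / 3,
       delta_v_mv = 10)
}

# symmetric triangular spike: -60 -> +40 mV in 1 ms, back in 1 ms;
# planted amplitude 100 mV, half-width 1.0 ms
triangle_shape <- function(rise_ms = 1, fall_ms = 1) {
  spike_shape(baseline_mv = -60, peak_mv = 40, antipeak_mv = -60,
              rise_ms = rise_ms, fall_ms = fall_ms, recover_ms = 2)
}

# a single triangular spike window as a bare trace (for threshold/half-width
# unit tests), vertices aligned to the sample grid
triangle_window <- function(baseline = -60, peak = 40, antipeak = -60,
                            rise_ms = 1, fall_ms = 1, dt_ms = 0.01,
                            pad_ms = 2) {
  t_peak <- pad_ms + rise_ms
  t_end <- t_peak + fall_ms + pad_ms
  tt <- seq(0, t_end, by = dt_ms)
  v <- rep(baseline, length(tt))
  up <- tt > pad_ms & tt <= t_peak
  v[up] <- baseline + (peak - baseline) * (tt[up] - pad_ms) / rise_ms
  dn <- tt > t_peak & tt <= t_peak + fall_ms
  v[dn] <- peak - (peak - antipeak) * (tt[dn] - t_peak) / fall_ms
  new_trace(v, dt_ms = dt_ms, kind = "voltage")
}

# two-group attenuation dataset simulated from the same or different curves
two_group_bap <- function(b1, b2, a0 = 75, sd = 2, n = 12, seed = 1) {
  d1 <- simulate_bap_dataset(
    sim_bap_spec(a0_mv = a0, b_amp = b1, noise_sd_amp_mv = sd,
                 distances_um = seq(10, 120, length.out = n), seed = seed),
    group = "g1")
  d2 <- simulate_bap_dataset(
    sim_bap_spec(a0_mv = a0, b_amp = b2, noise_sd_amp_mv = sd,
                 distances_um = seq(10, 120, length.out = n), seed = seed + 5000L),
    group = "g2")
  rbind(d1, d2)
}

max_rel_err <- function(cp, truth) {
  est <- c(cp$c1_pf, cp$c2_pf, cp$r1_mohm, cp$r2_mohm)
  max(abs(est - truth) / truth)
}
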