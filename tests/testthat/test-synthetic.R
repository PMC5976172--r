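test_that("generators are pure functions of (spec, seed)", {
  proto <- voltage_step_protocol(step_duration_ms = 50, dt_ms = 0.05)
  s <- sim_circuit_spec(noise_sd_pa = 5, n_sweeps = 3, seed = 7)
  expect_identical(simulate_capacitance_sweeps(s, proto)$i_pa,
                   simulate_capacitance_sweeps(s, proto)$i_pa)

  bs <- sim_bap_spec(seed = 7)
  expect_identical(simulate_bap_dataset(bs), simulate_bap_dataset(bs))

  sh <- triangle_shape()
  a <- simulate_spike_trace(sh, n_spikes = 3, duration_ms = 200,
                            noise_sd_mv = 1, seed = 7)
  b <- simulate_spike_trace(sh, n_spikes = 3, duration_ms = 200,
                            noise_sd_mv = 1, seed = 7)
  expect_identical(a$trace$value, b$trace$value)

  cs <- sim_ca_spec(noise_sd_mv = 0.5, seed = 7)
  f1 <- simulate_castep_family(cs)
  f2 <- simulate_castep_family(cs)
  expect_identical(purrr::map(f1$trace, "value"), purrr::map(f2$trace, "value"))

  expect_identical(simulate_expression_table(seed = 7),
                   simulate_expression_table(seed = 7))
})

test_that("zero-noise transient equals the analytic biexponential plus leak", {
  proto <- voltage_step_protocol(step_duration_ms = 100, dt_ms = 0.02)
  spec <- sim_circuit_spec(noise_sd_pa = 0, n_sweeps = 1, r_input_mohm = 200,
                           seed = 1)
  sw <- simulate_capacitance_sweeps(spec, proto)
  bx <- compartments_to_biexponential(c(example_circuit()[1:4],
                                        delta_v_mv = proto$delta_v_mv))
  ts <- sw$time_ms - proto$step_onset_ms
  in_step <- ts >= 0 & sw$time_ms <= proto$step_onset_ms + proto$step_duration_ms
  expected <- bx$a1 * exp(-ts[in_step] / bx$tau1) +
    bx$a2 * exp(-ts[in_step] / bx$tau2) + proto$delta_v_mv / 0.2
  expect_equal(sw$i_pa[in_step], expected, tolerance = 1e-12)
})

test_that("bAP generator matches its closed form and clips at zero", {
  flat <- sim_bap_spec(a0_mv = 75, b_amp = 0, noise_sd_amp_mv = 0,
                       noise_sd_hw_ms = 0)
  expect_true(all(simulate_bap_dataset(flat)$amplitude_mv == 75))

  spec <- sim_bap_spec(a0_mv = 75, b_amp = 0.0376, noise_sd_amp_mv = 0,
                       distances_um = seq(10, 120, by = 10))
  d <- simulate_bap_dataset(spec)
  expect_equal(d$amplitude_mv[d$distance_um == 120], 75 * exp(-4.512),
               tolerance = 1e-12)

  # strong noise at far distances cannot push amplitude negative
  noisy <- sim_bap_spec(a0_mv = 5, b_amp = 0.05, noise_sd_amp_mv = 20, seed = 3)
  expect_true(all(simulate_bap_dataset(noisy)$amplitude_mv >= 0))

  expect_error(sim_bap_spec(distances_um = c(50, 50)), "2 distinct")
})

test_that("spike-trace generator plants exact features and rejects overlap", {
  sim <- simulate_spike_trace(
    spike_shape(baseline_mv = -60, peak_mv = 10, antipeak_mv = -60,
                rise_ms = 1, fall_ms = 1),
    n_spikes = 10, duration_ms = 600, rate_hz = 20, noise_sd_mv = 0)
  expect_equal(nrow(sim$truth), 10)
  expect_equal(unique(sim$truth$amplitude_mv), 70)
  expect_equal(unique(sim$truth$half_width_ms), 1.0)
  expect_equal(max(sim$trace$value), 10)

  expect_error(
    simulate_spike_trace(spike_shape(recover_ms = 20), rate_hz = 100),
    "overlap")
})

test_that("calcium-step generator plants threshold and passive slope", {
  fam <- simulate_castep_family(sim_ca_spec(threshold_pa = 600, seed = 2))
  th <- threshold_current(fam)
  expect_true(th$reached)
  expect_equal(th$threshold_pa, 600)
  expect_equal(th$calls$spike, fam$step_pa >= 600)

  # planted r_input recovered from small steps inside the voltage window
  fam_rin <- simulate_castep_family(sim_ca_spec(
    threshold_pa = 1e6, r_input_mohm = 50,
    step_levels_pa = c(20, 40, 60, 80, 100)))
  expect_equal(input_resistance(fam_rin)$rin_mohm, 50, tolerance = 0.02)

  # threshold above the largest step: never reached
  fam_no <- simulate_castep_family(sim_ca_spec(threshold_pa = 2000))
  expect_false(threshold_current(fam_no)$reached)
  expect_true(is.na(threshold_current(fam_no)$threshold_pa))
})

test_that("expression-table generator plants exact counts and the gene universe", {
  tb <- simulate_expression_table(n_genes = 1000, n_signif_channels = 12,
                                  seed = 9)
  expect_equal(nrow(tb), 1000)
  sub <- subset_channels(tb)
  expect_equal(nrow(sub), 145)
  fl <- flag_significant(sub)
  expect_equal(sum(fl$significant), 12)
  # non-significant genes sit strictly above the cutoff
  expect_true(all(tb$q_value[tb$q_value > 0.05] > 0.05))
  expect_true(all(tb$fold_change > 0))
  # planting named genes overrides the count
  tb2 <- simulate_expression_table(
    n_genes = 500, n_signif_channels = 3,
    signif_channel_genes = c("Kcnma1", "Kcnd3", "Cacna1g"), seed = 9)
  fl2 <- flag_significant(subset_channels(tb2))
  expect_setequal(fl2$gene[fl2$significant], c("Kcnma1", "Kcnd3", "Cacna1g"))
})
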