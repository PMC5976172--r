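test_that("compartment equations reproduce the hand-worked example", {
  fit <- structure(list(a1 = 1000, tau1 = 0.5, a2 = 500, tau2 = 10,
                        baseline = 0, rss = 0, n = 100L, converged = TRUE,
                        ill_conditioned = FALSE, delta_v_mv = 10),
                   class = "biexp_fit")
  cp <- derive_compartments(fit)
  expect_equal(cp$c1_pf, 112.5)
  expect_equal(cp$c2_pf, 500)
  expect_equal(cp$r1_mohm, 20 / 3, tolerance = 1e-10)
  expect_equal(cp$r2_mohm, 40 / 3, tolerance = 1e-10)
  expect_false(cp$single_compartment)

  # and the forward map inverts it
  bx <- compartments_to_biexponential(example_circuit())
  expect_equal(bx$a1, 1000, tolerance = 1e-10)
  expect_equal(bx$tau1, 0.5, tolerance = 1e-10)
  expect_equal(bx$a2, 500, tolerance = 1e-10)
  expect_equal(bx$tau2, 10, tolerance = 1e-10)
})

test_that("a2 = 0 degenerates to a single compartment with R2 missing", {
  fit <- structure(list(a1 = 1000, tau1 = 0.5, a2 = 0, tau2 = 10,
                        baseline = 0, rss = 0, n = 100L, converged = TRUE,
                        ill_conditioned = FALSE, delta_v_mv = 10),
                   class = "biexp_fit")
  cp <- derive_compartments(fit)
  expect_equal(cp$c2_pf, 0)
  expect_true(is.na(cp$r2_mohm))
  expect_true(cp$single_compartment)
})

test_that("round trip derive ∘ forward is the identity over random circuits", {
  set.seed(42)
  for (i in 1:200) {
    p <- list(c1_pf = runif(1, 20, 300), c2_pf = runif(1, 50, 1000),
              r1_mohm = runif(1, 2, 30), r2_mohm = runif(1, 2, 60),
              delta_v_mv = sample(c(-10, 10, 5, -20), 1))
    bx <- compartments_to_biexponential(p)
    cp <- derive_compartments(bx)
    rel <- abs(c(cp$c1_pf, cp$c2_pf, cp$r1_mohm, cp$r2_mohm) -
               c(p$c1_pf, p$c2_pf, p$r1_mohm, p$r2_mohm)) /
      c(p$c1_pf, p$c2_pf, p$r1_mohm, p$r2_mohm)
    expect_lt(max(rel), 1e-10)
  }
})

test_that("forward map rejects non-positive circuits and a2 vanishes for huge R2", {
  p <- example_circuit()
  p$c1_pf <- -1
  expect_error(compartments_to_biexponential(p), "positive")
  p <- example_circuit()
  p$r2_mohm <- 1e12
  expect_lt(compartments_to_biexponential(p)$a2, 1e-5)
})

test_that("sweep averaging and leak correction behave as identities", {
  proto <- voltage_step_protocol(step_duration_ms = 200, dt_ms = 0.05)
  spec <- sim_circuit_spec(noise_sd_pa = 0, n_sweeps = 10, r_input_mohm = 150,
                           seed = 1)
  sw <- simulate_capacitance_sweeps(spec, proto)
  tr <- preprocess_transient(sw, r_input_mohm = 150, filter_cutoff_khz = NULL)
  # ten identical noiseless sweeps average to one sweep minus its leak term
  one <- simulate_capacitance_sweeps(
    sim_circuit_spec(noise_sd_pa = 0, n_sweeps = 1, r_input_mohm = 150, seed = 1),
    proto)
  leak <- proto$delta_v_mv / (150 / 1000)
  in_step <- one$time_ms >= proto$step_onset_ms &
    one$time_ms <= proto$step_onset_ms + proto$step_duration_ms
  expect_equal(tr$value[in_step], one$i_pa[in_step] - leak, tolerance = 1e-12)

  # a leak-only cell corrects to ~0 everywhere inside the step
  leak_only <- sim_circuit_spec(c1_pf = 1e-6, c2_pf = 1e-6, noise_sd_pa = 0,
                                n_sweeps = 1, r_input_mohm = 150, seed = 1)
  tr0 <- preprocess_transient(simulate_capacitance_sweeps(leak_only, proto),
                              r_input_mohm = 150, filter_cutoff_khz = NULL)
  late <- tr0$time_ms > proto$step_onset_ms + 1
  expect_lt(max(abs(tr0$value[late & in_step])), 1e-6)
})

test_that("averaging n sweeps shrinks tail noise by sqrt(n)", {
  proto <- voltage_step_protocol(step_duration_ms = 500, dt_ms = 0.01)
  spec <- sim_circuit_spec(noise_sd_pa = 5, n_sweeps = 10, seed = 11)
  sw <- simulate_capacitance_sweeps(spec, proto)
  tr <- preprocess_transient(sw, r_input_mohm = 150, filter_cutoff_khz = NULL)
  # keep clear of the step-off edge, where zero-phase filtering rings
  tail_sel <- tr$time_ms > proto$step_onset_ms + 400 &
    tr$time_ms < proto$step_onset_ms + 498
  sd_tail <- sd(tr$value[tail_sel])
  expect_equal(sd_tail, 5 / sqrt(10), tolerance = 0.1)
  # filtering reduces it further
  trf <- preprocess_transient(sw, r_input_mohm = 150, filter_cutoff_khz = 5)
  expect_lt(sd(trf$value[tail_sel]), sd_tail)
})

test_that("noiseless simulate -> preprocess -> fit -> derive recovers the circuit", {
  truth <- c(112.5, 500, 20 / 3, 40 / 3)
  sw <- simulate_capacitance_sweeps(
    sim_circuit_spec(noise_sd_pa = 0, n_sweeps = 1, seed = 3))
  tr <- preprocess_transient(sw, r_input_mohm = 150, filter_cutoff_khz = NULL)
  fit <- fit_biexponential(tr)
  expect_true(fit$converged)
  # amplitudes carry the polarity of the (negative) step
  expect_lt(abs(abs(fit$a1) - 1000) / 1000, 1e-3)
  expect_lt(abs(fit$tau1 - 0.5) / 0.5, 1e-3)
  cp <- derive_compartments(fit)
  expect_lt(max_rel_err(cp, truth), 1e-3)
  # the 5 kHz zero-phase filter perturbs the fast component only mildly
  cpf <- derive_compartments(
    fit_biexponential(preprocess_transient(sw, r_input_mohm = 150)))
  expect_lt(max_rel_err(cpf, truth), 0.02)
})

test_that("single-exponential input yields a2 ~ 0 and c2 ~ 0 downstream", {
  # depolarising step so the constructed transient polarity matches
  proto <- voltage_step_protocol(v_step_mv = -70, step_duration_ms = 200,
                                 dt_ms = 0.02)
  tt <- seq(0, 220, by = 0.02)
  ts <- tt - proto$step_onset_ms
  y <- ifelse(ts >= 0 & tt <= 210, 1000 * exp(-ts / 0.5), 0)
  tr <- new_trace(y, dt_ms = 0.02, kind = "current")
  attr(tr, "protocol") <- proto
  fit <- fit_biexponential(tr, proto)
  expect_true(fit$converged)
  expect_lt(abs(fit$a2), 1)
  cp <- derive_compartments(fit)
  expect_lt(abs(cp$c2_pf), 1) # pF, against a 112.5 pF proximal compartment
})

test_that("pure-noise input is flagged rather than silently wrong", {
  proto <- voltage_step_protocol(step_duration_ms = 100, dt_ms = 0.02)
  set.seed(5)
  y <- rnorm(round(150 / 0.02) + 1, sd = 5)
  tr <- new_trace(y, dt_ms = 0.02, kind = "current")
  fit <- fit_biexponential(tr, proto, fit_window = c(10, 110))
  sel <- tr$time_ms >= 10 & tr$time_ms <= 110
  ok <- !fit$converged ||
    fit$rss > 0.5 * sum((y[sel] - mean(y[sel]))^2) # no real structure found
  expect_true(ok)
})

test_that("doubling the step doubles amplitudes but not the derived circuit", {
  circ <- example_circuit()
  b1 <- compartments_to_biexponential(circ)
  circ2 <- circ
  circ2$delta_v_mv <- 20
  b2 <- compartments_to_biexponential(circ2)
  expect_equal(b2$a1 / b1$a1, 2, tolerance = 1e-12)
  expect_equal(b2$a2 / b1$a2, 2, tolerance = 1e-12)
  cp1 <- derive_compartments(b1)
  cp2 <- derive_compartments(b2)
  expect_equal(cp1$c1_pf, cp2$c1_pf, tolerance = 1e-12)
  expect_equal(cp1$c2_pf, cp2$c2_pf, tolerance = 1e-12)
  expect_equal(cp1$r1_mohm, cp2$r1_mohm, tolerance = 1e-12)
  expect_equal(cp1$r2_mohm, cp2$r2_mohm, tolerance = 1e-12)
})

test_that("input-resistance QC excludes below 100 MOhm, strictly", {
  expect_equal(qc_cell(c(99.9, 100, 250)),
               c("exclude", "include", "include"))
})
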