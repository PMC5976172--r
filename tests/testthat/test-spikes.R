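cfg <- spike_config()

test_that("junction-potential correction shifts by -10 mV exactly once", {
  tr <- new_trace(rep(-40, 100), dt_ms = 0.01, kind = "voltage")
  out <- ljp_correct(tr, cfg)
  expect_true(all(out$value == -50))
  expect_error(ljp_correct(out, cfg), "already")
  # zero correction is the identity (and warns at config time)
  expect_warning(cfg0 <- spike_config(ljp_mv = 0), "ljp")
  expect_equal(ljp_correct(tr, cfg0)$value, tr$value)
})

test_that("spike detection finds planted spikes, none on flat traces", {
  sim <- simulate_spike_trace(triangle_shape(), n_spikes = 10,
                              duration_ms = 600, rate_hz = 20, noise_sd_mv = 0)
  sp <- detect_spikes(sim$trace, cfg)
  expect_equal(nrow(sp), 10)
  expect_equal(sp$t_peak_ms, sim$truth$t_peak_ms, tolerance = 1e-9)

  flat <- new_trace(rep(-60, 1000), dt_ms = 0.01, kind = "voltage")
  expect_equal(nrow(detect_spikes(flat, cfg)), 0)
})

test_that("peaks inside the refractory window are merged, taller wins", {
  dt <- 0.01
  tt <- seq(0, 10, by = dt)
  v <- rep(-60, length(tt))
  tri <- function(center, height) {
    w <- 0.3
    pmax(0, (1 - abs(tt - center) / w)) * (height + 60)
  }
  v <- v + tri(5, 40) + tri(6, 20) # 1 ms apart, second smaller
  tr <- new_trace(v, dt_ms = dt, kind = "voltage")
  sp <- detect_spikes(tr, spike_config(refractory_ms = 2))
  expect_equal(nrow(sp), 1)
  expect_equal(sp$t_peak_ms, 5, tolerance = dt)
  # with a short refractory both are kept
  expect_equal(nrow(detect_spikes(tr, spike_config(refractory_ms = 0.5))), 2)
})

test_that("threshold sits at the onset of a constant-slope rise", {
  w <- triangle_window()
  thr <- spike_threshold(w, cfg)
  expect_equal(thr$t_threshold_ms, 2, tolerance = 2 * trace_dt(w))
  expect_equal(thr$v_threshold_mv, -60, tolerance = 1)
})

test_that("threshold matches the analytic 5% point of a sigmoid upstroke", {
  dt <- 0.005
  k <- 5 # per ms
  t0 <- 10
  tt <- seq(0, 20, by = dt)
  v <- -60 + 100 / (1 + exp(-k * (tt - t0)))
  w <- new_trace(v, dt_ms = dt, kind = "voltage")
  thr <- spike_threshold(w, cfg)
  # dV/dt = 5% of max where u/(1+u)^2 = 1/80, earliest root u = (78+sqrt(6080))/2
  u <- (78 + sqrt(78^2 - 4)) / 2
  t_expect <- t0 - log(u) / k
  expect_equal(thr$t_threshold_ms, t_expect, tolerance = 2 * dt)
})

test_that("a monotone-decreasing window has no upstroke", {
  w <- new_trace(seq(0, -50, length.out = 200), dt_ms = 0.01, kind = "voltage")
  expect_error(spike_threshold(w, cfg), "upstroke")
})

test_that("half-width follows the crossing geometry of triangles", {
  expect_equal(spike_half_width(triangle_window(rise_ms = 1, fall_ms = 1), cfg),
               1.0, tolerance = 1e-6)
  # translation invariance
  w <- triangle_window()
  w_shift <- trace_like(w, w$value - 10)
  expect_equal(spike_half_width(w_shift, cfg), spike_half_width(w, cfg),
               tolerance = 1e-9)
  # asymmetric fall: 1 ms rise, 3 ms fall -> 0.5 + 1.5 = 2.0 ms
  expect_equal(spike_half_width(triangle_window(rise_ms = 1, fall_ms = 3), cfg),
               2.0, tolerance = 1e-6)
  # no downward crossing -> flagged missing
  dt <- 0.01
  v <- c(rep(-60, 100), seq(-60, 40, by = 1), rep(40, 100))
  w_up <- new_trace(v, dt_ms = dt, kind = "voltage")
  expect_warning(hw <- spike_half_width(w_up, cfg), "missing")
  expect_true(is.na(hw))
})

test_that("half-width is stable under resampling at twice the rate", {
  sh <- triangle_shape()
  s1 <- simulate_spike_trace(sh, n_spikes = 3, duration_ms = 200,
                             noise_sd_mv = 0, dt_ms = 0.02)
  s2 <- simulate_spike_trace(sh, n_spikes = 3, duration_ms = 200,
                             noise_sd_mv = 0, dt_ms = 0.01)
  h1 <- spike_half_width(detect_spikes(s1$trace, cfg)$window[[1]], cfg)
  h2 <- spike_half_width(detect_spikes(s2$trace, cfg)$window[[1]], cfg)
  expect_lt(abs(h1 - h2), 0.02)
})

test_that("per-trace amplitude is mean of peak-to-antipeak differences", {
  sim <- simulate_spike_trace(
    spike_shape(baseline_mv = -55, peak_mv = 10, antipeak_mv = -60,
                rise_ms = 0.5, fall_ms = 0.5),
    n_spikes = 8, duration_ms = 500, rate_hz = 20, noise_sd_mv = 0)
  st <- trace_amplitude_stats(sim$trace, cfg, duration_ms = 500)
  expect_equal(nrow(st$per_spike), 8)
  expect_equal(st$mean_amplitude_mv, 70, tolerance = 1e-6)
  expect_equal(st$per_spike$v_antipeak_mv, rep(-60, 8), tolerance = 1e-6)

  # mixed planted amplitudes average arithmetically: build three triangles
  dt <- 0.01
  tt <- seq(0, 30, by = dt)
  v <- rep(-60, length(tt))
  peaks <- c(0, 10, 20) # mV; antipeak -60 => amplitudes 60, 70, 80
  for (i in seq_along(peaks)) {
    c0 <- 5 + 10 * (i - 1)
    up <- tt > c0 - 1 & tt <= c0
    dn <- tt > c0 & tt <= c0 + 1
    v[up] <- -60 + (peaks[i] + 60) * (tt[up] - (c0 - 1))
    v[dn] <- peaks[i] - (peaks[i] + 60) * (tt[dn] - c0)
  }
  st2 <- trace_amplitude_stats(new_trace(v, dt_ms = dt, kind = "voltage"),
                               cfg, duration_ms = 30)
  expect_equal(st2$mean_amplitude_mv, 70, tolerance = 1e-6)

  flat <- new_trace(rep(-60, 2000), dt_ms = 0.01, kind = "voltage")
  expect_warning(st3 <- trace_amplitude_stats(flat, cfg, 20), "no spikes")
  expect_true(is.na(st3$mean_amplitude_mv))
})

test_that("five-spike half-width mean uses the first five spikes only", {
  sim <- simulate_spike_trace(triangle_shape(), n_spikes = 8,
                              duration_ms = 500, rate_hz = 20, noise_sd_mv = 0)
  hw <- first_n_spike_halfwidths(sim$trace, cfg, n = 5)
  expect_equal(nrow(hw$per_spike), 5)
  expect_equal(hw$mean_halfwidth_ms, 1.0, tolerance = 1e-6)

  sim3 <- simulate_spike_trace(triangle_shape(), n_spikes = 3,
                               duration_ms = 500, rate_hz = 20, noise_sd_mv = 0)
  expect_warning(out <- first_n_spike_halfwidths(sim3$trace, cfg, n = 5),
                 "half-width missing")
  expect_true(is.na(out$mean_halfwidth_ms))
})

test_that("voltage offset moves thresholds but not amplitude or half-width", {
  sim <- simulate_spike_trace(triangle_shape(), n_spikes = 5,
                              duration_ms = 300, rate_hz = 20, noise_sd_mv = 0)
  tr <- sim$trace
  tr10 <- trace_like(tr, tr$value + 7)
  sp <- detect_spikes(tr, cfg)
  sp10 <- detect_spikes(tr10, cfg)
  th <- spike_threshold(sp$window[[1]], cfg)
  th10 <- spike_threshold(sp10$window[[1]], cfg)
  expect_equal(th10$v_threshold_mv - th$v_threshold_mv, 7, tolerance = 1e-9)
  expect_equal(trace_amplitude_stats(tr10, cfg, 300)$mean_amplitude_mv,
               trace_amplitude_stats(tr, cfg, 300)$mean_amplitude_mv,
               tolerance = 1e-9)
  expect_equal(first_n_spike_halfwidths(tr10, cfg, 3)$mean_halfwidth_ms,
               first_n_spike_halfwidths(tr, cfg, 3)$mean_halfwidth_ms,
               tolerance = 1e-9)
})
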