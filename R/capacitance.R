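#' Voltage-step protocol for capacitative transient acquisition
#'
#' Describes the voltage-clamp step used to evoke the capacitative transient.
#' The standard protocol is a 1 second step to -90 mV from a holding
#' potential of -80 mV, digitised at 100 kHz.
#'
#' @param v_hold_mv Holding potential (mV).
#' @param v_step_mv Step potential (mV).
#' @param step_onset_ms Time of step onset from sweep start (ms).
#' @param step_duration_ms Step length (ms).
#' @param dt_ms Sampling interval (ms); 0.01 is 100 kHz.
#' @return A list of class `voltage_step_protocol`; `delta_v_mv` is
#'   `v_step_mv - v_hold_mv`.
#' @export
voltage_step_protocol <- function(v_hold_mv = -80, v_step_mv = -90,
                                  step_onset_ms = 10, step_duration_ms = 1000,
                                  dt_ms = 0.01) {
  delta_v <- v_step_mv - v_hold_mv
  if (delta_v == 0) stop("`v_step_mv` must differ from `v_hold_mv` (delta_v = 0)", call. = FALSE)
  if (step_duration_ms <= 0) stop("`step_duration_ms` must be positive", call. = FALSE)
  if (dt_ms <= 0) stop("`dt_ms` must be positive", call. = FALSE)
  structure(list(v_hold_mv = v_hold_mv, v_step_mv = v_step_mv,
                 step_onset_ms = step_onset_ms,
                 step_duration_ms = step_duration_ms,
                 delta_v_mv = delta_v, dt_ms = dt_ms),
            class = "voltage_step_protocol")
}

#' Bundle repeated capacitative-transient sweeps
#'
#' @param traces List of congruent current traces (same `dt_ms`, same length).
#' @param protocol The [voltage_step_protocol()] they were acquired under.
#' @return A long tibble of class `sweep_set` with columns `sweep`, `time_ms`,
#'   `i_pa`, carrying the protocol as an attribute.
#' @export
new_sweep_set <- function(traces, protocol) {
  stopifnot(inherits(protocol, "voltage_step_protocol"))
  if (length(traces) < 1L) stop("need at least one sweep", call. = FALSE)
  purrr::walk(traces, assert_trace, kind = "current")
  dts <- purrr::map_dbl(traces, trace_dt)
  lens <- purrr::map_int(traces, nrow)
  if (length(unique(dts)) != 1L || length(unique(lens)) != 1L) {
    stop("sweeps are incongruent: all must share dt and length", call. = FALSE)
  }
  out <- purrr::imap_dfr(traces, function(tr, i) {
    tibble::tibble(sweep = as.integer(i), time_ms = tr$time_ms, i_pa = tr$value)
  })
  structure(out, class = c("sweep_set", class(out)),
            protocol = protocol, dt_ms = dts[[1]])
}

#' @rdname new_sweep_set
#' @param x A `sweep_set`.
#' @export
sweep_protocol <- function(x) attr(x, "protocol")

#' Zero-phase low-pass filter a trace
#'
#' 4th-order Butterworth applied forward and backward
#' (via [signal::filtfilt()]) so the filter adds no phase delay.
#'
#' @param trace An `ephys_trace`.
#' @param cutoff_khz Cutoff frequency in kHz (default 5, the standard offline
#'   filter for these recordings). `NULL` returns the trace unchanged.
#' @return The filtered trace.
#' @export
filter_trace <- function(trace, cutoff_khz = 5) {
  assert_trace(trace)
  if (is.null(cutoff_khz)) return(trace)
  fs_khz <- 1 / trace_dt(trace)
  w <- cutoff_khz / (fs_khz / 2)
  if (w >= 1) return(trace) # cutoff at/above Nyquist: nothing to remove
  bf <- signal::butter(4, w, type = "low")
  trace_like(trace, signal::filtfilt(bf, trace$value))
}

#' Average, filter and leak-correct capacitative transient sweeps
#'
#' Takes the pointwise mean of the repeated sweeps (ten in the standard
#' protocol), low-pass filters the average at 5 kHz with a zero-phase
#' Butterworth filter, and subtracts the steady-state leak current
#' `delta_v / r_input` so the corrected transient decays toward zero.
#'
#' @param sweeps A [new_sweep_set()].
#' @param r_input_mohm Input resistance in MOhm used for the leak term.
#'   `NULL` (default) estimates the steady-state leak directly from the mean
#'   current over the final 100 ms of the step.
#' @param filter_cutoff_khz Low-pass cutoff (kHz); `NULL` disables filtering.
#' @return A leak-corrected current `ephys_trace`, with the protocol and the
#'   leak current used stored in attributes `protocol` and `leak_pa`.
#' @export
preprocess_transient <- function(sweeps, r_input_mohm = NULL,
                                 filter_cutoff_khz = 5) {
  if (!inherits(sweeps, "sweep_set")) stop("`sweeps` must be a sweep_set", call. = FALSE)
  if (!is.null(r_input_mohm) && r_input_mohm <= 0) {
    stop("`r_input_mohm` must be positive", call. = FALSE)
  }
  proto <- sweep_protocol(sweeps)
  dt <- attr(sweeps, "dt_ms")

  # sweeps are congruent, so the pointwise mean is a plain matrix average
  n_sweeps <- length(unique(sweeps$sweep))
  times <- sweeps$time_ms[sweeps$sweep == sweeps$sweep[[1]]]
  avg_i <- rowMeans(matrix(sweeps$i_pa, ncol = n_sweeps))
  tr <- new_trace(avg_i, dt_ms = dt, kind = "current", t0_ms = times[[1]])
  tr <- filter_trace(tr, filter_cutoff_khz)

  step_end <- proto$step_onset_ms + proto$step_duration_ms
  if (is.null(r_input_mohm)) {
    # steady state from the final 100 ms of the step
    tail_win <- tr$time_ms >= (step_end - 100) & tr$time_ms <= step_end
    if (!any(tail_win)) stop("step too short to estimate steady-state leak", call. = FALSE)
    leak_pa <- mean(tr$value[tail_win])
  } else {
    leak_pa <- proto$delta_v_mv / (r_input_mohm / 1000) # mV / GOhm = pA
  }
  in_step <- tr$time_ms >= proto$step_onset_ms & tr$time_ms <= step_end
  corrected <- tr$value
  corrected[in_step] <- corrected[in_step] - leak_pa
  out <- trace_like(tr, corrected)
  attr(out, "protocol") <- proto
  attr(out, "leak_pa") <- leak_pa
  attr(out, "filter_cutoff_khz") <- filter_cutoff_khz
  out
}

#' Fit a two-exponential decay to a capacitative transient
#'
#' Fits I(t) = A1*exp(-t/tau1) + A2*exp(-t/tau2) + c by nonlinear least
#' squares to the decay of the leak-corrected transient, with t measured from
#' step onset. Components are reported fast-first (tau1 < tau2). The constant
#' offset `c` absorbs residual leak-correction error and is expected to be
#' near zero. Initialisation is by peel-off: a log-linear fit to the slow
#' tail, then a log-linear fit to the fast residual.
#'
#' @param transient Leak-corrected current trace from [preprocess_transient()].
#' @param protocol The acquisition [voltage_step_protocol()]; defaults to the
#'   one attached by `preprocess_transient()`.
#' @param fit_window Numeric length-2 vector of times (ms, absolute) bounding
#'   the fit. Default: from the sample after the post-step peak of |I| to the
#'   end of the step; when the transient was low-pass filtered, both ends
#'   are additionally guarded by the filter settling time (1.5 / cutoff) so
#'   the filter-shaped rise and the step-off ringing stay outside the fit.
#' @return A list of class `biexp_fit` with elements `a1`, `tau1`, `a2`,
#'   `tau2` (pA, ms), `baseline` (pA), `rss`, `n`, `converged`,
#'   `ill_conditioned` (tau1 ~ tau2), and `delta_v_mv`.
#' @export
fit_biexponential <- function(transient, protocol = attr(transient, "protocol"),
                              fit_window = NULL) {
  assert_trace(transient, kind = "current")
  stopifnot(inherits(protocol, "voltage_step_protocol"))
  step_end <- protocol$step_onset_ms + protocol$step_duration_ms

  if (is.null(fit_window)) {
    in_step <- which(transient$time_ms >= protocol$step_onset_ms &
                       transient$time_ms <= step_end)
    i_peak <- in_step[which.max(abs(transient$value[in_step]))]
    cutoff <- attr(transient, "filter_cutoff_khz")
    guard <- if (is.null(cutoff)) 0 else 1.5 / cutoff # filter settling (ms)
    fit_window <- c(
      max(transient$time_ms[min(i_peak + 1L, max(in_step))],
          protocol$step_onset_ms + guard),
      step_end - guard)
  }
  sel <- transient$time_ms >= fit_window[[1]] & transient$time_ms <= fit_window[[2]]
  if (sum(sel) < 10L) stop("fit window contains fewer than 10 samples", call. = FALSE)

  t <- transient$time_ms[sel] - protocol$step_onset_ms
  y <- transient$value[sel]
  s <- sign(protocol$delta_v_mv) # transient polarity follows the step
  ys <- s * y                    # work on a positive-going decay

  fail <- function() {
    structure(list(a1 = NA_real_, tau1 = NA_real_, a2 = NA_real_,
                   tau2 = NA_real_, baseline = NA_real_, rss = NA_real_,
                   n = length(y), converged = FALSE, ill_conditioned = FALSE,
                   delta_v_mv = protocol$delta_v_mv),
              class = "biexp_fit")
  }

  start <- biexp_peel_start(t, ys)
  try_biexp <- function(st) tryCatch(
    minpack.lm::nlsLM(
      ys ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2) + c0,
      start = st,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  fit <- try_biexp(start)
  if (is.null(fit)) {
    # retry treating the peel's slow component as dominant
    fit <- try_biexp(list(a1 = start$a2 / 10, tau1 = start$tau2 / 20,
                          a2 = start$a2, tau2 = start$tau2, c0 = 0))
  }
  if (is.null(fit)) {
    # a single-exponential transient makes the biexponential Jacobian
    # rank-deficient; fit one component and report the cell as lacking a
    # resolvable second compartment
    fit1 <- tryCatch(
      minpack.lm::nlsLM(ys ~ a * exp(-t / tau) + c0,
                        start = list(a = start$a2, tau = start$tau2, c0 = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit1)) return(fail())
    cf1 <- stats::coef(fit1)
    if (cf1[["tau"]] <= 0 || cf1[["a"]] < 0) return(fail())
    return(structure(list(
      a1 = s * cf1[["a"]], tau1 = cf1[["tau"]], a2 = 0, tau2 = NA_real_,
      baseline = s * cf1[["c0"]], rss = sum(stats::resid(fit1)^2),
      n = length(y), converged = TRUE, ill_conditioned = FALSE,
      delta_v_mv = protocol$delta_v_mv), class = "biexp_fit"))
  }

  cf <- stats::coef(fit)
  # validity: positive taus and amplitudes, offset small next to the transient
  if (any(!is.finite(cf)) || cf[["tau1"]] <= 0 || cf[["tau2"]] <= 0 ||
      cf[["a1"]] < 0 || cf[["a2"]] < 0 ||
      abs(cf[["c0"]]) > 0.1 * max(ys)) {
    return(fail())
  }
  a <- s * c(cf[["a1"]], cf[["a2"]])
  tau <- c(cf[["tau1"]], cf[["tau2"]])
  ord <- order(tau)          # fast (somatic) component first
  a <- a[ord]; tau <- tau[ord]
  # a genuinely single-exponential transient: park the negligible component
  # in the slow slot so C2 -> 0 downstream
  amax <- max(abs(a))
  if (amax > 0 && abs(a[1]) / amax < 1e-4 && abs(a[2]) / amax >= 1e-4) {
    a <- rev(a); tau <- rev(tau)
  }
  ill <- tau[2] / tau[1] < 1.5 # taus too close to separate compartments

  structure(list(a1 = a[1], tau1 = tau[1], a2 = a[2], tau2 = tau[2],
                 baseline = s * cf[["c0"]],
                 rss = sum(stats::resid(fit)^2), n = length(y),
                 converged = TRUE, ill_conditioned = ill,
                 delta_v_mv = protocol$delta_v_mv),
            class = "biexp_fit")
}

# peel-off starting values for the biexponential fit; ys is positive-going.
# Both log-linear fits are restricted to samples well above the numerical
# floor, otherwise the fully-decayed tail dominates and the slopes are junk.
biexp_peel_start <- function(t, ys) {
  ymax <- max(ys)
  alive <- ys > 1e-3 * ymax
  # first sustained drop below the floor marks the end of the live decay;
  # stray late samples (filter ringing at the step edges) must not extend it
  i_dead <- which(!alive)
  i_dead <- i_dead[i_dead > which.max(ys)]
  t_live <- if (length(i_dead)) t[i_dead[1]] else max(t)
  alive <- alive & t <= t_live

  tail_ok <- alive & t >= t_live / 2
  if (sum(tail_ok) >= 3L) {
    sl <- stats::lm(log(ys[tail_ok]) ~ t[tail_ok])
    tau2 <- -1 / min(stats::coef(sl)[[2]], -1e-8)
    a2 <- exp(stats::coef(sl)[[1]])
  } else {
    tau2 <- t_live / 5
    a2 <- ymax / 2
  }
  if (!is.finite(tau2) || tau2 <= 0 || tau2 > 100 * t_live) tau2 <- t_live / 5
  if (!is.finite(a2) || a2 <= 0) a2 <- ymax / 2

  res <- ys - a2 * exp(-t / tau2)
  head_ok <- t <= t_live / 10 & res > 1e-3 * ymax
  if (sum(head_ok) >= 3L) {
    fl <- stats::lm(log(res[head_ok]) ~ t[head_ok])
    tau1 <- -1 / min(stats::coef(fl)[[2]], -1e-8)
    a1 <- exp(stats::coef(fl)[[1]])
  } else {
    tau1 <- tau2 / 20
    a1 <- ymax / 2
  }
  # keep starts ordered, positive and finite
  if (!is.finite(tau1) || tau1 <= 0 || tau1 >= tau2) tau1 <- tau2 / 20
  if (!is.finite(a1) || a1 <= 0) a1 <- ymax / 2
  list(a1 = a1, tau1 = tau1, a2 = a2, tau2 = tau2, c0 = 0)
}

#' Derive two-compartment circuit parameters from a biexponential fit
#'
#' Maps the fitted transient coefficients onto the equivalent circuit:
#' C1 (soma and main proximal dendrites), C2 (distal dendritic arbor),
#' R1 (pipette access plus somatic internal resistance) and R2 (internal
#' resistance coupling the distal arbor):
#' \deqn{C_1 = \tau_1 (A_1+A_2)^2 / (A_1 \Delta V), \quad
#'       C_2 = A_2 \tau_2 / \Delta V}
#' \deqn{R_1 = \Delta V / (A_1+A_2), \quad
#'       R_2 = \Delta V / A_2 - \Delta V / (A_1+A_2)}
#' With pA/ms/mV inputs, capacitances come out in pF and resistances in GOhm;
#' resistances are reported in MOhm.
#'
#' @param fit A converged `biexp_fit`.
#' @param delta_v_mv Voltage step size (mV); defaults to the one recorded in
#'   the fit.
#' @return A list of class `compartment_params`: `c1_pf`, `c2_pf`, `r1_mohm`,
#'   `r2_mohm`, `delta_v_mv`, `single_compartment`. When `a2 = 0` the cell is
#'   flagged single-compartment: `c2_pf = 0`, `r2_mohm = NA`.
#' @export
derive_compartments <- function(fit, delta_v_mv = fit$delta_v_mv) {
  stopifnot(inherits(fit, "biexp_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge; compartments undefined", call. = FALSE)
  a1 <- fit$a1; a2 <- fit$a2; tau1 <- fit$tau1; tau2 <- fit$tau2
  dv <- delta_v_mv
  if (a1 + a2 == 0) stop("a1 + a2 = 0: total transient amplitude is zero", call. = FALSE)
  single <- (a2 == 0)
  c1 <- tau1 * (a1 + a2)^2 / (a1 * dv)                    # pF
  c2 <- if (single) 0 else a2 * tau2 / dv                 # pF
  r1_g <- dv / (a1 + a2)                                  # GOhm
  r2_g <- if (single) NA_real_ else dv / a2 - dv / (a1 + a2)
  structure(list(c1_pf = c1, c2_pf = c2,
                 r1_mohm = r1_g * 1000, r2_mohm = r2_g * 1000,
                 delta_v_mv = dv, single_compartment = single),
            class = "compartment_params")
}

#' Forward map: circuit parameters to biexponential coefficients
#'
#' Algebraic inverse of [derive_compartments()], used by the simulator to
#' construct the noiseless transient a given circuit produces:
#' A1 + A2 = dV/R1, A2 = dV/(R1+R2), tau2 = C2 (R1+R2),
#' tau1 = C1 A1 dV / (A1+A2)^2.
#'
#' @param params A `compartment_params` (or list with `c1_pf`, `c2_pf`,
#'   `r1_mohm`, `r2_mohm`, `delta_v_mv`); all circuit values must be positive.
#' @return A `biexp_fit` whose [derive_compartments()] reproduces `params`.
#' @export
compartments_to_biexponential <- function(params) {
  p <- params
  vals <- c(p$c1_pf, p$c2_pf, p$r1_mohm, p$r2_mohm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all circuit parameters must be positive and finite", call. = FALSE)
  }
  dv <- p$delta_v_mv
  if (is.null(dv) || dv == 0) stop("`delta_v_mv` must be non-zero", call. = FALSE)
  r1 <- p$r1_mohm / 1000; r2 <- p$r2_mohm / 1000 # GOhm
  a_tot <- dv / r1                               # pA
  a2 <- dv / (r1 + r2)
  a1 <- a_tot - a2
  tau2 <- p$c2_pf * (r1 + r2)                    # ms
  tau1 <- p$c1_pf * a1 * dv / a_tot^2
  structure(list(a1 = a1, tau1 = tau1, a2 = a2, tau2 = tau2,
                 baseline = 0, rss = 0, n = NA_integer_,
                 converged = TRUE, ill_conditioned = tau2 / tau1 < 1.5,
                 delta_v_mv = dv),
            class = "biexp_fit")
}

#' Cell-level quality control on input resistance
#'
#' Recordings with a measured input resistance below 100 MOhm are excluded;
#' the threshold is strict, so exactly 100 MOhm passes.
#'
#' @param r_input_mohm Measured input resistance (MOhm). Vectorised.
#' @param threshold_mohm Exclusion threshold; default 100.
#' @return Character vector, `"include"` or `"exclude"`.
#' @examples
#' qc_cell(c(99.9, 100, 250))
#' @export
qc_cell <- function(r_input_mohm, threshold_mohm = 100) {
  if (any(!is.finite(r_input_mohm))) stop("`r_input_mohm` must be finite", call. = FALSE)
  ifelse(r_input_mohm < threshold_mohm, "exclude", "include")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat("Biexponential transient fit (I(t) = A1 e^{-t/tau1} + A2 e^{-t/tau2} + c)\n")
  cat(sprintf("  A1 = %.6g pA, tau1 = %.6g ms (fast)\n", x$a1, x$tau1))
  cat(sprintf("  A2 = %.6g pA, tau2 = %.6g ms (slow)\n", x$a2, x$tau2))
  cat(sprintf("  baseline = %.4g pA, RSS = %.4g pA^2, converged: %s\n",
              x$baseline, x$rss, x$converged))
  if (isTRUE(x$ill_conditioned)) cat("  note: tau1 ~ tau2, compartments ill-conditioned\n")
  invisible(x)
}

#' @export
print.compartment_params <- function(x, ...) {
  cat("Two-compartment circuit parameters\n")
  cat(sprintf("  C1 = %.6g pF (soma + proximal), C2 = %.6g pF (distal arbor)\n",
              x$c1_pf, x$c2_pf))
  cat(sprintf("  R1 = %.6g MOhm (access + somatic), R2 = %s MOhm (coupling)\n",
              x$r1_mohm, ifelse(is.na(x$r2_mohm), "NA", sprintf("%.6g", x$r2_mohm))))
  if (isTRUE(x$single_compartment)) cat("  flagged single-compartment (A2 = 0)\n")
  invisible(x)
}

#' Tidy methods for capacitance fits
#'
#' @param x A `biexp_fit` or `compartment_params`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`tidy`) or one row of fit
#'   summaries (`glance`).
#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a1", "tau1", "a2", "tau2", "baseline"),
    estimate = c(x$a1, x$tau1, x$a2, x$tau2, x$baseline),
    unit = c("pA", "ms", "pA", "ms", "pA")
  )
}

#' @rdname tidy.biexp_fit
#' @export
glance.biexp_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, converged = x$converged,
                 ill_conditioned = x$ill_conditioned)
}

#' @rdname tidy.biexp_fit
#' @export
tidy.compartment_params <- function(x, ...) {
  tibble::tibble(
    term = c("c1", "c2", "r1", "r2"),
    estimate = c(x$c1_pf, x$c2_pf, x$r1_mohm, x$r2_mohm),
    unit = c("pF", "pF", "MOhm", "MOhm")
  )
}
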