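#' Fit a two-parameter single-exponential distance model
#'
#' Fits y = A e^(-b x) (decay) or y = A e^(b x) (growth) by nonlinear least
#' squares on the original scale, with b constrained positive. A log-linear
#' regression of ln(y) on x supplies the deterministic starting values. This
#' is the model used for back-propagating action potential amplitude (decay
#' with distance from the soma) and half-width (growth).
#'
#' @param data A data frame of per-cell records; one row per cell.
#' @param x,y Columns holding distance (um) and the response, given
#'   unquoted; defaults match [simulate_bap_dataset()] output
#'   (`distance_um`, `amplitude_mv`).
#' @param sign `"decay"` or `"growth"`.
#' @return An object of class `exp_decay_fit`: `a`, `b`, `sign`,
#'   `lambda_um = 1/b`, `r2`, `rss`, `n`, `df = n - 2`, standard errors
#'   `se_a`, `se_b`, and flags `converged`, `flat`.
#' @examples
#' d <- simulate_bap_dataset(sim_bap_spec(noise_sd_amp_mv = 0))
#' fit_exponential_model(d)
#' @export
fit_exponential_model <- function(data, x = distance_um, y = amplitude_mv,
                                  sign = c("decay", "growth")) {
  sign <- match.arg(sign)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) stop("need at least 3 points to fit a two-parameter curve", call. = FALSE)
  s <- if (sign == "decay") -1 else 1

  flat_fit <- function(converged = TRUE) {
    a <- mean(yv)
    rss <- sum((yv - a)^2)
    structure(list(a = a, b = 0, sign = sign, lambda_um = Inf,
                   r2 = 0, rss = rss, n = n, df = n - 2L,
                   se_a = stats::sd(yv) / sqrt(n), se_b = NA_real_,
                   converged = converged, flat = TRUE),
              class = "exp_decay_fit")
  }

  # deterministic start from the log-linear regression (positive y only)
  pos <- yv > 0
  if (sum(pos) >= 3L) {
    ll <- stats::lm(log(yv[pos]) ~ xv[pos])
    b0 <- s * stats::coef(ll)[[2]]
    a0 <- exp(stats::coef(ll)[[1]])
  } else {
    b0 <- 0.01
    a0 <- max(abs(yv))
  }
  if (!is.finite(b0) || b0 <= 0) b0 <- 1e-6
  if (!is.finite(a0) || a0 <= 0) a0 <- max(abs(yv))

  fit <- tryCatch(
    minpack.lm::nlsLM(yv ~ a * exp(s * b * xv),
                      start = list(a = a0, b = b0),
                      lower = c(a = 0, b = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- flat_fit(converged = FALSE)
    warning("exponential fit did not converge; flat fit reported")
    return(out)
  }
  cf <- stats::coef(fit)
  a <- cf[["a"]]; b <- cf[["b"]]
  # flat when the fitted curve changes by < 0.1% across the sampled range
  if (b * diff(range(xv)) < 1e-3) return(flat_fit())
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((yv - mean(yv))^2)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  structure(list(a = a, b = b, sign = sign, lambda_um = 1 / b,
                 r2 = 1 - rss / tss, rss = rss, n = n, df = n - 2L,
                 se_a = se[[1]], se_b = se[[2]],
                 converged = TRUE, flat = FALSE),
            class = "exp_decay_fit")
}

#' Length constant of an exponential attenuation fit
#'
#' The distance over which the fitted signal falls to 1/e of its somatic
#' value: the reciprocal of the fitted rate b. Applied to the published
#' five-week best-fit rates, b = 0.0215 gives 46.5 um and b = 0.0376 gives
#' 26.6 um (one-decimal rounding).
#'
#' @param fit An `exp_decay_fit`, or a positive rate b (per um) directly.
#' @param digits Decimal places for the reported value; `NULL` for full
#'   precision (reports round to one decimal).
#' @return Length constant in um.
#' @examples
#' length_constant(0.0215, digits = 1) # 46.5
#' @export
length_constant <- function(fit, digits = NULL) {
  b <- if (inherits(fit, "exp_decay_fit")) fit$b else fit
  if (!is.numeric(b) || any(b <= 0)) stop("rate `b` must be positive", call. = FALSE)
  lam <- 1 / b
  if (!is.null(digits)) lam <- round(lam, digits) else lam
}

#' Extra sum-of-squares F test: one curve versus one curve per group
#'
#' Tests whether two groups' distance profiles are better described by
#' separate exponential curves than by a single pooled curve. A pooled
#' two-parameter fit (df = n - 2) is compared with independent per-group
#' fits (df = n - 4):
#' \deqn{F = \frac{(RSS_{pooled} - RSS_{sep}) / (df_{pooled} - df_{sep})}
#'            {RSS_{sep} / df_{sep}}}
#' with p from the upper tail of the F distribution. Rejection (p < 0.05)
#' means the groups' curves differ.
#'
#' @param data A data frame with a `group` column (exactly two levels) plus
#'   the distance and response columns.
#' @param x,y Distance and response columns, unquoted (defaults
#'   `distance_um`, `amplitude_mv`).
#' @param sign `"decay"` or `"growth"`, passed to the curve fits.
#' @param group Grouping column, unquoted (default `group`).
#' @return An object of class `extra_ss_f`: `f_stat`, `df_num`, `df_den`,
#'   `p_value`, `pooled` (ExpFit), `per_group` (named list of ExpFits),
#'   `perfect_separate_fit` flag (RSS_sep = 0, p taken in the limit).
#' @export
extra_ss_f_test <- function(data, x = distance_um, y = amplitude_mv,
                            sign = c("decay", "growth"), group = group) {
  sign <- match.arg(sign)
  gv <- as.character(dplyr::pull(data, {{ group }}))
  levels <- unique(gv)
  if (length(levels) != 2L) {
    stop(sprintf("exactly 2 groups required, got %d", length(levels)), call. = FALSE)
  }
  splits <- split(seq_len(nrow(data)), gv)
  if (any(purrr::map_int(splits, length) < 3L)) {
    stop("every group needs at least 3 points", call. = FALSE)
  }

  pooled <- fit_exponential_model(data, {{ x }}, {{ y }}, sign = sign)
  per_group <- purrr::map(splits, function(idx) {
    fit_exponential_model(data[idx, , drop = FALSE], {{ x }}, {{ y }}, sign = sign)
  })

  rss_sep <- sum(purrr::map_dbl(per_group, "rss"))
  n_tot <- pooled$n
  df_pooled <- n_tot - 2L
  df_sep <- n_tot - 4L
  df_num <- df_pooled - df_sep

  perfect <- rss_sep <= .Machine$double.eps * max(1, pooled$rss)
  if (perfect) {
    f_stat <- if (pooled$rss > rss_sep) Inf else 0
    p <- if (is.infinite(f_stat)) 0 else 1
    warning("separate fits are exact (RSS = 0); p-value taken in the limit")
  } else {
    f_stat <- ((pooled$rss - rss_sep) / df_num) / (rss_sep / df_sep)
    f_stat <- max(f_stat, 0) # numerically tiny negative differences
    p <- stats::pf(f_stat, df_num, df_sep, lower.tail = FALSE)
  }
  structure(list(f_stat = f_stat, df_num = df_num, df_den = df_sep,
                 p_value = p, pooled = pooled, per_group = per_group,
                 perfect_separate_fit = perfect),
            class = "extra_ss_f")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  form <- if (x$sign == "decay") "y = A e^(-b x)" else "y = A e^(b x)"
  cat(sprintf("Single-exponent %s fit: %s\n", x$sign, form))
  cat(sprintf("  A = %.4g, b = %.4g per um, length constant = %.1f um\n",
              x$a, x$b, x$lambda_um))
  cat(sprintf("  R^2 = %.4f, RSS = %.4g, n = %d\n", x$r2, x$rss, x$n))
  if (x$flat) cat("  flagged flat (b ~ 0)\n")
  invisible(x)
}

#' @export
print.extra_ss_f <- function(x, ...) {
  cat("Extra sum-of-squares F test (single pooled curve vs per-group curves)\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              x$df_num, x$df_den, x$f_stat, x$p_value))
  for (nm in names(x$per_group)) {
    f <- x$per_group[[nm]]
    cat(sprintf("  %s: A = %.4g, b = %.4g, lambda = %.1f um, R^2 = %.4f\n",
                nm, f$a, f$b, f$lambda_um, f$r2))
  }
  invisible(x)
}

#' Tidy methods for attenuation fits
#'
#' @param x An `exp_decay_fit` or `extra_ss_f`.
#' @param ... Unused.
#' @return A tibble (one row per term for `tidy`, one summary row for
#'   `glance`; for `extra_ss_f`, `tidy` gives one row per fitted curve).
#' @export
tidy.exp_decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b),
    std.error = c(x$se_a, x$se_b)
  )
}

#' @rdname tidy.exp_decay_fit
#' @export
glance.exp_decay_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, lambda_um = x$lambda_um, r.squared = x$r2,
                 rss = x$rss, n = x$n, df = x$df,
                 converged = x$converged, flat = x$flat)
}

#' @rdname tidy.exp_decay_fit
#' @export
tidy.extra_ss_f <- function(x, ...) {
  fits <- c(list(pooled = x$pooled), x$per_group)
  purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(curve = nm, a = f$a, b = f$b, lambda_um = f$lambda_um,
                   r.squared = f$r2, rss = f$rss, n = f$n)
  })
}

#' @rdname tidy.exp_decay_fit
#' @export
glance.extra_ss_f <- function(x, ...) {
  tibble::tibble(statistic = x$f_stat, df_num = x$df_num, df_den = x$df_den,
                 p.value = x$p_value)
}
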