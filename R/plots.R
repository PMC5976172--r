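#' Plot a bAP attenuation dataset with its fitted curves
#'
#' Scatter of the per-cell measurements against soma-to-patch distance with
#' the per-group single-exponent best-fit curves overlaid, mirroring the
#' standard presentation of attenuation data.
#'
#' @param object An `extra_ss_f` result.
#' @param data The dataset the test was run on (columns `distance_um`,
#'   response, `group`).
#' @param y Response column, unquoted (default `amplitude_mv`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.extra_ss_f <- function(object, data, y = amplitude_mv, ...) {
  yq <- rlang::enquo(y)
  grid <- tidyr::expand_grid(
    group = names(object$per_group),
    distance_um = seq(min(data$distance_um), max(data$distance_um),
                      length.out = 200)
  ) |>
    dplyr::mutate(fitted = purrr::map2_dbl(.data$group, .data$distance_um,
      function(g, x) {
        f <- object$per_group[[g]]
        s <- if (f$sign == "decay") -1 else 1
        f$a * exp(s * f$b * x)
      }))
  ggplot2::ggplot(data, ggplot2::aes(.data$distance_um, !!yq,
                                     colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fitted, colour = .data$group)) +
    ggplot2::labs(
      x = "soma-to-patch distance (µm)",
      y = rlang::as_label(yq),
      colour = NULL,
      subtitle = sprintf("extra sum-of-squares F(%d, %d) = %.3g, p = %.3g",
                         object$df_num, object$df_den, object$f_stat,
                         object$p_value)) +
    ggplot2::theme_classic()
}

#' Plot a capacitative transient and its biexponential fit
#'
#' @param object A `biexp_fit`.
#' @param transient The leak-corrected transient it was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.biexp_fit <- function(object, transient, ...) {
  proto <- attr(transient, "protocol")
  t0 <- if (!is.null(proto)) proto$step_onset_ms else 0
  d <- tibble::as_tibble(transient) |>
    dplyr::filter(.data$time_ms >= t0) |>
    dplyr::mutate(fitted = object$a1 * exp(-(.data$time_ms - t0) / object$tau1) +
                    object$a2 * exp(-(.data$time_ms - t0) / object$tau2) +
                    object$baseline)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_ms)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red",
                       linetype = 2) +
    ggplot2::labs(x = "time (ms)", y = "current (pA)",
                  subtitle = sprintf(
                    "A1 = %.0f pA, τ1 = %.2f ms; A2 = %.0f pA, τ2 = %.2f ms",
                    object$a1, object$tau1, object$a2, object$tau2)) +
    ggplot2::theme_classic()
}

#' Heat map of log2 fold changes
#'
#' Tile display of the genes-by-timepoints matrix from
#' [log2_heatmap_matrix()], rows optionally grouped by channel subfamily.
#'
#' @param mat Matrix from [log2_heatmap_matrix()].
#' @param channel_list Optional tibble (`gene`, `subfamily`) used to facet
#'   rows by subfamily.
#' @return A ggplot object.
#' @export
plot_channel_heatmap <- function(mat, channel_list = NULL) {
  d <- tibble::as_tibble(mat, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "timepoint",
                        values_to = "log2_fc")
  if (!is.null(channel_list)) {
    d <- dplyr::left_join(d, channel_list, by = "gene")
  }
  d <- dplyr::mutate(d, gene = factor(.data$gene, levels = rev(rownames(mat))))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$timepoint, .data$gene,
                                       fill = .data$log2_fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal()
  if (!is.null(channel_list)) {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$subfamily),
                                 scales = "free_y", space = "free_y")
  }
  p
}

#' Plot a calcium-spike current-step family
#'
#' Voltage responses stacked by injected current, with spiking steps (per
#' [threshold_current()]) drawn in colour.
#'
#' @param family A `current_step_family`.
#' @param threshold Optional `ca_threshold` result used to colour spiking
#'   steps.
#' @return A ggplot object.
#' @export
plot_step_family <- function(family, threshold = NULL) {
  d <- family |>
    dplyr::mutate(v = purrr::map(.data$trace, tibble::as_tibble)) |>
    dplyr::select(-"trace") |>
    tidyr::unnest("v")
  if (!is.null(threshold)) {
    d <- dplyr::left_join(d, threshold$calls[, c("step_pa", "spike")],
                          by = "step_pa")
  } else {
    d$spike <- FALSE
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$time_ms, .data$value,
                                  group = .data$step_pa,
                                  colour = .data$spike)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)") +
    ggplot2::theme_classic()
}
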