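#' Re-exported autoplot generic
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' DAmFRET density plot
#'
#' AmFRET versus acceptor intensity (log10 scale) as a two-dimensional bin
#' plot, optionally with the negative-gate boundary overlaid. This is the
#' standard visual: a bimodal vertical split with expression overlap between
#' the two populations is the signature of a nucleation-limited transition.
#'
#' @param events Event tibble.
#' @param gate Optional `damfret_gate` to overlay.
#' @param bins Number of hexagonal/rectangular bins per axis.
#' @return A ggplot object.
#' @export
plot_damfret <- function(events, gate = NULL, bins = 120) {
  events <- compute_amfret(events)
  events <- events[!events$amfret_excluded & events$acceptor > 0, ,
                   drop = FALSE]
  p <- ggplot2::ggplot(events,
                       ggplot2::aes(x = .data$acceptor, y = .data$amfret)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "Acceptor intensity (a.u.)", y = "AmFRET",
                  fill = "Cells") +
    ggplot2::theme_minimal()
  if (!is.null(gate)) {
    p <- p + ggplot2::geom_step(
      data = gate, ggplot2::aes(x = .data$lower, y = .data$boundary),
      inherit.aes = FALSE, color = "red")
  }
  p
}

#' Plot a binned Weibull fit
#'
#' Observed per-bin assembled fractions (point size = occupancy) with the
#' fitted Weibull response curve and, for censored monomer fits, the data
#' alone.
#'
#' @param object A `damfret_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.damfret_fit <- function(object, ...) {
  bins <- object$bins
  occ <- bins[!is.na(bins$fraction), , drop = FALSE]
  p <- ggplot2::ggplot(occ, ggplot2::aes(x = .data$center,
                                         y = .data$fraction)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_total), alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "Acceptor intensity (a.u.)",
                  y = "Fraction assembled", size = "Events") +
    ggplot2::theme_minimal()
  if (!object$censored) {
    grid <- tibble::tibble(
      center = exp(seq(log(min(occ$center)), log(max(occ$center)),
                       length.out = 200)))
    grid$fraction <- weibull_response(grid$center, object$ec50, object$delta,
                                      object$plateau)
    p <- p + ggplot2::geom_line(data = grid, color = "#2166ac") +
      ggplot2::geom_vline(xintercept = object$ec50, linetype = 2,
                          color = "#2166ac")
  }
  p
}

#' Plot a dose-response summary
#'
#' Responder fraction by dose (left axis behavior of a binary switch: the
#' probability of activation rises with dose while the ON level does not).
#'
#' @param summary Tibble from [dose_response_summary()].
#' @return A ggplot object.
#' @export
plot_dose_response <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$dose,
                                        y = .data$fraction_on)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Dose", y = "Fraction responding") +
    ggplot2::theme_minimal()
}

#' Plot per-cell CV traces
#'
#' @param trace `trace` tibble from [cv_timecourse()].
#' @return A ggplot object.
#' @export
plot_cv_timecourse <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$frame, y = .data$cv,
                                      group = .data$id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", linewidth = 1, color = "#b2182b") +
    ggplot2::labs(x = "Frame", y = "Pixel-intensity CV") +
    ggplot2::theme_minimal()
}
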