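#' Plot methods for digitalizer result objects
#'
#' `autoplot()` methods give a quick standard view of each result type:
#' time courses (species vs time), dose-response curves (readout vs dose,
#' log-log), repression sweeps (one curve per strength, the classic
#' fan-with-pivot view), phase portraits (mS vs mR across doses), hysteresis
#' scans (up and down branches overlaid), survival curves, de-induction decay
#' and cytometry summaries (median with fraction-ON facet).
#'
#' @param object A result object from this package.
#' @param readout Readout column for curve-type plots.
#' @param ... Unused.
#' @return A ggplot object.
#' @name digitalizer-plots
NULL

#' @rdname digitalizer-plots
#' @export
autoplot.digitalizer_timecourse <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("mR", "mS", "R", "G"),
                              names_to = "species", values_to = "conc")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$conc,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "concentration (nM)") +
    ggplot2::theme_minimal()
}

#' @rdname digitalizer-plots
#' @export
autoplot.dose_response <- function(object, readout = "mR", ...) {
  df <- object[object$dose > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$dose, .data[[readout]])) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "active TF (nM)", y = paste(readout, "(nM)")) +
    ggplot2::theme_minimal()
}

#' @rdname digitalizer-plots
#' @export
autoplot.repression_sweep <- function(object, readout = NULL, ...) {
  readout <- readout %||% attr(object, "readout")
  df <- object$curves[object$curves$dose > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$dose, .data[[readout]],
                                   colour = factor(.data$strength),
                                   group = .data$strength)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_viridis_d(option = "turbo", name = "repression\nstrength") +
    ggplot2::labs(x = "active TF (nM)", y = paste("steady-state", readout, "(nM)")) +
    ggplot2::theme_minimal()
}

#' Phase-plane view of a repression sweep (mS vs mR)
#'
#' The mutual-exclusivity plot: steady-state `mS` against `mR` across the dose
#' grid, one curve per repression strength. Strong repression pushes the curve
#' onto the axes - the population is dominated by one RNA species or the
#' other, never both.
#'
#' @param sweep A [repression_sweep()] object.
#' @param floor Positive floor applied before log scaling.
#' @return A ggplot object.
#' @export
plot_phase_plane <- function(sweep, floor = 1e-6) {
  stopifnot(inherits(sweep, "repression_sweep"))
  df <- sweep$curves
  df$mR <- pmax(df$mR, floor); df$mS <- pmax(df$mS, floor)
  ggplot2::ggplot(df, ggplot2::aes(.data$mR, .data$mS,
                                   colour = factor(.data$strength),
                                   group = .data$strength)) +
    ggplot2::geom_path() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_viridis_d(option = "turbo", name = "repression\nstrength") +
    ggplot2::labs(x = "mR (nM)", y = "mS (nM)") +
    ggplot2::theme_minimal()
}

#' @rdname digitalizer-plots
#' @export
autoplot.hysteresis_scan <- function(object, ...) {
  readout <- attr(object, "readout")
  df <- dplyr::bind_rows(
    dplyr::mutate(object$up, direction = "up"),
    dplyr::mutate(object$down, direction = "down"))
  df <- df[df$dose > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$dose, .data[[readout]],
                                   colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "active TF (nM)", y = paste(readout, "(nM)")) +
    ggplot2::theme_minimal()
}

#' @rdname digitalizer-plots
#' @export
autoplot.survival_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$dose, .data$survival)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log1p") +
    ggplot2::labs(x = "inducer dose (nM)", y = "surviving fraction") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname digitalizer-plots
#' @export
autoplot.deinduction <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$G_norm,
                                       colour = .data$construct)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "t_on"), linetype = 2) +
    ggplot2::labs(x = "time (min)", y = "G / G(t_on)") +
    ggplot2::theme_minimal()
}

#' @rdname digitalizer-plots
#' @export
autoplot.cytometry_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("median_au", "frac_on"),
                              names_to = "stat", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$construct,
                                     group = interaction(.data$construct,
                                                         .data$dose))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
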