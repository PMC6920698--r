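#' Population statistics of flow-cytometry events
#'
#' The summary statistics used to benchmark the digitalizer constructs:
#' `median_fluorescence()` is the standard sample median;
#' `cv100()` is the coefficient of variation expressed as a percentage,
#' `100 * sd / mean`, with the sample (n-1) standard deviation - the higher
#' the CV the less homogeneous the population;
#' `gate_threshold()` derives the upper edge of the no-fluorescence gate from
#' the promoterless control population as an empirical quantile (default the
#' 99.5th percentile, type-7 linear interpolation);
#' `fraction_on()` is the proportion of events strictly above the gate.
#'
#' @param events Numeric vector of fluorescence values (AU).
#' @param control_events Fluorescence of the promoterless (autofluorescence
#'   only) control population.
#' @param q Gate quantile in (0, 1); default 0.995.
#' @param threshold Gate value (AU).
#' @return A single numeric value.
#' @export
median_fluorescence <- function(events) {
  stopifnot(is.numeric(events), length(events) >= 1)
  if (any(!is.finite(events))) stop("events must be finite", call. = FALSE)
  stats::median(events)
}

#' @rdname median_fluorescence
#' @export
cv100 <- function(events) {
  stopifnot(is.numeric(events))
  if (length(events) < 2) stop("cv100() needs at least 2 events", call. = FALSE)
  m <- mean(events)
  if (!is.finite(m) || m <= 0) stop("cv100() needs a positive mean", call. = FALSE)
  100 * stats::sd(events) / m
}

#' @rdname median_fluorescence
#' @export
gate_threshold <- function(control_events, q = 0.995) {
  stopifnot(is.numeric(control_events), length(control_events) >= 1)
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  unname(stats::quantile(control_events, q, type = 7))
}

#' @rdname median_fluorescence
#' @export
fraction_on <- function(events, threshold) {
  stopifnot(is.numeric(events), is.numeric(threshold), threshold >= 0)
  mean(events > threshold)
}

#' Summarise an event table per condition
#'
#' Computes the full [CytometrySummary]-style table per
#' `(construct, dose, time)` cell: event count, median, mean, SD, CV*100 and
#' fraction ON against a no-fluorescence gate derived per time point from the
#' promoterless control (pooled over control doses, since the control has no
#' promoter to respond with). Dead cells are excluded from all statistics.
#'
#' @param events An event table (see [generate_flow_experiment()]).
#' @param gate_q Gate quantile applied to the control population (default 0.995).
#' @return A tibble of class `cytometry_summary` with columns `construct`,
#'   `dose`, `time`, `n_events`, `median_au`, `mean_au`, `sd_au`, `cv100`,
#'   `frac_on`, `gate_au`.
#' @name summarize_cytometry
#' @export
summarize_cytometry <- function(events, gate_q = 0.995) {
  stopifnot(is.data.frame(events),
            all(c("construct", "dose", "time", "fluorescence", "alive")
                %in% names(events)))
  ev <- events[events$alive, ]
  times <- sort(unique(ev$time))
  ctrl <- ev[ev$construct == "promoterless", ]
  missing_t <- setdiff(times, unique(ctrl$time))
  if (nrow(ctrl) == 0 || length(missing_t)) {
    stop("missing promoterless control events",
         if (length(missing_t)) paste0(" at time(s) ",
                                       paste(missing_t, collapse = ", ")),
         call. = FALSE)
  }
  gates <- vapply(times, function(tt) {
    gate_threshold(ctrl$fluorescence[ctrl$time == tt], q = gate_q)
  }, numeric(1))
  names(gates) <- as.character(times)
  out <- ev |>
    dplyr::group_by(.data$construct, .data$dose, .data$time) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      median_au = stats::median(.data$fluorescence),
      mean_au = mean(.data$fluorescence),
      sd_au = stats::sd(.data$fluorescence),
      .groups = "drop")
  out$cv100 <- ifelse(out$n_events >= 2 & out$mean_au > 0,
                      100 * out$sd_au / out$mean_au, NA_real_)
  out$gate_au <- gates[as.character(out$time)]
  frac <- mapply(function(cn, d, tt, g) {
    fraction_on(ev$fluorescence[ev$construct == cn & ev$dose == d & ev$time == tt], g)
  }, out$construct, out$dose, out$time, out$gate_au)
  out$frac_on <- unname(frac)
  out <- out[, c("construct", "dose", "time", "n_events", "median_au",
                 "mean_au", "sd_au", "cv100", "frac_on", "gate_au")]
  structure(out, class = c("cytometry_summary", class(out)), gate_q = gate_q)
}
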