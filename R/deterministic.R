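ode_rhs <- function(t, y, parms) {
  p <- parms$p
  y <- pmax(y, 0)
  pair <- p$k_pair * y[1] * y[2]
  xn <- (parms$tf_a / p$K_TF)^p$n_act
  act <- if (parms$tf_a <= 0) 0 else xn / (1 + xn)
  rn <- (y[3] / p$K_R)^p$n_rep
  rep_ <- 1 / (1 + rn)
  list(c(p$beta_R + p$alpha_R * act - (p$delta_mR + p$mu) * y[1] - pair,
         p$alpha_S * rep_ - (p$delta_mS + p$mu) * y[2] - pair,
         p$lambda_R * y[1] - (p$delta_R + p$mu) * y[3],
         p$lambda_G * y[1] - (p$delta_G + p$mu) * y[4]))
}

default_init <- function() c(mR = 0, mS = 0, R = 0, G = 0)

as_state <- function(init) {
  if (is.null(init)) return(default_init())
  s <- unlist(init)[c("mR", "mS", "R", "G")]
  if (any(is.na(s))) stop("init must contain mR, mS, R, G", call. = FALSE)
  if (any(s < -1e-9)) stop("init must be non-negative", call. = FALSE)
  pmax(s, 0)
}

integrate_segment <- function(params, tf_a, times, init, rtol = 1e-10, atol = 1e-10) {
  out <- deSolve::lsoda(init, times, func = "dig_derivs",
                        parms = c(params_vec(params), tf_a = tf_a),
                        dllname = "digitalizer", initfunc = "dig_init",
                        rtol = rtol, atol = atol, maxsteps = 500000)
  colnames(out) <- c("time", "mR", "mS", "R", "G")
  if (attr(out, "istate")[1] < 0) {
    stop(sprintf("ODE solver failed on segment [%g, %g] at tf_a = %g",
                 min(times), max(times), tf_a), call. = FALSE)
  }
  out
}

#' Integrate the digitalizer ODE model
#'
#' Solves the circuit ODEs over a time grid under a piecewise-constant inducer
#' protocol. Each constant-input segment is integrated separately with
#' `deSolve::lsoda()` at tight tolerances, so protocol steps are handled
#' exactly rather than smoothed over.
#'
#' @param params A [digitalizer_params()] object.
#' @param protocol An [inducer_protocol()], or a single number for a constant
#'   `tf_a` input.
#' @param times Strictly increasing output time grid (min), starting at or
#'   after the first protocol breakpoint.
#' @param init Named vector `(mR, mS, R, G)` of initial concentrations
#'   (default: all zero).
#' @return A tibble of class `digitalizer_timecourse` with columns `time`,
#'   `tf_a`, `mR`, `mS`, `R`, `G`.
#' @examples
#' p <- digitalizer_params()
#' tc <- simulate_ode(p, 1000, times = seq(0, 160, by = 5))
#' @export
simulate_ode <- function(params, protocol, times, init = NULL) {
  validate_params(params)
  protocol <- as_protocol(protocol)
  stopifnot(is.numeric(times), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (times[1] < protocol$breakpoints[1]) {
    stop("times start before the first protocol breakpoint", call. = FALSE)
  }
  state <- as_state(init)
  bp <- protocol$breakpoints
  seg_edges <- unique(c(times[1], bp[bp > times[1] & bp < times[length(times)]],
                        times[length(times)]))
  rows <- list()
  for (k in seq_len(length(seg_edges) - 1)) {
    t0 <- seg_edges[k]; t1 <- seg_edges[k + 1]
    tf_a <- protocol_level_at(protocol, t0)
    tt <- times[times >= t0 & times <= t1]
    tt <- unique(c(t0, tt, t1))
    out <- integrate_segment(params, tf_a, tt, state)
    state <- pmax(out[nrow(out), -1], 0)
    keep <- out[, "time"] %in% times
    if (k > 1) keep <- keep & out[, "time"] > t0  # segment start already emitted
    if (any(keep)) {
      m <- out[keep, , drop = FALSE]
      rows[[length(rows) + 1]] <- tibble::tibble(
        time = m[, "time"], tf_a = tf_a,
        mR = pmax(m[, "mR"], 0), mS = pmax(m[, "mS"], 0),
        R = pmax(m[, "R"], 0), G = pmax(m[, "G"], 0))
    }
  }
  tc <- dplyr::bind_rows(rows)
  tc <- tc[!duplicated(tc$time), ]
  # label each output time with the level of its own (half-open) interval
  tc$tf_a <- protocol_level_at(protocol, tc$time)
  structure(tc, class = c("digitalizer_timecourse", class(tc)),
            params = params, protocol = protocol)
}

#' Steady state of the digitalizer circuit at a constant input
#'
#' Finds a steady state by long integration from `init` followed by a damped
#' Newton refinement on the right-hand side. The returned state depends on
#' `init` by design: in a bistable regime, seeding from the OFF (all-zero) or
#' an ON state selects the corresponding branch, which is what the
#' dose-response continuation and the hysteresis scan exploit.
#'
#' @inheritParams simulate_ode
#' @param tf_a Constant active-TF input (nM).
#' @param tol Convergence tolerance: the max absolute derivative must fall
#'   below `tol * (1 + max(state))`.
#' @return Named numeric vector `(mR, mS, R, G)`.
#' @export
steady_state <- function(params, tf_a, init = NULL, tol = 1e-9) {
  validate_params(params)
  dec <- unlist(params[c("delta_mR", "delta_mS", "delta_R", "delta_G")]) + params$mu
  if (any(dec <= 0)) stop("all effective decay rates must be > 0 for a steady state",
                          call. = FALSE)
  y <- as_state(init)
  horizon <- 10 / min(dec)
  f <- function(y) unlist(ode_rhs(0, y, list(p = params, tf_a = tf_a))[[1]])
  resid <- function(y) max(abs(f(y))) / (1 + max(abs(y)))
  for (round in 1:8) {
    out <- integrate_segment(params, tf_a, c(0, horizon / 2, horizon), y)
    y <- pmax(out[nrow(out), -1], 0)
    y_ref <- newton_refine(f, y)
    if (!is.null(y_ref) && resid(y_ref) <= tol) {
      names(y_ref) <- c("mR", "mS", "R", "G")
      return(y_ref)
    }
    if (resid(y) <= tol) {
      names(y) <- c("mR", "mS", "R", "G")
      return(y)
    }
  }
  stop(sprintf("steady_state() did not converge at tf_a = %g (residual %.3e)",
               tf_a, resid(y)), call. = FALSE)
}

newton_refine <- function(f, y, max_iter = 40) {
  y0 <- y
  for (i in seq_len(max_iter)) {
    fy <- f(y)
    if (max(abs(fy)) < 1e-13 * (1 + max(abs(y)))) break
    J <- matrix(0, 4, 4)
    for (j in 1:4) {
      h <- 1e-7 * (abs(y[j]) + 1e-7)
      yp <- y; yp[j] <- yp[j] + h
      J[, j] <- (f(yp) - fy) / h
    }
    step <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    # damp: never move more than 50% of the current scale in one step
    scale <- abs(y) + 1e-6
    lim <- max(abs(step) / (0.5 * scale))
    if (lim > 1) step <- step / lim
    y <- y + step
    if (any(y < 0)) y <- pmax(y, 0)
    if (any(!is.finite(y))) return(NULL)
  }
  # reject refinements that wandered to a different attractor
  if (max(abs(y - y0)) > 0.2 * (1 + max(abs(y0)))) return(NULL)
  y
}

#' Steady-state dose-response curve with branch continuation
#'
#' Computes the steady state at each dose, seeding each solve from the
#' previous dose's state. `direction = "up"` walks the dose grid upward from
#' the uninduced (all-zero) state and therefore follows the OFF branch through
#' any bistable window; `direction = "down"` walks downward from a fully
#' induced state and follows the ON branch. On a monostable system the two
#' directions coincide.
#'
#' @inheritParams steady_state
#' @param doses Strictly increasing `tf_a` grid (nM); may start at 0.
#' @param direction `"up"` (default) or `"down"`.
#' @return A tibble of class `dose_response` with columns `dose`, `mR`, `mS`,
#'   `R`, `G`, `converged`.
#' @export
dose_response <- function(params, doses, direction = c("up", "down"), tol = 1e-9) {
  validate_params(params)
  direction <- match.arg(direction)
  stopifnot(is.numeric(doses), length(doses) >= 1)
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing", call. = FALSE)
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  n <- length(doses)
  res <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("mR", "mS", "R", "G")))
  conv <- rep(FALSE, n)
  if (direction == "up") {
    idx <- seq_len(n)
    init <- default_init()
  } else {
    idx <- rev(seq_len(n))
    # fully induced seed: production-limited mR with the sRNA promoter shut
    mR_hi <- (params$beta_R + params$alpha_R) / (params$delta_mR + params$mu)
    init <- c(mR = mR_hi, mS = 0,
              R = params$lambda_R * mR_hi / (params$delta_R + params$mu),
              G = params$lambda_G * mR_hi / (params$delta_G + params$mu))
  }
  for (i in idx) {
    y <- tryCatch(steady_state(params, doses[i], init, tol = tol),
                  error = function(e) {
                    stop(sprintf("dose_response() failed at dose index %d (dose %g): %s",
                                 i, doses[i], conditionMessage(e)), call. = FALSE)
                  })
    res[i, ] <- y
    conv[i] <- TRUE
    init <- y
  }
  out <- tibble::as_tibble(as.data.frame(res))
  out <- dplyr::bind_cols(tibble::tibble(dose = doses), out)
  out$converged <- conv
  structure(out, class = c("dose_response", class(out)),
            params = params, direction = direction)
}

interp_crossing <- function(doses, y, target) {
  i <- which(y >= target)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(doses[1])
  doses[i - 1] + (target - y[i - 1]) / (y[i] - y[i - 1]) * (doses[i] - doses[i - 1])
}

#' Digitalization metrics of a dose-response curve
#'
#' Summarises a monotone dose-response curve by the quantities used to judge
#' how "digital" the switch is: OFF level (readout at dose 0), ON level (at
#' the maximal dose), fold change, EC50 (dose at half-range), transition width
#' (dose span between 10% and 90% of the range, linear dose axis, monotone
#' linear interpolation) and an effective Hill coefficient from a four-
#' parameter least-squares Hill fit.
#'
#' @param curve A [dose_response()] tibble (or any tibble with `dose` and the
#'   readout column); must include dose 0 for the OFF level and be monotone in
#'   the readout.
#' @param readout `"mR"` (default, the operon mRNA) or `"G"` (the GOI product).
#' @param log_axis If `TRUE`, EC50 and transition width are measured on the
#'   log10 dose axis (positive doses only). The default `FALSE` (linear axis)
#'   is what the package's own analyses use.
#' @return A one-row tibble: `readout`, `off_level`, `on_level`, `fold_change`,
#'   `ec50`, `transition_width`, `effective_hill`.
#' @export
response_metrics <- function(curve, readout = c("mR", "G"), log_axis = FALSE) {
  readout <- match.arg(readout)
  stopifnot(is.data.frame(curve), all(c("dose", readout) %in% names(curve)))
  if (!is.null(curve[["converged"]]) && !all(curve$converged)) {
    stop("curve contains non-converged points", call. = FALSE)
  }
  doses <- curve$dose
  y <- curve[[readout]]
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing", call. = FALSE)
  rng <- max(y) - min(y)
  if (!is.finite(rng) || rng < 1e-12 * max(1, max(abs(y)))) {
    stop("degenerate dose-response curve: readout range is (numerically) zero",
         call. = FALSE)
  }
  wiggle <- min(diff(cummax(y)))
  if (wiggle < -1e-6 * rng) {
    stop("curve is not monotone non-decreasing in the readout", call. = FALSE)
  }
  ym <- cummax(y)  # absorb solver-level wiggles before interpolating
  off <- y[which(doses == 0)[1]]
  if (is.na(off)) off <- y[1]
  on <- y[length(y)]
  axis <- doses
  if (log_axis) {
    keep <- doses > 0
    axis <- log10(doses[keep]); ym <- cummax(y[keep])
  }
  lo <- min(ym); hi <- max(ym)
  ec50 <- interp_crossing(axis, ym, lo + 0.5 * (hi - lo))
  d10 <- interp_crossing(axis, ym, lo + 0.1 * (hi - lo))
  d90 <- interp_crossing(axis, ym, lo + 0.9 * (hi - lo))
  hill <- fit_effective_hill(doses, y)
  tibble::tibble(readout = readout, off_level = off, on_level = on,
                 fold_change = on / off, ec50 = ec50,
                 transition_width = d90 - d10, effective_hill = hill)
}

fit_effective_hill <- function(doses, y) {
  df <- data.frame(d = doses, y = y)
  ec0 <- interp_crossing(doses, cummax(y), min(y) + 0.5 * diff(range(y)))
  if (!is.finite(ec0) || ec0 <= 0) ec0 <- stats::median(doses[doses > 0])
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      y ~ off + (on - off) * ifelse(d > 0, d^h / (ec^h + d^h), 0),
      data = df,
      start = list(off = min(y), on = max(y), ec = ec0, h = 2),
      lower = c(off = 0, on = 0, ec = min(doses[doses > 0]) / 10, h = 0.1),
      upper = c(off = Inf, on = Inf, ec = max(doses) * 10, h = 50),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  unname(stats::coef(fit)[["h"]])
}

#' Sweep the joint repression strength of the switch
#'
#' Recomputes the up-direction dose-response curve after scaling both
#' repression arms by each factor in `strengths` (see [scale_repression()]),
#' and attaches the digitalization metrics per strength. The `(mR, mS)` pairs
#' per dose are the phase-plane data showing the mutual exclusivity of the
#' two RNA species.
#'
#' @inheritParams dose_response
#' @param strengths Positive scale factors, e.g. `c(0.3, 1, 3, 10, 30)`.
#' @param readout Readout passed to [response_metrics()].
#' @return An object of class `repression_sweep`: a list with tibbles
#'   `curves` (`strength`, `dose`, `mR`, `mS`, `R`, `G`, `converged`) and
#'   `metrics` (`strength` + metric columns).
#' @export
repression_sweep <- function(params, strengths = c(0.3, 1, 3, 10, 30),
                             doses = default_dose_grid(), readout = "mR") {
  validate_params(params)
  stopifnot(is.numeric(strengths), all(strengths > 0))
  curves <- purrr::map_dfr(strengths, function(s) {
    cv <- dose_response(scale_repression(params, s), doses)
    dplyr::bind_cols(tibble::tibble(strength = s), cv)
  })
  metrics <- purrr::map_dfr(strengths, function(s) {
    cv <- curves[curves$strength == s, setdiff(names(curves), "strength")]
    dplyr::bind_cols(tibble::tibble(strength = s),
                     response_metrics(cv, readout = readout))
  })
  structure(list(curves = curves, metrics = metrics),
            class = "repression_sweep", params = params, readout = readout)
}

#' @export
print.repression_sweep <- function(x, ...) {
  cat("<repression_sweep> of", length(unique(x$curves$strength)), "strengths x",
      length(unique(x$curves$dose)), "doses\n")
  print(x$metrics)
  invisible(x)
}

#' Default dose grid for dose-response analyses
#'
#' Dose 0 (for the OFF level) plus a log-spaced grid. The default spans
#' 0.1-1000 nM of active TF with enough resolution to localise the sharp
#' transitions of strongly repressed circuits.
#'
#' @param from,to Positive grid limits (nM).
#' @param n Number of log-spaced points.
#' @export
default_dose_grid <- function(from = 0.1, to = 1000, n = 241) {
  c(0, 10^seq(log10(from), log10(to), length.out = n))
}

#' Scan for hysteresis between up and down dose sweeps
#'
#' Runs the dose-response continuation in both directions and reports the
#' largest branch separation. The circuit is called bistable when the maximal
#' gap between up- and down-branch readouts exceeds `rel_tol` times the
#' dynamic range of the readout.
#'
#' @inheritParams dose_response
#' @param readout Column used for the branch comparison (default `"mR"`).
#' @param rel_tol Bistability threshold relative to the dynamic range.
#' @return A list of class `hysteresis_scan`: `bistable`, `max_branch_gap`,
#'   `relative_gap`, `dose_at_max_gap`, and the `up`/`down` curves.
#' @export
hysteresis_scan <- function(params, doses = default_dose_grid(), readout = "mR",
                            rel_tol = 1e-3) {
  up <- dose_response(params, doses, "up")
  down <- dose_response(params, doses, "down")
  gap <- abs(up[[readout]] - down[[readout]])
  rng <- max(up[[readout]], down[[readout]]) - min(up[[readout]], down[[readout]])
  rel <- if (rng > 0) max(gap) / rng else 0
  structure(list(bistable = rel > rel_tol,
                 max_branch_gap = max(gap),
                 relative_gap = rel,
                 dose_at_max_gap = doses[which.max(gap)],
                 up = up, down = down),
            class = "hysteresis_scan", readout = readout, rel_tol = rel_tol)
}

#' @export
print.hysteresis_scan <- function(x, ...) {
  cat("<hysteresis_scan>", if (x$bistable) "BISTABLE" else "monostable",
      sprintf("(relative branch gap %.3g at dose %.3g)\n",
              x$relative_gap, x$dose_at_max_gap))
  invisible(x)
}

#' De-induction kinetics of the digitalized vs non-digitalized construct
#'
#' Simulates full induction for `t_on` minutes followed by inducer removal,
#' for the digitalized circuit and its non-digitalized parent (`alpha_S = 0`),
#' with identical solver settings. Both runs start from their own uninduced
#' steady state. The normalised post-removal decay of `G` is the model
#' counterpart of following the fluorescence decay of washed, fully induced
#' cultures: symmetric decay between the two constructs argues against
#' hysteresis in the digitalized device.
#'
#' @inheritParams simulate_ode
#' @param t_on Induction duration (min).
#' @param t_total Total simulated time (min), > `t_on`.
#' @param tf_a_on Inducer level during induction (nM).
#' @param mu Dilution rate override applied to both constructs (default: the
#'   value in `params`).
#' @param dt Output resolution (min).
#' @return A tibble of class `deinduction` with columns `construct`, `time`,
#'   `tf_a`, `mR`, `mS`, `R`, `G`, and `G_norm` (G relative to its value at
#'   `t_on`).
#' @export
deinduction <- function(params, t_on = 180, t_total = 360, tf_a_on = 1000,
                        mu = NULL, dt = 1) {
  validate_params(params)
  stopifnot(t_on > 0, t_total > t_on)
  if (!is.null(mu)) {
    params <- do.call(digitalizer_params, utils::modifyList(unclass(params),
                                                            list(mu = mu)))
  }
  protocol <- inducer_protocol(c(0, t_on), c(tf_a_on, 0))
  times <- unique(sort(c(seq(0, t_total, by = dt), t_on)))
  run_one <- function(p, label) {
    init <- steady_state(p, 0)
    tc <- simulate_ode(p, protocol, times, init = init)
    g_on <- tc$G[tc$time == t_on]
    dplyr::bind_cols(tibble::tibble(construct = label), tc,
                     tibble::tibble(G_norm = tc$G / g_on))
  }
  nd <- do.call(digitalizer_params, utils::modifyList(unclass(params),
                                                      list(alpha_S = 0)))
  out <- dplyr::bind_rows(run_one(params, "digitalized"),
                          run_one(nd, "non_digitalized"))
  structure(out, class = c("deinduction", class(out)), t_on = t_on)
}
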