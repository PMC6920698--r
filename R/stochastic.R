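#' Reaction set of the stochastic digitalizer model
#'
#' The nine reaction channels of the count-level model at system size `omega`
#' (molecules per nM), as a tibble of stoichiometries plus a propensity
#' evaluator. Propensities are the ODE fluxes evaluated at concentrations
#' `counts / omega` and multiplied by `omega`, so dividing any propensity by
#' `omega` at state `x * omega` recovers the corresponding ODE flux at `x`
#' exactly. A dilution rate `mu > 0` is folded into the four first-order decay
#' channels (an explicit dilution channel would have the identical propensity).
#'
#' This function is the readable specification of the network; the simulator
#' itself ([gillespie()]) implements the same propensities in compiled code.
#'
#' @inheritParams simulate_ode
#' @param omega System-size conversion factor (molecules per nM), > 0.
#' @return A list with `stoichiometry` (9 x 4 integer matrix over
#'   `mR, mS, R, G`), `reactions` (a tibble describing each channel), and
#'   `propensity(counts, tf_a)` returning the nine propensities (1/min).
#' @export
build_reactions <- function(params, omega = 1) {
  validate_params(params)
  stopifnot(is.numeric(omega), omega > 0, is.finite(omega))
  S <- matrix(c(+1, 0, 0, 0,
                0, +1, 0, 0,
                -1, 0, 0, 0,
                0, -1, 0, 0,
                -1, -1, 0, 0,
                0, 0, +1, 0,
                0, 0, 0, +1,
                0, 0, -1, 0,
                0, 0, 0, -1), nrow = 9, byrow = TRUE,
              dimnames = list(NULL, c("mR", "mS", "R", "G")))
  reactions <- tibble::tibble(
    reaction = c("P1 transcription", "P2 transcription", "mR decay", "mS decay",
                 "mR-mS pairing co-degradation", "R translation", "G translation",
                 "R decay", "G decay"),
    rate_law = c("omega * (beta_R + alpha_R * hill_activation(tf_a))",
                 "omega * alpha_S * hill_repression(R / omega)",
                 "(delta_mR + mu) * mR", "(delta_mS + mu) * mS",
                 "(k_pair / omega) * mR * mS",
                 "lambda_R * mR", "lambda_G * mR",
                 "(delta_R + mu) * R", "(delta_G + mu) * G"))
  p <- params
  propensity <- function(counts, tf_a) {
    n <- unlist(counts)[c("mR", "mS", "R", "G")]
    if (any(is.na(n)) || any(n < 0)) {
      stop("counts must be named non-negative values over mR, mS, R, G",
           call. = FALSE)
    }
    c(p1_transcription = omega * (p$beta_R +
        p$alpha_R * hill_activation(tf_a, p$K_TF, p$n_act)),
      p2_transcription = omega * p$alpha_S *
        hill_repression(n[["R"]] / omega, p$K_R, p$n_rep),
      mR_decay = (p$delta_mR + p$mu) * n[["mR"]],
      mS_decay = (p$delta_mS + p$mu) * n[["mS"]],
      pairing = (p$k_pair / omega) * n[["mR"]] * n[["mS"]],
      R_translation = p$lambda_R * n[["mR"]],
      G_translation = p$lambda_G * n[["mR"]],
      R_decay = (p$delta_R + p$mu) * n[["R"]],
      G_decay = (p$delta_G + p$mu) * n[["G"]])
  }
  list(stoichiometry = S, reactions = reactions, propensity = propensity,
       omega = omega)
}

params_vec <- function(params) {
  unlist(unclass(params)[c("alpha_R", "beta_R", "K_TF", "n_act", "alpha_S",
                           "K_R", "n_rep", "k_pair", "delta_mR", "delta_mS",
                           "delta_R", "delta_G", "lambda_R", "lambda_G", "mu")])
}

#' Exact stochastic simulation of a single cell
#'
#' Gillespie direct-method simulation of the digitalizer network for one cell.
#' The random stream is derived from `(seed, cell_index)` by a counter hash,
#' so the same pair always reproduces the same trajectory and cells of a
#' population are independent regardless of simulation order. Piecewise
#' protocols are handled by re-drawing the waiting time at each breakpoint.
#'
#' @inheritParams build_reactions
#' @param protocol An [inducer_protocol()] or a constant `tf_a` level.
#' @param t_max Simulation horizon (min).
#' @param snapshot_times Times at which to report the state (default: a
#'   201-point grid over `[0, t_max]`). Must lie within `[0, t_max]`.
#' @param init Named initial counts (default: all zero).
#' @param seed Integer root seed of the population.
#' @param cell_index Positive integer identifying the cell within the population.
#' @param record_trajectory If `TRUE`, also return the full piecewise-constant
#'   event trajectory (one row per reaction event).
#' @param toxin_threshold If > 0, the cell dies (state frozen) the moment the
#'   `G` count reaches this threshold - the one-hit toxin abstraction.
#' @return A list of class `ssa_cell`: `snapshots` (tibble `time, mR, mS, R, G`),
#'   `alive`, `death_time`, and optionally `trajectory`.
#' @export
gillespie <- function(params, protocol, t_max, omega = 1,
                      snapshot_times = NULL, init = NULL, seed = 1,
                      cell_index = 1, record_trajectory = FALSE,
                      toxin_threshold = 0) {
  validate_params(params)
  protocol <- as_protocol(protocol)
  stopifnot(t_max > 0, omega > 0, cell_index >= 1)
  if (is.null(snapshot_times)) snapshot_times <- seq(0, t_max, length.out = 201)
  stopifnot(all(snapshot_times >= 0), all(snapshot_times <= t_max),
            !is.unsorted(snapshot_times))
  snapshot_times <- unique(c(snapshot_times, t_max))
  init <- if (is.null(init)) c(mR = 0, mS = 0, R = 0, G = 0) else as_state(init)
  out <- .ssa_cell(params_vec(params), omega, protocol$breakpoints,
                   protocol$levels, snapshot_times, init,
                   as.double(seed), as.double(cell_index),
                   as.double(toxin_threshold), record_trajectory)
  snaps <- tibble::as_tibble(as.data.frame(out$snapshots))
  names(snaps) <- c("mR", "mS", "R", "G")
  snaps <- dplyr::bind_cols(tibble::tibble(time = snapshot_times), snaps)
  res <- list(snapshots = snaps, alive = out$alive, death_time = out$death_time,
              omega = omega, seed = seed, cell_index = cell_index)
  if (record_trajectory) {
    res$trajectory <- tibble::as_tibble(as.data.frame(out$trajectory))
  }
  structure(res, class = "ssa_cell")
}

#' @export
print.ssa_cell <- function(x, ...) {
  cat("<ssa_cell> cell", x$cell_index, "seed", x$seed,
      if (!x$alive) sprintf("(dead at t = %.3g)", x$death_time) else "(alive)", "\n")
  print(x$snapshots)
  invisible(x)
}

#' Stochastic population snapshots
#'
#' Simulates `n_cells` independent cells with [gillespie()] streams and
#' reports every cell's counts at each snapshot time.
#'
#' @inheritParams gillespie
#' @param n_cells Number of independent cells.
#' @param snapshot_times Times (min) at which the population is sampled.
#' @return A tibble of class `population_snapshots` with columns `cell`,
#'   `time`, `mR`, `mS`, `R`, `G`, `alive`.
#' @export
simulate_population <- function(params, protocol, snapshot_times, n_cells,
                                omega = 1, init = NULL, seed = 1,
                                toxin_threshold = 0) {
  validate_params(params)
  protocol <- as_protocol(protocol)
  stopifnot(n_cells >= 1, all(snapshot_times >= 0), !is.unsorted(snapshot_times))
  init <- if (is.null(init)) c(mR = 0, mS = 0, R = 0, G = 0) else as_state(init)
  out <- .ssa_population(params_vec(params), omega, protocol$breakpoints,
                         protocol$levels, as.numeric(snapshot_times), init,
                         as.double(seed), as.double(n_cells),
                         as.double(toxin_threshold))
  st <- tibble::as_tibble(as.data.frame(out$states))
  st$alive <- out$alive[st$cell]
  structure(st, class = c("population_snapshots", class(st)),
            omega = omega, seed = seed)
}

#' One-hit toxin killing curve
#'
#' Survival fraction of a stochastic population as a function of inducer dose
#' when the GOI product is a one-hit toxin: a cell is dead as soon as its `G`
#' count ever reaches `threshold` (default one molecule) within `[0, t_max]`.
#' Dead cells stay in the survival denominator; escaper mutations are not
#' modelled.
#'
#' @inheritParams simulate_population
#' @param doses Inducer (`tf_a`) levels to test.
#' @param t_max Exposure window (min).
#' @param threshold Lethal `G` count (>= 1).
#' @return A tibble of class `survival_curve`: `dose`, `n_cells`, `survivors`,
#'   `survival`.
#' @export
one_hit_survival <- function(params, doses, t_max = 60, n_cells = 500,
                             omega = 1, threshold = 1, seed = 1, init = NULL) {
  validate_params(params)
  stopifnot(threshold >= 1, t_max > 0, n_cells >= 1)
  rows <- purrr::map_dfr(seq_along(doses), function(i) {
    pop <- simulate_population(params, doses[i], snapshot_times = c(0, t_max),
                               n_cells = n_cells, omega = omega, init = init,
                               seed = seed + (i - 1) * 1000003,
                               toxin_threshold = threshold)
    alive <- pop[pop$time == t_max, ]
    tibble::tibble(dose = doses[i], n_cells = n_cells,
                   survivors = sum(alive$alive), survival = mean(alive$alive))
  })
  structure(rows, class = c("survival_curve", class(rows)),
            t_max = t_max, threshold = threshold, omega = omega, seed = seed)
}
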