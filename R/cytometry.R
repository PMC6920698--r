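#' Measurement noise model for synthetic flow cytometry
#'
#' Parameters of the mapping from per-cell GOI molecule counts to
#' fluorescence in arbitrary units (AU):
#' `AU = gain * G * exp(eps) + A`, with extrinsic noise
#' `eps ~ Normal(0, sigma_ext)` and autofluorescence
#' `A ~ Lognormal(autofluor_mu, autofluor_sigma)`, clipped at the instrument
#' `floor`. The lognormal forms reproduce the right-skewed, log-scale unimodal
#' histograms typical of bacterial flow cytometry; the promoterless control
#' construct (G = 0) measures pure autofluorescence and defines the
#' no-fluorescence gate.
#'
#' @param gain AU per GOI molecule (> 0).
#' @param sigma_ext SD of the extrinsic lognormal noise (log-units, >= 0).
#' @param autofluor_mu,autofluor_sigma Meanlog and sdlog of the
#'   autofluorescence distribution (AU scale).
#' @param floor Instrument baseline (AU, >= 0).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(gain = 4, sigma_ext = 0.3,
                        autofluor_mu = log(100), autofluor_sigma = 0.4,
                        floor = 1) {
  stopifnot(gain > 0, sigma_ext >= 0, autofluor_sigma >= 0, floor >= 0)
  structure(list(gain = gain, sigma_ext = sigma_ext,
                 autofluor_mu = autofluor_mu, autofluor_sigma = autofluor_sigma,
                 floor = floor),
            class = "noise_model")
}

#' Per-cell fluorescence from molecule counts
#'
#' Applies the [noise_model()] mapping to a vector of per-cell `G` counts.
#' Seeded and reproducible; with both sigmas at zero the mapping is the
#' deterministic affine `gain * G + exp(autofluor_mu)` (clipped at the floor).
#'
#' @param G Non-negative per-cell molecule counts.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return Numeric vector of fluorescence values (AU), same length as `G`.
#' @export
fluorescence_model <- function(G, noise = noise_model(), seed = 1) {
  stopifnot(inherits(noise, "noise_model"), is.numeric(G))
  if (any(!is.finite(G)) || any(G < 0)) {
    stop("G counts must be finite and non-negative", call. = FALSE)
  }
  n <- length(G)
  au <- local_seed(seed, {
    eps <- if (noise$sigma_ext > 0) stats::rnorm(n, 0, noise$sigma_ext) else numeric(n)
    A <- if (noise$autofluor_sigma > 0) {
      stats::rlnorm(n, noise$autofluor_mu, noise$autofluor_sigma)
    } else {
      rep(exp(noise$autofluor_mu), n)
    }
    noise$gain * G * exp(eps) + A
  })
  pmax(au, noise$floor)
}

local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Experimental design of a synthetic flow-cytometry run
#'
#' The full-factorial design of constructs x doses x times, mirroring the
#' study layout: three constructs (digitalized, non-digitalized parent and
#' promoterless autofluorescence control), inducer doses spanning the
#' dose-response range, and snapshot times from induction (t = 0) to late
#' stationary phase (24 h).
#'
#' @param constructs Subset of `c("digitalized", "non_digitalized", "promoterless")`.
#' @param doses Inducer doses (nM active-TF equivalents).
#' @param times Snapshot times (min).
#' @return A tibble with one row per condition.
#' @export
flow_design <- function(constructs = c("digitalized", "non_digitalized", "promoterless"),
                        doses = c(0, 10, 50, 200, 1000),
                        times = c(0, 5, 20, 60, 160, 1440)) {
  stopifnot(all(constructs %in% c("digitalized", "non_digitalized", "promoterless")))
  tidyr::expand_grid(construct = constructs, dose = doses, time = times)
}

#' Generate a synthetic flow-cytometry event table
#'
#' Simulates every condition of the design and converts per-cell `G` to
#' fluorescence with the noise model. Two simulation backends are available:
#' `"ode"` (default) computes the population-mean `G(t)` from the ODE model
#' and lets the lognormal measurement layer carry the cell-to-cell
#' variability - appropriate at the molecule numbers of a strong reporter,
#' where intrinsic noise is dwarfed by extrinsic noise; `"ssa"` simulates
#' every cell with [gillespie()] (slower, adds intrinsic noise). Cells start
#' from the construct's uninduced steady state, as cultures grown without
#' inducer do.
#'
#' @param design A [flow_design()] tibble.
#' @param base A `digitalizer_params` baseline from which the three construct
#'   presets are derived (see [construct_params()]).
#' @param n_events Cells per condition (study default: 25000).
#' @param noise A [noise_model()].
#' @param omega Molecules per nM for the count conversion.
#' @param seed Integer seed; every condition derives an independent stream.
#' @param backend `"ode"` or `"ssa"`.
#' @param scenario Passed to [construct_params()].
#' @param init_state `"zero"` (default) starts every cell reporter-free, as in
#'   a freshly diluted outgrowth where previously accumulated reporter has
#'   been diluted away - uninduced cultures then accumulate their basal signal
#'   over the time course; `"basal"` starts cells at the construct's uninduced
#'   steady state.
#' @return A tibble of class `event_table` with columns `cell_id`, `construct`,
#'   `dose`, `time`, `fluorescence`, `alive`.
#' @export
generate_flow_experiment <- function(design = flow_design(),
                                     base = digitalizer_params(),
                                     n_events = 25000,
                                     noise = noise_model(),
                                     omega = 1, seed = 1,
                                     backend = c("ode", "ssa"),
                                     scenario = "xyls_pm",
                                     init_state = c("zero", "basal")) {
  backend <- match.arg(backend)
  init_state <- match.arg(init_state)
  stopifnot(is.data.frame(design),
            all(c("construct", "dose", "time") %in% names(design)),
            n_events >= 1)
  bad <- setdiff(unique(design$construct),
                 c("digitalized", "non_digitalized", "promoterless"))
  if (length(bad)) {
    stop("unknown construct label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  params_of <- lapply(stats::setNames(nm = unique(design$construct)),
                      function(cn) construct_params(cn, base, scenario))
  conds <- dplyr::distinct(design, .data$construct, .data$dose)
  rows <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    cn <- conds$construct[i]; dose <- conds$dose[i]
    p <- params_of[[cn]]
    times <- sort(unique(design$time[design$construct == cn & design$dose == dose]))
    cond_seed <- (seed + 7919 * i) %% .Machine$integer.max
    if (backend == "ode") {
      init <- if (init_state == "basal") steady_state(p, 0) else NULL
      tgrid <- unique(sort(c(0, times)))
      tc <- if (length(tgrid) >= 2) {
        simulate_ode(p, dose, tgrid, init = init)
      } else {
        tibble::tibble(time = tgrid,
                       G = if (is.null(init)) 0 else init[["G"]])
      }
      G_mean <- tc$G[match(times, tc$time)] * omega
      per_time <- lapply(seq_along(times), function(k) {
        au <- fluorescence_model(rep(G_mean[k], n_events), noise,
                                 seed = cond_seed + k)
        tibble::tibble(cell_id = seq_len(n_events), construct = cn, dose = dose,
                       time = times[k], fluorescence = au, alive = TRUE)
      })
      rows[[i]] <- dplyr::bind_rows(per_time)
    } else {
      init <- if (init_state == "basal") round(steady_state(p, 0) * omega) else
        NULL
      pop <- simulate_population(p, dose, snapshot_times = times,
                                 n_cells = n_events, omega = omega,
                                 init = init, seed = cond_seed)
      au <- unlist(lapply(seq_along(times), function(k) {
        g <- pop$G[pop$time == times[k]]
        fluorescence_model(g, noise, seed = cond_seed + k)
      }))
      rows[[i]] <- tibble::tibble(
        cell_id = rep(seq_len(n_events), times = length(times)),
        construct = cn, dose = dose,
        time = rep(times, each = n_events),
        fluorescence = au,
        alive = rep(pop$alive[match(seq_len(n_events), pop$cell)],
                    times = length(times)))
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("event_table", class(out)),
            noise = noise, omega = omega, seed = seed, backend = backend)
}

#' Write and read event tables as CSV
#'
#' Plain-CSV round trip for [generate_flow_experiment()] output, with the
#' canonical header `cell_id, construct, dose_nM, time_min, fluorescence_au,
#' alive`.
#'
#' @param events An event table tibble.
#' @param path File path.
#' @export
write_event_csv <- function(events, path) {
  stopifnot(all(c("cell_id", "construct", "dose", "time", "fluorescence",
                  "alive") %in% names(events)))
  df <- data.frame(cell_id = events$cell_id, construct = events$construct,
                   dose_nM = events$dose, time_min = events$time,
                   fluorescence_au = events$fluorescence, alive = events$alive)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_csv
#' @return `read_event_csv()`: an `event_table` tibble.
#' @export
read_event_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "construct", "dose_nM", "time_min", "fluorescence_au", "alive")
  if (!all(need %in% names(df))) {
    stop("event CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(cell_id = df$cell_id, construct = df$construct,
                        dose = df$dose_nM, time = df$time_min,
                        fluorescence = df$fluorescence_au,
                        alive = as.logical(df$alive))
  structure(out, class = c("event_table", class(out)))
}

#' Synthetic plate-reader growth and fluorescence table
#'
#' Bulk-culture counterpart of the flow experiment: optical density follows
#' logistic growth, bulk fluorescence is the cell density times the mean
#' per-cell fluorescence from the ODE model plus autofluorescence, and the
#' reported `fluorescence_per_od` normalises out growth, as plate-reader
#' dose-response experiments do.
#'
#' @inheritParams generate_flow_experiment
#' @param growth List with `r` (1/min) and `K_od` (carrying capacity, OD600),
#'   plus optional `od0` (initial OD600, default 0.05).
#' @param times Measurement times (min).
#' @param cells_per_od Scaling from OD600 to relative cell density (only sets
#'   the bulk AU scale).
#' @return A tibble with columns `construct`, `dose`, `time`, `od600`,
#'   `fluorescence`, `fluorescence_per_od`.
#' @export
generate_platereader <- function(design = flow_design(times = seq(0, 720, by = 60)),
                                 base = digitalizer_params(),
                                 growth = list(r = 0.023, K_od = 4, od0 = 0.05),
                                 noise = noise_model(sigma_ext = 0),
                                 omega = 1, cells_per_od = 1,
                                 seed = 1) {
  stopifnot(growth$r > 0, growth$K_od > 0)
  od0 <- if (is.null(growth$od0)) 0.05 else growth$od0
  od_at <- function(t) {
    growth$K_od / (1 + (growth$K_od / od0 - 1) * exp(-growth$r * t))
  }
  autofluor_mean <- exp(noise$autofluor_mu + noise$autofluor_sigma^2 / 2)
  conds <- dplyr::distinct(design, .data$construct, .data$dose)
  rows <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    cn <- conds$construct[i]; dose <- conds$dose[i]
    p <- construct_params(cn, base)
    times <- sort(unique(design$time[design$construct == cn & design$dose == dose]))
    init <- steady_state(p, 0)
    tgrid <- unique(sort(c(0, times)))
    tc <- if (length(tgrid) >= 2) simulate_ode(p, dose, tgrid, init = init) else
      tibble::tibble(time = tgrid, G = init[["G"]])
    G_mean <- tc$G[match(times, tc$time)] * omega
    per_cell_au <- noise$gain * G_mean * exp(noise$sigma_ext^2 / 2) + autofluor_mean
    od <- od_at(times)
    bulk <- od * cells_per_od * per_cell_au
    rows[[i]] <- tibble::tibble(construct = cn, dose = dose, time = times,
                                od600 = od, fluorescence = bulk,
                                fluorescence_per_od = bulk / od)
  }
  dplyr::bind_rows(rows)
}
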