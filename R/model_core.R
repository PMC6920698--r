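#' Right-hand side of the digitalizer ODE system
#'
#' Time derivatives of the four circuit species at a given state and active-TF
#' input. The model couples an inducible operon mRNA (`mR`, encoding both the
#' repressor and the gene of interest), a translation-inhibitory sRNA (`mS`)
#' transcribed from a repressible promoter, the repressor protein (`R`) and the
#' GOI product (`G`):
#'
#' \deqn{dmR/dt = \beta_R + \alpha_R h^+(TF_a) - (\delta_{mR}+\mu) mR - k_{pair} mR\, mS}
#' \deqn{dmS/dt = \alpha_S h^-(R) - (\delta_{mS}+\mu) mS - k_{pair} mR\, mS}
#' \deqn{dR/dt  = \lambda_R mR - (\delta_R+\mu) R}
#' \deqn{dG/dt  = \lambda_G mR - (\delta_G+\mu) G}
#'
#' where \eqn{h^+} is [hill_activation()] with `(K_TF, n_act)` and \eqn{h^-}
#' is [hill_repression()] with `(K_R, n_rep)`. The bimolecular pairing term
#' removes one mR and one mS per event, so it appears with identical magnitude
#' in both RNA equations.
#'
#' @param state Named numeric vector or list with components `mR`, `mS`, `R`,
#'   `G` (nM, all >= 0).
#' @param params A [digitalizer_params()] object.
#' @param tf_a Active transcription-factor concentration (nM); the external input.
#' @return Named numeric vector of derivatives over `(mR, mS, R, G)` (nM/min).
#' @export
digitalizer_derivatives <- function(state, params, tf_a) {
  validate_params(params)
  s <- unlist(state)[c("mR", "mS", "R", "G")]
  if (any(is.na(s))) stop("state must contain mR, mS, R, G", call. = FALSE)
  if (any(!is.finite(s)) || any(s < -1e-9)) {
    stop("species concentrations must be finite and non-negative", call. = FALSE)
  }
  s <- pmax(s, 0)
  if (!is.finite(tf_a) || tf_a < 0) {
    stop("tf_a must be finite and non-negative", call. = FALSE)
  }
  p <- params
  pair <- p$k_pair * s[["mR"]] * s[["mS"]]
  c(mR = p$beta_R + p$alpha_R * hill_activation(tf_a, p$K_TF, p$n_act) -
        (p$delta_mR + p$mu) * s[["mR"]] - pair,
    mS = p$alpha_S * hill_repression(s[["R"]], p$K_R, p$n_rep) -
        (p$delta_mS + p$mu) * s[["mS"]] - pair,
    R = p$lambda_R * s[["mR"]] - (p$delta_R + p$mu) * s[["R"]],
    G = p$lambda_G * s[["mR"]] - (p$delta_G + p$mu) * s[["G"]])
}

#' Closed-form steady state of the unpaired (k_pair = 0) cascade
#'
#' With the pairing rate set to zero the circuit is a feed-forward cascade and
#' its unique steady state has the closed form
#' \eqn{mR^* = (\beta_R + \alpha_R h^+(TF_a))/(\delta_{mR}+\mu)},
#' \eqn{R^* = \lambda_R mR^*/(\delta_R+\mu)},
#' \eqn{G^* = \lambda_G mR^*/(\delta_G+\mu)},
#' \eqn{mS^* = \alpha_S h^-(R^*)/(\delta_{mS}+\mu)}.
#' Used throughout the package as the independent oracle for the numerical
#' steady-state solver.
#'
#' @inheritParams digitalizer_derivatives
#' @return Named numeric vector `(mR, mS, R, G)` at steady state.
#' @export
steady_state_unpaired <- function(params, tf_a) {
  validate_params(params)
  if (params$k_pair != 0) {
    stop("steady_state_unpaired() requires k_pair = 0; use steady_state() otherwise",
         call. = FALSE)
  }
  dec <- unlist(params[c("delta_mR", "delta_mS", "delta_R", "delta_G")]) + params$mu
  if (any(dec <= 0)) {
    stop("all effective decay rates (delta + mu) must be > 0", call. = FALSE)
  }
  mR <- (params$beta_R + params$alpha_R * hill_activation(tf_a, params$K_TF, params$n_act)) /
    (params$delta_mR + params$mu)
  R <- params$lambda_R * mR / (params$delta_R + params$mu)
  G <- params$lambda_G * mR / (params$delta_G + params$mu)
  mS <- params$alpha_S * hill_repression(R, params$K_R, params$n_rep) /
    (params$delta_mS + params$mu)
  c(mR = mR, mS = mS, R = R, G = G)
}

#' Piecewise-constant inducer protocols
#'
#' Encodes the active-TF input as a step function: `levels[i]` holds on the
#' half-open interval `[breakpoints[i], breakpoints[i+1])`, and the last level
#' holds indefinitely. A constant input is a single breakpoint at time 0.
#'
#' @param breakpoints Strictly increasing times (min); the first is the start
#'   of the experiment.
#' @param levels Non-negative `tf_a` values (nM), one per breakpoint.
#' @return An object of class `inducer_protocol`.
#' @examples
#' inducer_protocol(0, 1000)                 # constant full induction
#' inducer_protocol(c(0, 180), c(1000, 0))   # induce, then remove at t = 180
#' @export
inducer_protocol <- function(breakpoints, levels) {
  stopifnot(is.numeric(breakpoints), is.numeric(levels),
            length(breakpoints) == length(levels), length(levels) >= 1)
  if (any(diff(breakpoints) <= 0)) {
    stop("breakpoints must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(levels)) || any(levels < 0)) {
    stop("levels must be finite and non-negative", call. = FALSE)
  }
  structure(list(breakpoints = as.numeric(breakpoints),
                 levels = as.numeric(levels)),
            class = "inducer_protocol")
}

#' @export
print.inducer_protocol <- function(x, ...) {
  cat("<inducer_protocol>\n")
  print(tibble::tibble(from = x$breakpoints, tf_a = x$levels))
  invisible(x)
}

protocol_level_at <- function(protocol, t) {
  i <- findInterval(t, protocol$breakpoints)
  if (any(i < 1)) stop("time before first protocol breakpoint", call. = FALSE)
  protocol$levels[i]
}

as_protocol <- function(x) {
  if (inherits(x, "inducer_protocol")) return(x)
  if (is.numeric(x) && length(x) == 1) return(inducer_protocol(0, x))
  stop("expected an inducer_protocol or a single constant tf_a level", call. = FALSE)
}
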