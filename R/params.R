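#' Kinetic parameters of the digitalizer circuit
#'
#' Constructs and validates the full kinetic parameter set of the
#' digitalizer model. All concentrations are in nM and all times in minutes.
#' Calling `digitalizer_params()` with no arguments returns the package
#' baseline: an operating point in the sRNA threshold-linear regime, where the
#' sRNA synthesis rate `alpha_S` lies between the basal (`beta_R`) and fully
#' induced (`beta_R + alpha_R`) mRNA synthesis rates, so the uninduced circuit
#' sits far below the sRNA supply (digital OFF) while induction can outrun it
#' (switch ON). See the package vignette for the derivation of the baseline.
#'
#' @param alpha_R Maximal transcription rate of the inducible promoter P1 (nM/min).
#' @param beta_R Basal (uninduced) transcription rate of P1 (nM/min).
#' @param K_TF Half-activation constant of P1 by active TF (nM).
#' @param n_act Activation Hill coefficient (>= 1).
#' @param alpha_S Maximal transcription rate of the repressible sRNA promoter P2 (nM/min).
#' @param K_R Half-repression constant of P2 by repressor R (nM).
#' @param n_rep Repression Hill coefficient (>= 1).
#' @param k_pair Bimolecular mR-mS pairing/co-degradation rate (1/(nM min)).
#' @param delta_mR,delta_mS First-order decay rates of mR and mS (1/min).
#' @param delta_R,delta_G First-order decay rates of the repressor and GOI
#'   product (1/min); for stable proteins these act as effective
#'   dilution-by-growth rates.
#' @param lambda_R,lambda_G Translation rates of R and of the GOI product per
#'   mR molecule (1/min).
#' @param mu Optional extra dilution rate applied to every species (1/min).
#'   The default 0 reproduces the growth-free model.
#' @return A named list of class `digitalizer_params`.
#' @seealso [construct_params()] for the three experimental construct presets,
#'   [scale_repression()] for the joint repression-strength scaling.
#' @export
digitalizer_params <- function(alpha_R = 10,
                               beta_R = 0.075,
                               K_TF = 100,
                               n_act = 2,
                               alpha_S = 5,
                               K_R = 5000,
                               n_rep = 2,
                               k_pair = 1,
                               delta_mR = 0.2,
                               delta_mS = 0.2,
                               delta_R = 0.01,
                               delta_G = 0.01,
                               lambda_R = 2,
                               lambda_G = 2,
                               mu = 0) {
  p <- list(alpha_R = alpha_R, beta_R = beta_R, K_TF = K_TF, n_act = n_act,
            alpha_S = alpha_S, K_R = K_R, n_rep = n_rep, k_pair = k_pair,
            delta_mR = delta_mR, delta_mS = delta_mS, delta_R = delta_R,
            delta_G = delta_G, lambda_R = lambda_R, lambda_G = lambda_G,
            mu = mu)
  validate_params(p)
  structure(p, class = "digitalizer_params")
}

validate_params <- function(p) {
  need <- c("alpha_R", "beta_R", "K_TF", "n_act", "alpha_S", "K_R", "n_rep",
            "k_pair", "delta_mR", "delta_mS", "delta_R", "delta_G",
            "lambda_R", "lambda_G", "mu")
  missing <- setdiff(need, names(p))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(p[need])
  if (any(!is.finite(vals))) stop("all parameters must be finite", call. = FALSE)
  if (any(vals < 0)) stop("all rates and constants must be >= 0", call. = FALSE)
  if (p$n_act < 1 || p$n_rep < 1) stop("Hill coefficients must be >= 1", call. = FALSE)
  if (p$K_TF <= 0 || p$K_R <= 0) stop("K_TF and K_R must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.digitalizer_params <- function(x, ...) {
  cat("<digitalizer_params>\n")
  print(tibble::as_tibble(unclass(x)[lengths(unclass(x)) == 1L]))
  invisible(x)
}

#' Construct presets used in the benchmarking experiments
#'
#' The three constructs measured against each other in the study design:
#' the full digitalized device, the non-digitalized parent (no sRNA cassette,
#' `alpha_S = 0`), and the promoterless fluorescence control
#' (`alpha_R = beta_R = 0`), which defines the autofluorescence-only
#' no-fluorescence gate.
#'
#' The `"alks_palkb"` scenario raises the basal rate `beta_R` five-fold over
#' the default `"xyls_pm"` scenario, mimicking an expression system with a
#' conspicuously leakier principal promoter; it is intended for qualitative
#' scenario exploration only.
#'
#' @param construct One of `"digitalized"`, `"non_digitalized"`, `"promoterless"`.
#' @param base A `digitalizer_params` object to start from (default: package baseline).
#' @param scenario `"xyls_pm"` (default) or `"alks_palkb"` (five-fold basal rate).
#' @return A `digitalizer_params` object.
#' @export
construct_params <- function(construct = c("digitalized", "non_digitalized", "promoterless"),
                             base = digitalizer_params(),
                             scenario = c("xyls_pm", "alks_palkb")) {
  construct <- match.arg(construct)
  scenario <- match.arg(scenario)
  p <- unclass(base)
  if (scenario == "alks_palkb") p$beta_R <- p$beta_R * 5
  if (construct == "non_digitalized") {
    p$alpha_S <- 0
  } else if (construct == "promoterless") {
    p$alpha_R <- 0
    p$beta_R <- 0
  }
  validate_params(p)
  structure(p, class = "digitalizer_params")
}

#' Scale the joint strength of both repression arms
#'
#' Multiplies the sRNA pairing rate `k_pair` by `s` and divides the
#' transcriptional half-repression constant `K_R` by `s`, so a single factor
#' moves both arms of the mutual-inhibition switch from "very weak"
#' (`s << 1`) to "very strong" (`s >> 1`). This is the colour axis of the
#' repression sweep.
#'
#' @param params A `digitalizer_params` object.
#' @param s Positive scale factor.
#' @return A `digitalizer_params` object.
#' @export
scale_repression <- function(params, s) {
  stopifnot(inherits(params, "digitalizer_params"), is.numeric(s), s > 0,
            is.finite(s))
  p <- unclass(params)
  p$k_pair <- p$k_pair * s
  p$K_R <- p$K_R / s
  structure(p, class = "digitalizer_params")
}
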