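#' Hill activation and repression functions
#'
#' The two regulatory input functions of the digitalizer circuit. `hill_activation()`
#' is the fraction of maximal activity of the inducible promoter P1 at an active
#' transcription-factor concentration `x`; `hill_repression()` is the fraction of
#' maximal activity of the repressible sRNA promoter P2 left at repressor
#' concentration `r`. They are complementary: `hill_repression(r, K, n)` equals
#' `1 - hill_activation(r, K, n)`.
#'
#' @param x,r Non-negative concentration (nM). Vectorised.
#' @param K Half-activation (or half-repression) constant, > 0 (nM).
#' @param n Hill coefficient, >= 1.
#' @return A fraction in `[0, 1]`, same length as `x`/`r`.
#' @examples
#' hill_activation(10, K = 5, n = 2) # 0.8
#' hill_repression(3, K = 1, n = 2)  # 0.1
#' @export
hill_activation <- function(x, K, n) {
  stopifnot(is.numeric(x), is.numeric(K), is.numeric(n))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("hill_activation(): `x` must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("hill_activation(): `K` must be finite and positive", call. = FALSE)
  }
  if (any(n < 1)) stop("hill_activation(): `n` must be >= 1", call. = FALSE)
  # (x/K)^n form avoids overflow for large x
  xn <- (x / K)^n
  xn / (1 + xn)
}

#' @rdname hill_activation
#' @export
hill_repression <- function(r, K, n) {
  1 - hill_activation(r, K, n)
}
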