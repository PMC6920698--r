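#' Recover kinetic parameters from summarized time courses
#'
#' Fits selected model parameters to observed median fluorescence over a
#' (dose, time) design by bounded multi-start least squares on log-scale
#' medians. The model median is `gain * G_ode(t, dose) + median(A)` where
#' `G_ode` is the deterministic GOI trajectory from the construct's uninduced
#' steady state and `median(A) = exp(autofluor_mu)` is the autofluorescence
#' median; the loss is `sum((log median_model - log median_obs)^2)`.
#' Fluorescence spans decades, hence log residuals; the search runs in log
#' parameter space from `n_starts` log-uniform starting points within the
#' bounds, refined by `stats::nlminb()`.
#'
#' `gain` and `lambda_G` are perfectly confounded (the observable is their
#' product), so fitting both jointly is refused.
#'
#' @param observed A tibble with columns `dose`, `time`, `median_au` (a
#'   [summarize_cytometry()] output, possibly filtered to one construct);
#'   must cover at least 2 doses and 2 times.
#' @param free Character vector of parameter names to fit (subset of
#'   [digitalizer_params()] fields, plus optionally `"gain"`).
#' @param fixed A `digitalizer_params` object providing every non-free
#'   parameter.
#' @param noise The [noise_model()] assumed for the measurement layer (its
#'   `gain` is used unless `"gain"` is free).
#' @param lower,upper Named bounds for the free parameters; defaults span
#'   two decades around the values in `fixed`.
#' @param n_starts Number of log-uniform multi-start points.
#' @param seed Integer seed controlling the start draws.
#' @param omega Molecules per nM (count scale of the medians).
#' @return An object of class `digitalizer_fit`: list with `estimates`,
#'   `loss`, `n_starts`, `converged` (per start), `best_start`, `starts`
#'   (tibble of per-start diagnostics), and the fitting context.
#' @export
fit_parameters <- function(observed, free, fixed = digitalizer_params(),
                           noise = noise_model(), lower = NULL, upper = NULL,
                           n_starts = 10, seed = 1, omega = 1) {
  stopifnot(is.data.frame(observed),
            all(c("dose", "time", "median_au") %in% names(observed)))
  if (length(unique(observed$dose)) < 2 || length(unique(observed$time)) < 2) {
    stop("observed must cover at least 2 doses and 2 times", call. = FALSE)
  }
  allowed <- c(names(formals(digitalizer_params)), "gain")
  if (!all(free %in% allowed)) {
    stop("free must be a subset of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  if (all(c("gain", "lambda_G") %in% free)) {
    stop("`gain` and `lambda_G` are perfectly confounded (only their product ",
         "is observable); fit at most one of them", call. = FALSE)
  }
  obs <- observed[is.finite(observed$median_au) & observed$median_au > 0, ]
  doses <- sort(unique(obs$dose))
  times <- sort(unique(obs$time))
  if (!length(free)) {
    # nothing to fit: report the residual loss of the fixed parameter set
    loss0 <- local({
      autofluor_med <- exp(noise$autofluor_mu)
      tgrid <- unique(sort(c(0, times)))
      tot <- 0
      for (d in doses) {
        tc <- simulate_ode(fixed, d, tgrid)
        med <- noise$gain * tc$G[match(times, tc$time)] * omega + autofluor_med
        o <- obs[obs$dose == d, ]
        tot <- tot + sum((log(med[match(o$time, times)]) - log(o$median_au))^2)
      }
      tot
    })
    return(structure(list(estimates = stats::setNames(numeric(0), character(0)),
                          loss = loss0, n_starts = 0L, converged = logical(0),
                          best_start = NA_integer_,
                          starts = tibble::tibble(start = integer(0),
                                                  objective = numeric(0),
                                                  converged = logical(0)),
                          free = character(0), lower = numeric(0),
                          upper = numeric(0), fixed = fixed, noise = noise,
                          seed = seed),
                     class = "digitalizer_fit"))
  }

  base_vals <- c(unlist(unclass(fixed)), gain = noise$gain)
  default_bound <- function(side) {
    vapply(free, function(nm) {
      v <- base_vals[[nm]]
      if (v <= 0) v <- 1e-3  # zero-valued parameters get a generic span
      if (side == "lo") v / 10 else v * 10
    }, numeric(1))
  }
  lo <- default_bound("lo"); hi <- default_bound("hi")
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)
  if (any(lo <= 0) || any(hi <= lo)) {
    stop("bounds must satisfy 0 < lower < upper (log-scale search)", call. = FALSE)
  }

  autofluor_med <- exp(noise$autofluor_mu)
  model_medians <- function(theta) {
    vals <- as.list(theta)
    gain <- if ("gain" %in% names(vals)) vals$gain else noise$gain
    p <- utils::modifyList(unclass(fixed), vals[setdiff(names(vals), "gain")])
    p <- tryCatch(do.call(digitalizer_params, p), error = function(e) NULL)
    if (is.null(p)) return(NULL)
    # cells start reporter-free, matching generate_flow_experiment()'s default
    tgrid <- unique(sort(c(0, times)))
    med <- matrix(NA_real_, length(doses), length(times),
                  dimnames = list(doses, times))
    for (i in seq_along(doses)) {
      tc <- tryCatch(simulate_ode(p, doses[i], tgrid),
                     error = function(e) NULL)
      if (is.null(tc)) return(NULL)
      med[i, ] <- gain * tc$G[match(times, tc$time)] * omega + autofluor_med
    }
    med
  }
  loss_fn <- function(log_theta) {
    theta <- stats::setNames(exp(log_theta), free)
    med <- model_medians(theta)
    if (is.null(med)) return(1e10)
    r <- log(med[cbind(match(obs$dose, doses), match(obs$time, times))]) -
      log(obs$median_au)
    sum(r^2)
  }

  starts <- local_seed(seed, {
    m <- matrix(stats::runif(n_starts * length(free)), n_starts, length(free))
    sweep(sweep(m, 2, log(hi) - log(lo), "*"), 2, log(lo), "+")
  })
  colnames(starts) <- free

  fits <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    fits[[k]] <- tryCatch(
      stats::nlminb(starts[k, ], loss_fn, lower = log(lo), upper = log(hi),
                    control = list(eval.max = 400, iter.max = 300)),
      error = function(e) list(objective = Inf, convergence = 1L,
                               par = starts[k, ], message = conditionMessage(e)))
  }
  objectives <- vapply(fits, function(f) f$objective, numeric(1))
  converged <- vapply(fits, function(f) isTRUE(f$convergence == 0), logical(1))
  if (all(!is.finite(objectives))) {
    diag <- paste(sprintf("start %d: %s", seq_len(n_starts),
                          vapply(fits, function(f) f$message %||% "?", "")),
                  collapse = "; ")
    stop("all optimizer starts failed: ", diag, call. = FALSE)
  }
  best <- which.min(objectives)
  estimates <- stats::setNames(exp(fits[[best]]$par), free)
  structure(list(
    estimates = estimates,
    loss = objectives[best],
    n_starts = n_starts,
    converged = converged,
    best_start = best,
    starts = tibble::tibble(start = seq_len(n_starts),
                            objective = objectives, converged = converged),
    free = free, lower = lo, upper = hi, fixed = fixed, noise = noise,
    seed = seed),
    class = "digitalizer_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.digitalizer_fit <- function(x, ...) {
  cat("<digitalizer_fit>", x$n_starts, "starts, best loss",
      format(x$loss, digits = 4), "\n")
  print(tibble::tibble(parameter = names(x$estimates),
                       estimate = unname(x$estimates),
                       lower = unname(x$lower), upper = unname(x$upper)))
  invisible(x)
}

#' Tidy a digitalizer fit
#'
#' `tidy()` returns one row per fitted parameter; `glance()` returns a
#' one-row model-level summary.
#'
#' @param x A `digitalizer_fit` object.
#' @param ... Unused.
#' @export
tidy.digitalizer_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates),
                 lower = unname(x$lower),
                 upper = unname(x$upper))
}

#' @rdname tidy.digitalizer_fit
#' @export
glance.digitalizer_fit <- function(x, ...) {
  tibble::tibble(loss = x$loss, n_starts = x$n_starts,
                 n_converged = sum(x$converged), best_start = x$best_start)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
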