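# Direct nonlinear estimation by minimization of Marquardt's percent
# standard deviation (MPSD), with a deterministic multistart schedule.

#' Marquardt's percent standard deviation (MPSD)
#'
#' The relative-error objective minimized by the nonlinear estimation path:
#' `100 * sqrt( (1 / (n - p)) * sum(((qe_exp - qe_calc) / qe_exp)^2) )`,
#' where `n` is the number of points and `p` the number of model parameters.
#' Scale-invariant: multiplying both inputs by the same positive constant
#' leaves it unchanged.
#'
#' @param qe_exp Observed adsorbed amounts (mg/g), all > 0.
#' @param qe_calc Model-predicted adsorbed amounts (mg/g), same length.
#' @param p Number of fitted model parameters (`n > p` required).
#' @return The MPSD value (dimensionless, conventionally quoted x100).
#' @examples
#' mpsd(c(100, 200), c(90, 210), p = 1)
#' @export
mpsd <- function(qe_exp, qe_calc, p) {
  n <- length(qe_exp)
  if (length(qe_calc) != n) {
    abort("`qe_exp` and `qe_calc` must have equal length.",
          class = "sorbkit_error_input")
  }
  if (any(!is.finite(qe_exp)) || any(qe_exp <= 0)) {
    abort("MPSD needs all observed Qe > 0 (relative error is undefined).",
          class = "sorbkit_error_domain")
  }
  if (n <= p) {
    abort(paste0("MPSD needs n > p (got n = ", n, ", p = ", p, ")."),
          class = "sorbkit_error_input")
  }
  100 * sqrt(sum(((qe_exp - qe_calc) / qe_exp)^2) / (n - p))
}

# Evaluate the RNG-consuming `code` under `seed`, restoring the caller's
# RNG state afterwards (keeps fits deterministic without global side effects).
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Heuristic starting values when a linear-method seed is unavailable.
heuristic_start <- function(family, data, temp_k, cs) {
  qtop <- max(data$qe) * 1.25
  cmid <- stats::median(data$ce)
  switch(family,
    langmuir = c(q_max = qtop, k_l = 1 / cmid),
    freundlich = c(k_f = max(stats::median(data$qe / sqrt(data$ce)), 1e-12),
                   n_f = 2),
    redlich_peterson = c(k_rp = 2 * max(data$qe / data$ce),
                         a_rp = max(data$qe / data$ce) / qtop, beta = 0.9),
    temkin = c(k_t = 1 / cmid,
               b_t = GAS_CONSTANT * temp_k / max(stats::sd(data$qe), 1e-9)),
    dubinin_radushkevich = {
      eps <- polanyi_potential(data$ce, cs, temp_k)
      c(q_max = qtop, k_dr = log(2) / stats::median(eps)^2)
    },
    dubinin_astakhov = {
      eps <- polanyi_potential(data$ce, cs, temp_k)
      c(q_max = qtop, k_da = log(2) / stats::median(eps)^2, n_da = 2)
    }
  )
}

# Box bounds on log-parameters (shape parameters carry real constraints;
# positive parameters are effectively unbounded on the log scale).
log_bounds <- function(family) {
  info <- family_registry()[[family]]
  k <- length(info$pars)
  lower <- rep(-690, k)
  upper <- rep(690, k)
  names(lower) <- names(upper) <- info$pars
  if (family == "redlich_peterson") upper["beta"] <- 0 # beta <= 1
  if (family == "freundlich") lower["n_f"] <- 0        # n_f >= 1
  if (family == "dubinin_astakhov") {
    lower["n_da"] <- 0
    upper["n_da"] <- log(6)
  }
  list(lower = lower, upper = upper)
}

# Deterministic multistart schedule: the linear-method estimate (when it
# exists) plus `n_starts` seeded log-perturbations of it (a full decade on
# rate constants, +/-50% on capacities, mild jitter on shape exponents).
multistart_points <- function(family, base, control) {
  info <- family_registry()[[family]]
  bb <- log_bounds(family)
  starts <- list(log(base))
  perturbed <- with_local_seed(control$seed, {
    lapply(seq_len(control$n_starts), function(i) {
      th <- log(base)
      for (pn in info$rate) th[pn] <- th[pn] + stats::runif(1, -1, 1) * log(10)
      for (pn in info$cap) th[pn] <- th[pn] + log1p(stats::runif(1, -0.5, 0.5))
      for (pn in info$shape) th[pn] <- th[pn] + stats::runif(1, -0.2, 0.2)
      pmin(pmax(th, bb$lower), bb$upper)
    })
  })
  c(starts, perturbed)
}

# Core MPSD minimization for one family. Returns params, mpsd and
# convergence details; errors if every start fails.
nonlinear_optimize <- function(family, data, temp_k, cs, start, control) {
  info <- family_registry()[[family]]
  p <- length(info$pars)
  bb <- log_bounds(family)
  objective <- function(theta) {
    pars <- exp(theta)
    names(pars) <- info$pars
    qcalc <- tryCatch(
      predict_qe(family, pars, data$ce, temp_k = temp_k, cs = cs),
      error = function(e) rep(NA_real_, nrow(data)),
      warning = function(w) suppressWarnings(
        predict_qe(family, pars, data$ce, temp_k = temp_k, cs = cs))
    )
    if (any(!is.finite(qcalc))) return(1e10)
    mpsd(data$qe, qcalc, p)
  }
  starts <- multistart_points(family, start, control)
  best <- NULL
  for (th0 in starts) {
    res <- tryCatch(
      stats::nlminb(
        th0, objective, lower = bb$lower, upper = bb$upper,
        control = list(eval.max = 5000, iter.max = 2000,
                       rel.tol = control$tol_mpsd, x.tol = control$tol_param)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) {
    abort(paste0("Nonlinear MPSD optimization failed for every start (",
                 family, ")."), class = "sorbkit_error_fit")
  }
  pars <- exp(best$par)
  names(pars) <- info$pars
  list(params = pars, mpsd = best$objective, convergence = best$convergence)
}
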