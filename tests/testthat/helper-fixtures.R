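# Shared fixtures: reference parameter sets, noiseless dataset builders,
# and the exhaustive-grid profile oracle used to validate the embedded
# 1-D search.

SIM_CS <- 69000 # simulation solubility convention, mg/dm^3

rel_err <- function(est, truth) {
  max(abs(est - truth) / abs(truth))
}

# Reference nonlinear-method parameter sets for the SBA-15-AP sorbent, one
# per family (used as generating truth for round-trip tests).
ref_truth <- function(family) {
  ga_param_set("SBA-15-AP", "nonlinear", family)
}

noiseless_data <- function(family, params, n = 12, cs = SIM_CS) {
  simulate_batch(family, params,
                 batch_design(c0 = geometric_schedule(n, 120, 6900),
                              cs = cs, noise_cv = 0))
}

# Independent dense-grid oracle for the profiled linear fits: 1000
# log-spaced candidates scored by the inner OLS r2, then golden-section
# refinement around the best grid cell.
grid_profile_oracle <- function(family, data, temp_k = 298.15, cs = NULL,
                                n_grid = 1000) {
  bounds <- if (family == "redlich_peterson") {
    lo <- (1 + 1e-6) * max(data$qe / data$ce)
    c(lo, lo * 1e6)
  } else c(1, 6)
  score <- function(aux) {
    tryCatch({
      xy <- transform_linear(family, data, aux = aux, temp_k = temp_k,
                             cs = cs)
      ols_line(xy$x, xy$y)$r2
    }, error = function(e) -Inf)
  }
  lg <- seq(log(bounds[1]), log(bounds[2]), length.out = n_grid)
  r2 <- vapply(lg, function(v) score(exp(v)), numeric(1))
  i <- which.max(r2)
  lo <- lg[max(i - 1, 1)]
  hi <- lg[min(i + 1, n_grid)]
  opt <- stats::optimize(function(v) score(exp(v)), c(lo, hi),
                         maximum = TRUE, tol = 1e-10)
  list(aux = exp(opt$maximum), r2 = opt$objective)
}

# Random physically plausible parameter draws for the three-parameter
# families (profile-search oracle tests).
random_rp_params <- function() {
  k_rp <- 10^stats::runif(1, -1, 0.5)
  q_scale <- stats::runif(1, 80, 250)
  c(k_rp = k_rp, a_rp = k_rp / q_scale, beta = stats::runif(1, 0.6, 1))
}

random_da_params <- function() {
  n_da <- stats::runif(1, 1.5, 3.5)
  e_target <- stats::runif(1, 6000, 10000) # J/mol
  c(q_max = stats::runif(1, 100, 300), k_da = e_target^(-n_da) / 2,
    n_da = n_da)
}
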