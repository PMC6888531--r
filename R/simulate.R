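# Batch-experiment simulator: solves the vial mass balance against a known
# isotherm to get the true equilibrium state, then injects seeded
# multiplicative measurement noise on the measured concentration.

#' Describe a batch adsorption experiment design
#'
#' Defaults follow the batch protocol the package targets: 12 geometrically
#' spaced initial concentrations over 120-6900 mg/dm^3, 0.010 dm^3 of
#' solution on 0.100 g of sorbent at 25 C. The solubility default
#' (69,000 mg/dm^3, ten times the largest initial concentration) is an
#' explicit simulation convention for the Polanyi-based families, not a
#' measured value.
#'
#' @param c0 Vector of initial concentrations, mg/dm^3 (all > 0).
#' @param v Solution volume, dm^3 (> 0).
#' @param m Sorbent mass, g (> 0).
#' @param temp_c Temperature, Celsius.
#' @param cs Adsorbate solubility, mg/dm^3.
#' @param noise_cv Relative standard deviation of the measured equilibrium
#'   concentration (>= 0; 0 gives noiseless data).
#' @param replicates Vials per initial concentration.
#' @param seed Integer seed for the measurement-noise generator.
#' @return A list of class `batch_design`.
#' @examples
#' batch_design(noise_cv = 0.05, seed = 42)
#' @export
batch_design <- function(c0 = geometric_schedule(12, 120, 6900),
                         v = 0.010, m = 0.100, temp_c = 25, cs = 69000,
                         noise_cv = 0, replicates = 1L, seed = 1L) {
  if (any(!is.finite(c0)) || any(c0 <= 0)) {
    abort("All initial concentrations `c0` must be > 0.",
          class = "sorbkit_error_input")
  }
  if (v <= 0 || m <= 0) {
    abort("`v` and `m` must be > 0.", class = "sorbkit_error_input")
  }
  if (noise_cv < 0) {
    abort("`noise_cv` must be >= 0.", class = "sorbkit_error_input")
  }
  if (replicates < 1) {
    abort("`replicates` must be >= 1.", class = "sorbkit_error_input")
  }
  structure(
    list(c0 = as.numeric(c0), v = v, m = m,
         temp_k = celsius_to_kelvin(temp_c), cs = cs,
         noise_cv = noise_cv, replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "batch_design"
  )
}

#' Geometrically spaced concentration schedule
#'
#' @param n Number of levels.
#' @param from,to Endpoints (included), mg/dm^3.
#' @return Numeric vector of length `n`.
#' @examples
#' geometric_schedule(12, 120, 6900)
#' @export
geometric_schedule <- function(n, from, to) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Solve the batch mass balance against an isotherm
#'
#' Finds the unique equilibrium concentration satisfying
#' `Ce + (m/V) * Qe(Ce) = C0` by bracketed root finding on `[0, C0]`,
#' then derives the true uptake `Qe = (C0 - Ce) * V / m`. The returned pair
#' satisfies the isotherm and the mass balance simultaneously.
#'
#' @inheritParams predict_qe
#' @param c0 Initial concentration(s), mg/dm^3 (vectorized).
#' @param v Solution volume, dm^3.
#' @param m Sorbent mass, g.
#' @return A tibble with columns `c0`, `ce`, `qe`.
#' @examples
#' equilibrate("langmuir", c(q_max = 169.5, k_l = 2.745e-3), c0 = 1000)
#' @export
equilibrate <- function(family, params, c0, v = 0.010, m = 0.100,
                        temp_k = 298.15, cs = NULL) {
  family <- match_family(family)
  params <- check_params(family, params)
  if (any(c0 < 0)) abort("`c0` must be >= 0.", class = "sorbkit_error_input")
  ratio <- m / v
  one <- function(c0i) {
    if (c0i == 0) return(c(0, 0))
    f <- function(ce) {
      qe <- suppressWarnings(
        predict_qe(family, params, ce, temp_k = temp_k, cs = cs)
      )
      ce + ratio * qe - c0i
    }
    # lower bracket: 0 works except for log-singular families (Temkin),
    # where f -> -Inf as ce -> 0+ anyway; use a tiny positive floor there.
    lo <- if (family == "temkin") c0i * 1e-12 else 0
    flo <- f(max(lo, .Machine$double.xmin))
    fhi <- f(c0i)
    if (!is.finite(flo)) flo <- -c0i
    if (is.na(fhi) || flo > 0 || fhi < 0) {
      abort(
        paste0("Mass balance has no bracketed root on [0, C0] for C0 = ",
               format(c0i), " (non-monotone or out-of-domain isotherm)."),
        class = "sorbkit_error_fit"
      )
    }
    root <- stats::uniroot(f, lower = max(lo, .Machine$double.xmin),
                           upper = c0i, f.lower = flo, f.upper = fhi,
                           tol = 1e-12 * c0i)
    ce <- root$root
    c(ce, (c0i - ce) / ratio)
  }
  res <- vapply(c0, one, numeric(2))
  tibble(c0 = as.numeric(c0), ce = res[1, ], qe = res[2, ])
}

#' Simulate a batch adsorption dataset from known isotherm truth
#'
#' For each scheduled initial concentration the vial mass balance is solved
#' exactly, then the measured equilibrium concentration is drawn as
#' `ce_obs = ce_true * (1 + noise_cv * z)` with standard-normal `z`,
#' resampled until `0 < ce_obs < c0`. The observed uptake is derived from
#' the observed concentration through the mass balance -- noise enters the
#' data exactly where the measurement does. Deterministic given the
#' design's seed; the caller's RNG state is left untouched.
#'
#' @inheritParams predict_qe
#' @param design A [batch_design()].
#' @return A tibble with columns `sample_id`, `c0`, `ce_true`, `qe_true`,
#'   `ce`, `qe`, `v`, `m`, carrying the design and the generating truth in
#'   attributes `design` and `truth`.
#' @examples
#' simulate_batch("langmuir", c(q_max = 169.5, k_l = 2.745e-3),
#'                batch_design(noise_cv = 0.05, seed = 1))
#' @export
simulate_batch <- function(family, params, design = batch_design()) {
  family <- match_family(family)
  params <- check_params(family, params)
  if (!inherits(design, "batch_design")) {
    abort("`design` must be a batch_design().", class = "sorbkit_error_input")
  }
  if (family %in% polanyi_families()) {
    check_polanyi_context(family, design$temp_k, design$cs)
  }
  c0 <- rep(design$c0, each = design$replicates)
  truth <- equilibrate(family, params, c0, v = design$v, m = design$m,
                       temp_k = design$temp_k, cs = design$cs)
  if (family %in% polanyi_families() && any(truth$ce > design$cs)) {
    abort("Simulated equilibrium exceeds the design solubility `cs`.",
          class = "sorbkit_error_domain")
  }
  ce_obs <- if (design$noise_cv == 0) truth$ce else {
    with_local_seed(design$seed, {
      vapply(seq_along(c0), function(i) {
        repeat {
          cand <- truth$ce[i] * (1 + design$noise_cv * stats::rnorm(1))
          if (cand > 0 && cand < c0[i]) return(cand)
        }
      }, numeric(1))
    })
  }
  out <- tibble(
    sample_id = seq_along(c0),
    c0 = c0,
    ce_true = truth$ce,
    qe_true = truth$qe,
    ce = ce_obs,
    qe = adsorbed_amount(c0, ce_obs, design$v, design$m),
    v = design$v,
    m = design$m
  )
  attr(out, "design") <- design
  attr(out, "truth") <- list(family = family, params = params)
  out
}
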