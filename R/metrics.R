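# Derived physico-chemical quantities: batch uptake and efficiency, mean
# free adsorption energies from the Polanyi-based models, molar uptake
# ratio, surface-normalized capacity, percent changes, and model ranking.

#' Adsorbed amount from a batch mass balance
#'
#' `Qe = (C0 - Ce) * V / m`: the equilibrium uptake inferred from the
#' depletion of solute concentration in a batch vial.
#'
#' @param c0 Initial concentration(s), mg/dm^3.
#' @param ce Equilibrium concentration(s), mg/dm^3 (`0 <= ce <= c0`).
#' @param v Solution volume, dm^3 (> 0).
#' @param m Sorbent mass, g (> 0).
#' @return Uptake in mg/g, vectorized.
#' @examples
#' adsorbed_amount(120, 24, 0.010, 0.100) # 9.6 mg/g
#' @export
adsorbed_amount <- function(c0, ce, v, m) {
  if (any(v <= 0) || any(m <= 0)) {
    abort("`v` and `m` must be > 0.", class = "sorbkit_error_domain")
  }
  if (any(ce < 0) || any(ce > c0)) {
    abort("Need 0 <= ce <= c0 in every record.",
          class = "sorbkit_error_domain")
  }
  (c0 - ce) * v / m
}

#' Percentage adsorption efficiency
#'
#' `E = 100 * (C0 - Ce) / C0`, the fraction of the initial solute load
#' captured by the sorbent.
#'
#' @inheritParams adsorbed_amount
#' @return Efficiency in percent, vectorized.
#' @examples
#' adsorption_efficiency(120, 24) # 80
#' @export
adsorption_efficiency <- function(c0, ce) {
  if (any(c0 <= 0)) {
    abort("`c0` must be > 0.", class = "sorbkit_error_domain")
  }
  if (any(ce < 0) || any(ce > c0)) {
    abort("Need 0 <= ce <= c0.", class = "sorbkit_error_domain")
  }
  100 * (c0 - ce) / c0
}

#' Mean free energy of adsorption from the Dubinin-Radushkevich constant
#'
#' `E = 1 / sqrt(2 * k_dr)` (J/mol), reported in kJ/mol. Magnitudes below
#' about 8 kJ/mol are conventionally read as physisorption, above as
#' chemisorption-like binding; the package reports the number and leaves
#' the classification to the analyst.
#'
#' @param k_dr Dubinin-Radushkevich energy constant, mol^2/J^2 (> 0).
#' @return Energy in kJ/mol, vectorized.
#' @examples
#' energy_dr(8.110e-9) # 7.85
#' @export
energy_dr <- function(k_dr) {
  if (any(!is.finite(k_dr)) || any(k_dr <= 0)) {
    abort("`k_dr` must be finite and > 0.", class = "sorbkit_error_domain")
  }
  1 / sqrt(2 * k_dr) / 1000
}

#' Mean free energy of adsorption from the Dubinin-Astakhov constants
#'
#' Uses the direct n-generalization of the Dubinin-Radushkevich expression,
#' `E = (2 * k_da)^(-1/n_da)` (J/mol), reported in kJ/mol; at `n_da = 2` it
#' reduces exactly to [energy_dr()].
#'
#' @param k_da Dubinin-Astakhov energy constant, mol^n/J^n (> 0).
#' @param n_da Heterogeneity exponent (>= 1).
#' @return Energy in kJ/mol, vectorized.
#' @examples
#' energy_da(8.110e-9, 2) # equals energy_dr(8.110e-9)
#' @export
energy_da <- function(k_da, n_da) {
  if (any(!is.finite(k_da)) || any(k_da <= 0)) {
    abort("`k_da` must be finite and > 0.", class = "sorbkit_error_domain")
  }
  if (any(!is.finite(n_da)) || any(n_da < 1)) {
    abort("`n_da` must be finite and >= 1.", class = "sorbkit_error_domain")
  }
  (2 * k_da)^(-1 / n_da) / 1000
}

#' Molar ratio of adsorbed solute to sorbent functional groups
#'
#' `(q_max * 1e-3 / molar_mass) / q_fg`: moles of adsorbate captured at
#' capacity per mole of grafted functional group. Values well below 1
#' indicate partial accessibility of the binding sites.
#'
#' @param q_max Maximum adsorption capacity, mg/g.
#' @param q_fg Functional-group content of the sorbent, mol/g (> 0).
#' @param molar_mass Adsorbate molar mass, g/mol. Defaults to 470.68, the
#'   molar mass of 18beta-glycyrrhetinic acid (C30H46O4).
#' @return Dimensionless molar ratio, vectorized.
#' @examples
#' molar_ratio(202.8, q_fg = 1.47e-3)
#' @export
molar_ratio <- function(q_max, q_fg, molar_mass = 470.68) {
  if (any(!is.finite(q_fg)) || any(q_fg <= 0)) {
    abort("`q_fg` must be finite and > 0.", class = "sorbkit_error_domain")
  }
  if (any(molar_mass <= 0)) {
    abort("`molar_mass` must be > 0.", class = "sorbkit_error_domain")
  }
  (q_max * 1e-3 / molar_mass) / q_fg
}

#' Surface-area-normalized adsorption capacity
#'
#' `q_max / s_bet` in mg/m^2: capacity per unit of BET surface area, a
#' measure of how efficiently the available surface is exploited.
#'
#' @param q_max Maximum adsorption capacity, mg/g.
#' @param s_bet BET surface area, m^2/g (> 0).
#' @return Capacity in mg/m^2, vectorized.
#' @examples
#' surface_capacity(210.3, 438)
#' @export
surface_capacity <- function(q_max, s_bet) {
  if (any(!is.finite(s_bet)) || any(s_bet <= 0)) {
    abort("`s_bet` must be finite and > 0.", class = "sorbkit_error_domain")
  }
  q_max / s_bet
}

#' Percent reduction relative to a reference value
#'
#' `100 * (reference - value) / reference`; negative output means the value
#' increased.
#'
#' @param reference Reference value(s), > 0.
#' @param value Compared value(s).
#' @return Percent change, vectorized.
#' @examples
#' percent_reduction(770, 438) # ~43.1
#' @export
percent_reduction <- function(reference, value) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    abort("`reference` must be finite and > 0.",
          class = "sorbkit_error_domain")
  }
  100 * (reference - value) / reference
}

rank_input_table <- function(fits) {
  if (is.data.frame(fits)) {
    tb <- tibble::as_tibble(fits)
    if (!"family" %in% names(tb)) {
      abort("`fits` needs a `family` column.", class = "sorbkit_error_input")
    }
    if (!"method" %in% names(tb)) tb$method <- NA_character_
    return(tb)
  }
  fl <- if (inherits(fits, "isotherm_fit")) list(fits) else fits
  purrr::map_dfr(fl, glance)
}

#' Rank isotherm models by goodness of fit
#'
#' Sorts fits descending by `r2` (linear method) or ascending by `mpsd`
#' (nonlinear method) and classifies adjacent pairs as practically
#' equivalent ("~") or strictly ordered (">"). Two adjacent fits tie when
#' their MPSD ratio is at most `tie_threshold` (default 1.5) or their r2
#' values differ by at most `tie_delta_r2` (default 0.01).
#'
#' @param fits A tibble with columns `family` plus `mpsd` and/or `r2` (such
#'   as the output of [fit_isotherms()]), or a list of `isotherm_fit`
#'   objects. All fits must come from the same method unless
#'   `allow_mixed = TRUE`.
#' @param by `"auto"` picks `mpsd` when a nonlinear method is present,
#'   otherwise `r2`; or force `"mpsd"`/`"r2"`.
#' @param tie_threshold Maximum MPSD ratio for an adjacent tie.
#' @param tie_delta_r2 Maximum |delta r2| for an adjacent tie.
#' @param allow_mixed Permit ranking fits from different methods together.
#' @return A `model_ranking`: a tibble sorted by fit quality with columns
#'   `family`, `label`, the ranking score, and `relation` (the connector
#'   printed before the following model). Its `format()`/`print()` methods
#'   render the order as e.g. `"R-P ~ D-A ~ L > D-R > T ~ F"`.
#' @examples
#' scores <- tibble::tibble(
#'   family = c("langmuir", "freundlich", "redlich_peterson", "temkin",
#'              "dubinin_radushkevich", "dubinin_astakhov"),
#'   method = "nonlinear",
#'   mpsd = c(4.66, 23.15, 2.72, 22.22, 9.74, 3.58)
#' )
#' rank_models(scores)
#' @export
rank_models <- function(fits, by = c("auto", "mpsd", "r2"),
                        tie_threshold = 1.5, tie_delta_r2 = 0.01,
                        allow_mixed = FALSE) {
  by <- match.arg(by)
  tb <- rank_input_table(fits)
  if (!nrow(tb)) abort("No fits to rank.", class = "sorbkit_error_input")
  methods <- unique(stats::na.omit(tb$method))
  if (length(methods) > 1 && !allow_mixed) {
    abort("Fits mix estimation methods; set `allow_mixed = TRUE` to rank anyway.",
          class = "sorbkit_error_input")
  }
  if (by == "auto") {
    by <- if ("nonlinear" %in% methods && "mpsd" %in% names(tb)) "mpsd"
          else if ("r2" %in% names(tb) && length(methods) &&
                   all(methods == "linear")) "r2"
          else if ("mpsd" %in% names(tb)) "mpsd" else "r2"
  }
  if (!by %in% names(tb) || any(!is.finite(tb[[by]]))) {
    abort(paste0("Ranking by `", by, "` needs that column, finite for every fit."),
          class = "sorbkit_error_input")
  }
  tb$family <- vapply(tb$family, match_family, character(1))
  tb$label <- unname(purrr::map_chr(family_registry()[tb$family], "label"))
  # stable alphabetical tie-break on the label for exactly equal scores
  ord <- if (by == "mpsd") order(tb$mpsd, tb$label) else order(-tb$r2, tb$label)
  tb <- tb[ord, ]
  n <- nrow(tb)
  relation <- character(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      tie <- if (by == "mpsd") {
        tb$mpsd[i + 1] / tb$mpsd[i] <= tie_threshold
      } else {
        abs(tb$r2[i] - tb$r2[i + 1]) <= tie_delta_r2
      }
      relation[i] <- if (tie) "~" else ">"
    }
  }
  relation[n] <- ""
  tb$relation <- relation
  tb <- tb[c("family", "label", by, "relation",
             setdiff(names(tb), c("family", "label", by, "relation")))]
  structure(tb, class = c("model_ranking", class(tb)),
            by = by, tie_threshold = tie_threshold,
            tie_delta_r2 = tie_delta_r2)
}

#' @export
format.model_ranking <- function(x, ...) {
  if (nrow(x) == 1) return(x$label)
  out <- character(0)
  for (i in seq_len(nrow(x))) {
    out <- c(out, x$label[i])
    if (nzchar(x$relation[i])) out <- c(out, x$relation[i])
  }
  paste(out, collapse = " ")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("<model_ranking> by", attr(x, "by"), "\n")
  cat(" ", format(x), "\n\n")
  NextMethod()
}
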