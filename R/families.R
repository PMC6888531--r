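#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
NULL

#' Universal gas constant
#'
#' Gas constant used throughout the package, in J/(mol K). All Polanyi
#' potentials are therefore in J/mol; adsorption energies are reported in
#' kJ/mol.
#'
#' @export
GAS_CONSTANT <- 8.314

# Internal registry of the six isotherm families. `rate` marks parameters
# perturbed by a full decade during multistart; `cap` marks capacities
# (perturbed +/- 50%). `shape` parameters (beta, n_F, n_DA) are box-bounded.
family_registry <- function() {
  list(
    langmuir = list(
      label = "L", pretty = "Langmuir",
      pars = c("q_max", "k_l"), rate = "k_l", cap = "q_max", shape = character()
    ),
    freundlich = list(
      label = "F", pretty = "Freundlich",
      pars = c("k_f", "n_f"), rate = "k_f", cap = character(), shape = "n_f"
    ),
    redlich_peterson = list(
      label = "R-P", pretty = "Redlich-Peterson",
      pars = c("k_rp", "a_rp", "beta"), rate = c("k_rp", "a_rp"),
      cap = character(), shape = "beta"
    ),
    temkin = list(
      label = "T", pretty = "Temkin",
      pars = c("k_t", "b_t"), rate = "k_t", cap = "b_t", shape = character()
    ),
    dubinin_radushkevich = list(
      label = "D-R", pretty = "Dubinin-Radushkevich",
      pars = c("q_max", "k_dr"), rate = "k_dr", cap = "q_max",
      shape = character()
    ),
    dubinin_astakhov = list(
      label = "D-A", pretty = "Dubinin-Astakhov",
      pars = c("q_max", "k_da", "n_da"), rate = "k_da", cap = "q_max",
      shape = "n_da"
    )
  )
}

#' The isotherm families known to sorbkit
#'
#' @return A tibble with one row per family: machine id, short label used in
#'   rankings ("L", "F", "R-P", "T", "D-R", "D-A"), display name, parameter
#'   names, number of parameters `p`, and whether the family needs the
#'   Polanyi context (temperature and solubility `Cs`).
#' @examples
#' isotherm_families()
#' @export
isotherm_families <- function() {
  reg <- family_registry()
  tibble(
    family = names(reg),
    label = purrr::map_chr(reg, "label"),
    name = purrr::map_chr(reg, "pretty"),
    parameters = purrr::map(reg, "pars"),
    p = purrr::map_int(reg, ~ length(.x$pars)),
    needs_polanyi = names(reg) %in% polanyi_families(),
    needs_temperature = names(reg) %in% c("temkin", polanyi_families())
  )
}

polanyi_families <- function() c("dubinin_radushkevich", "dubinin_astakhov")

match_family <- function(family) {
  reg <- family_registry()
  if (length(family) != 1L || !is.character(family)) {
    abort("`family` must be a single string.", class = "sorbkit_error_family")
  }
  key <- gsub("[^a-z]", "_", tolower(family))
  # accept the short labels too ("R-P", "D-A", ...)
  bylabel <- purrr::map_chr(reg, "label")
  if (toupper(family) %in% bylabel) {
    return(names(bylabel)[match(toupper(family), bylabel)])
  }
  hit <- pmatch(key, names(reg))
  if (is.na(hit)) {
    abort(
      paste0("Unknown isotherm family: '", family, "'. Known families: ",
             paste(names(reg), collapse = ", "), "."),
      class = "sorbkit_error_family"
    )
  }
  names(reg)[hit]
}

#' Validate an isotherm parameter set
#'
#' Checks that `params` carries exactly the named parameters of `family`
#' (order-insensitively) and that each satisfies its physical domain:
#' capacities and rate constants strictly positive, `beta` in (0, 1],
#' `n_f >= 1`, `n_da >= 1`.
#'
#' @param family Isotherm family id or short label.
#' @param params Named numeric vector (or coercible list) of parameters.
#' @return The validated parameter vector in canonical order, invisibly
#'   usable anywhere a parameter set is expected.
#' @examples
#' check_params("langmuir", c(q_max = 169.5, k_l = 2.745e-3))
#' @export
check_params <- function(family, params) {
  family <- match_family(family)
  info <- family_registry()[[family]]
  params <- unlist(params)
  if (!is.numeric(params) || is.null(names(params))) {
    abort("`params` must be a named numeric vector.",
          class = "sorbkit_error_params")
  }
  missing <- setdiff(info$pars, names(params))
  extra <- setdiff(names(params), info$pars)
  if (length(missing) || length(extra)) {
    abort(
      paste0("Parameters for ", info$pretty, " must be {",
             paste(info$pars, collapse = ", "), "}; got {",
             paste(names(params), collapse = ", "), "}."),
      class = "sorbkit_error_params"
    )
  }
  params <- params[info$pars]
  if (any(!is.finite(params)) || any(params <= 0)) {
    abort(paste0("All ", info$pretty, " parameters must be finite and > 0."),
          class = "sorbkit_error_params")
  }
  if (family == "redlich_peterson" && params[["beta"]] > 1) {
    abort("Redlich-Peterson exponent `beta` must lie in (0, 1].",
          class = "sorbkit_error_params")
  }
  if (family == "freundlich" && params[["n_f"]] < 1) {
    abort("Freundlich exponent `n_f` must be >= 1.",
          class = "sorbkit_error_params")
  }
  if (family == "dubinin_astakhov" && params[["n_da"]] < 1) {
    abort("Dubinin-Astakhov heterogeneity factor `n_da` must be >= 1.",
          class = "sorbkit_error_params")
  }
  params
}

check_polanyi_context <- function(family, temp_k, cs, ce = NULL) {
  if (is.null(temp_k) || !is.finite(temp_k) || temp_k <= 0) {
    abort(paste0("Family '", family, "' needs a positive absolute temperature."),
          class = "sorbkit_error_missing_context")
  }
  if (family %in% polanyi_families()) {
    if (is.null(cs) || !is.finite(cs) || cs <= 0) {
      abort(
        paste0("Family '", family, "' is Polanyi-based and needs the ",
               "adsorbate solubility `cs` (mg/dm^3); none was supplied."),
        class = "sorbkit_error_missing_context"
      )
    }
    if (!is.null(ce) && any(ce > cs)) {
      abort(
        paste0("Equilibrium concentrations exceed the solubility limit ",
               "(max Ce = ", format(max(ce)), " > Cs = ", format(cs), ")."),
        class = "sorbkit_error_domain"
      )
    }
  }
  invisible(TRUE)
}

#' Polanyi adsorption potential
#'
#' Computes the adsorption potential relative to the solubility limit,
#' `epsilon = R T ln(Cs / Ce)`, in J/mol. This is the abscissa variable of
#' the Dubinin-Radushkevich and Dubinin-Astakhov pore-filling models.
#'
#' @param ce Equilibrium concentration(s), mg/dm^3; must satisfy 0 < ce <= cs.
#' @param cs Adsorbate solubility in the working solvent, mg/dm^3.
#' @param temp_k Absolute temperature, K.
#' @return Numeric vector of potentials (J/mol), all >= 0.
#' @examples
#' polanyi_potential(100, 1000, 298.15)
#' @export
polanyi_potential <- function(ce, cs, temp_k) {
  if (!is.finite(temp_k) || temp_k <= 0) {
    abort("`temp_k` must be a positive absolute temperature.",
          class = "sorbkit_error_domain")
  }
  if (!is.finite(cs) || cs <= 0) {
    abort("`cs` must be a positive solubility (mg/dm^3).",
          class = "sorbkit_error_domain")
  }
  if (any(ce <= 0)) {
    abort("Polanyi potential needs Ce > 0.", class = "sorbkit_error_domain")
  }
  if (any(ce > cs)) {
    abort("Polanyi potential needs Ce <= Cs.", class = "sorbkit_error_domain")
  }
  GAS_CONSTANT * temp_k * log(cs / ce)
}

#' Predict the equilibrium adsorbed amount under an isotherm model
#'
#' Forward evaluation `Qe(Ce)` for any of the six families. Vectorized over
#' `ce`.
#'
#' The Temkin prediction `(R T / b_t) ln(k_t Ce)` is negative wherever
#' `k_t * ce < 1`; it is returned as-is (with a warning) rather than clamped,
#' since the linearized fit must be able to operate on such data.
#'
#' @inheritParams check_params
#' @param ce Equilibrium concentration(s), mg/dm^3 (>= 0; > 0 for Temkin).
#' @param temp_k Absolute temperature (K); required by Temkin and the
#'   Polanyi-based families.
#' @param cs Adsorbate solubility (mg/dm^3); required by the Polanyi-based
#'   families, with `ce <= cs`.
#' @return Numeric vector of adsorbed amounts, mg/g.
#' @examples
#' predict_qe("langmuir", c(q_max = 169.5, k_l = 2.745e-3), ce = 1000)
#' @export
predict_qe <- function(family, params, ce, temp_k = NULL, cs = NULL) {
  family <- match_family(family)
  params <- check_params(family, params)
  if (any(!is.finite(ce)) || any(ce < 0)) {
    abort("`ce` must be finite and >= 0.", class = "sorbkit_error_domain")
  }
  switch(family,
    langmuir = {
      params[["q_max"]] * params[["k_l"]] * ce / (1 + params[["k_l"]] * ce)
    },
    freundlich = {
      params[["k_f"]] * ce^(1 / params[["n_f"]])
    },
    redlich_peterson = {
      params[["k_rp"]] * ce / (1 + params[["a_rp"]] * ce^params[["beta"]])
    },
    temkin = {
      check_polanyi_context(family, temp_k, cs = NULL)
      if (any(ce <= 0)) {
        abort("Temkin prediction needs Ce > 0 (k_t * Ce must be positive).",
              class = "sorbkit_error_domain")
      }
      qe <- (GAS_CONSTANT * temp_k / params[["b_t"]]) *
        log(params[["k_t"]] * ce)
      if (any(qe < 0)) {
        warn("Temkin prediction is negative where k_t * Ce < 1 (returned as-is).",
             class = "sorbkit_warning_temkin_negative")
      }
      qe
    },
    dubinin_radushkevich = {
      check_polanyi_context(family, temp_k, cs, ce)
      eps <- ifelse(ce > 0, GAS_CONSTANT * temp_k * log(cs / pmax(ce, 0)), Inf)
      params[["q_max"]] * exp(-params[["k_dr"]] * eps^2)
    },
    dubinin_astakhov = {
      check_polanyi_context(family, temp_k, cs, ce)
      eps <- ifelse(ce > 0, GAS_CONSTANT * temp_k * log(cs / pmax(ce, 0)), Inf)
      params[["q_max"]] * exp(-params[["k_da"]] * eps^params[["n_da"]])
    }
  )
}

#' Linearizing transform of an isotherm family
#'
#' Maps equilibrium points `(Ce, Qe)` to the `(x, y)` coordinates of the
#' family's straight-line form:
#' Langmuir `(1/Ce, 1/Qe)`; Freundlich `(ln Ce, ln Qe)`; Redlich-Peterson
#' `(ln Ce, ln(k_rp Ce / Qe - 1))` given an auxiliary `k_rp`; Temkin
#' `(ln Ce, Qe)`; Dubinin-Radushkevich `(eps^2, ln Qe)`; Dubinin-Astakhov
#' `(eps^n_da, ln Qe)` given an auxiliary `n_da`, with `eps` the Polanyi
#' potential.
#'
#' @inheritParams predict_qe
#' @param data Data frame with numeric columns `ce` and `qe`.
#' @param aux Auxiliary profiled parameter: `k_rp` for Redlich-Peterson,
#'   `n_da` for Dubinin-Astakhov; ignored otherwise.
#' @return A tibble with columns `x` and `y`, one row per input point.
#' @examples
#' transform_linear("langmuir", tibble::tibble(ce = 500, qe = 100))
#' @export
transform_linear <- function(family, data, aux = NULL, temp_k = NULL,
                             cs = NULL) {
  family <- match_family(family)
  ce <- data$ce
  qe <- data$qe
  if (is.null(ce) || is.null(qe)) {
    abort("`data` must have columns `ce` and `qe`.",
          class = "sorbkit_error_input")
  }
  bad <- function(cond, what) {
    if (any(cond)) {
      abort(
        paste0(family, " linearization: ", what, " at point(s) ",
               paste(which(cond), collapse = ", "), "."),
        class = "sorbkit_error_domain"
      )
    }
  }
  out <- switch(family,
    langmuir = {
      bad(ce <= 0 | qe <= 0, "needs Ce > 0 and Qe > 0")
      tibble(x = 1 / ce, y = 1 / qe)
    },
    freundlich = {
      bad(ce <= 0 | qe <= 0, "needs Ce > 0 and Qe > 0")
      tibble(x = log(ce), y = log(qe))
    },
    redlich_peterson = {
      if (is.null(aux) || !is.finite(aux) || aux <= 0) {
        abort("Redlich-Peterson linearization needs auxiliary `aux` = k_rp > 0.",
              class = "sorbkit_error_missing_context")
      }
      bad(ce <= 0 | qe <= 0, "needs Ce > 0 and Qe > 0")
      arg <- aux * ce / qe - 1
      bad(arg <= 0, paste0("needs k_rp * Ce / Qe > 1 (k_rp = ", format(aux), ")"))
      tibble(x = log(ce), y = log(arg))
    },
    temkin = {
      bad(ce <= 0, "needs Ce > 0")
      tibble(x = log(ce), y = qe)
    },
    dubinin_radushkevich = {
      check_polanyi_context(family, temp_k, cs, ce)
      bad(ce <= 0 | qe <= 0, "needs Ce > 0 and Qe > 0")
      tibble(x = polanyi_potential(ce, cs, temp_k)^2, y = log(qe))
    },
    dubinin_astakhov = {
      if (is.null(aux) || !is.finite(aux) || aux <= 0) {
        abort("Dubinin-Astakhov linearization needs auxiliary `aux` = n_da > 0.",
              class = "sorbkit_error_missing_context")
      }
      check_polanyi_context(family, temp_k, cs, ce)
      bad(ce <= 0 | qe <= 0, "needs Ce > 0 and Qe > 0")
      tibble(x = polanyi_potential(ce, cs, temp_k)^aux, y = log(qe))
    }
  )
  out
}

#' Convert Celsius to kelvin
#'
#' @param temp_c Temperature in degrees Celsius.
#' @return Temperature in kelvin.
#' @examples
#' celsius_to_kelvin(25) # 298.15
#' @export
celsius_to_kelvin <- function(temp_c) temp_c + 273.15
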