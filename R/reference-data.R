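# Reference data shipped with the package: published isotherm parameter
# estimates and sorbent textural metadata for 18beta-glycyrrhetinic acid
# adsorption on amine-functionalized SBA-15 and Aerosil silicas.

sorbkit_extdata <- function(file) {
  path <- system.file("extdata", file, package = "sorbkit")
  if (path == "") {
    abort(paste0("Bundled data file not found: ", file),
          class = "sorbkit_error_io")
  }
  path
}

#' Reference isotherm parameter estimates for functionalized silicas
#'
#' Tabulated parameter estimates for 18beta-glycyrrhetinic acid adsorption
#' on eight amine-functionalized silica sorbents (four mesoporous SBA-15
#' variants, four non-porous Aerosil variants), for both estimation
#' methods. Terms include the family parameters, the linear-method `r2`,
#' the nonlinear-method `mpsd`, and the reported adsorption energies
#' (`e_dr`, `e_da`). Family x sorbent combinations absent from the source
#' tables are absent here too.
#'
#' @param sorbent Optional sorbent name filter (e.g. `"SBA-15-AP"`).
#' @param method Optional method filter: `"linear"` or `"nonlinear"`.
#' @return A tibble with columns `sorbent`, `method`, `family`, `term`,
#'   `value`.
#' @examples
#' ga_reference_params("SBA-15-AP", "nonlinear")
#' @export
ga_reference_params <- function(sorbent = NULL, method = NULL) {
  tb <- readr::read_csv(sorbkit_extdata("ga_silica_isotherm_params.csv"),
                        col_types = "ccccd")
  if (!is.null(sorbent)) {
    if (!sorbent %in% tb$sorbent) {
      abort(paste0("Unknown sorbent '", sorbent, "'. Available: ",
                   paste(unique(tb$sorbent), collapse = ", "), "."),
            class = "sorbkit_error_input")
    }
    tb <- tb[tb$sorbent == sorbent, ]
  }
  if (!is.null(method)) {
    method <- match.arg(method, c("linear", "nonlinear"))
    tb <- tb[tb$method == method, ]
  }
  tb
}

#' Reference sorbent textural properties
#'
#' Functional-group content (from thermogravimetry) and nitrogen-sorption
#' descriptors (BET area; BJH pore volume and diameter where the material
#' is porous) for the parent and functionalized silicas.
#'
#' @return A tibble with columns `name`, `agent`, `q_fg_mol_per_g`,
#'   `s_bet_m2_per_g`, `pore_volume_cm3_per_g`, `pore_diameter_nm`.
#' @examples
#' ga_sorbent_properties()
#' @export
ga_sorbent_properties <- function() {
  readr::read_csv(sorbkit_extdata("ga_silica_sorbents.csv"),
                  col_types = "ccdddd")
}

#' Extract one reference parameter set as a fit-ready vector
#'
#' @param sorbent Sorbent name (see [ga_sorbent_properties()]).
#' @param method `"linear"` or `"nonlinear"`.
#' @param family Isotherm family id or label.
#' @return Named numeric vector of the family's parameters, validated.
#' @examples
#' ga_param_set("SBA-15-AP", "nonlinear", "langmuir")
#' @export
ga_param_set <- function(sorbent, method, family) {
  family <- match_family(family)
  tb <- ga_reference_params(sorbent, method)
  tb <- tb[tb$family == family, ]
  pars <- family_registry()[[family]]$pars
  if (!nrow(tb) || !all(pars %in% tb$term)) {
    abort(paste0("No ", family, " parameter set tabulated for ", sorbent,
                 " (", method, " method)."),
          class = "sorbkit_error_input")
  }
  check_params(family, stats::setNames(tb$value[match(pars, tb$term)], pars))
}
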