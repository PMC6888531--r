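# CSV input/output, run configuration, and report generation. Column
# headers carry units (mg/dm^3, mg/g, dm^3, g) so files are self-describing
# and unit drift is caught at the boundary.

raw_batch_cols <- c("c0_mg_dm3", "ce_mg_dm3", "v_dm3", "m_g")
equilibrium_cols <- c("ce_mg_dm3", "qe_mg_g")

#' Read equilibrium adsorption data from CSV
#'
#' Two dialects are supported and auto-detected from the header:
#' `raw_batch` (`c0_mg_dm3, ce_mg_dm3, v_dm3, m_g`, one vial per row, with
#' uptake derived through the mass balance) and `equilibrium`
#' (`ce_mg_dm3, qe_mg_g`, pass-through). Validation failures report the
#' offending row numbers.
#'
#' @param path CSV file path.
#' @param dialect `"auto"`, `"raw_batch"`, or `"equilibrium"`.
#' @return A tibble with columns `ce`, `qe` (plus `c0`, `v`, `m` for the
#'   raw-batch dialect), one row per equilibrium point.
#' @export
read_isotherm_data <- function(path, dialect = c("auto", "raw_batch",
                                                 "equilibrium")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "sorbkit_error_io")
  }
  tb <- readr::read_csv(path, col_types = readr::cols(),
                        show_col_types = FALSE)
  have <- names(tb)
  if (dialect == "auto") {
    dialect <- if (all(raw_batch_cols %in% have)) "raw_batch"
    else if (all(equilibrium_cols %in% have)) "equilibrium"
    else abort(
      paste0("Cannot detect dialect from header {",
             paste(have, collapse = ", "), "}; expected columns {",
             paste(raw_batch_cols, collapse = ", "), "} or {",
             paste(equilibrium_cols, collapse = ", "), "}."),
      class = "sorbkit_error_io"
    )
  }
  need <- if (dialect == "raw_batch") raw_batch_cols else equilibrium_cols
  missing <- setdiff(need, have)
  if (length(missing)) {
    abort(paste0("Missing column(s) for ", dialect, " dialect: ",
                 paste(missing, collapse = ", "), "."),
          class = "sorbkit_error_io")
  }
  report_rows <- function(bad, what) {
    if (any(bad)) {
      abort(paste0(what, " in row(s) ", paste(which(bad), collapse = ", "),
                   " of ", path, "."),
            class = "sorbkit_error_io")
    }
  }
  if (dialect == "raw_batch") {
    report_rows(!is.finite(tb$c0_mg_dm3) | tb$c0_mg_dm3 < 0 |
                  !is.finite(tb$ce_mg_dm3) | tb$ce_mg_dm3 < 0,
                "Negative or missing concentration")
    report_rows(tb$ce_mg_dm3 > tb$c0_mg_dm3,
                "Equilibrium concentration exceeds initial concentration")
    report_rows(!is.finite(tb$v_dm3) | tb$v_dm3 <= 0 |
                  !is.finite(tb$m_g) | tb$m_g <= 0,
                "Non-positive volume or mass")
    tibble(
      ce = tb$ce_mg_dm3,
      qe = adsorbed_amount(tb$c0_mg_dm3, tb$ce_mg_dm3, tb$v_dm3, tb$m_g),
      c0 = tb$c0_mg_dm3, v = tb$v_dm3, m = tb$m_g
    )
  } else {
    report_rows(!is.finite(tb$ce_mg_dm3) | tb$ce_mg_dm3 < 0 |
                  !is.finite(tb$qe_mg_g) | tb$qe_mg_g < 0,
                "Negative or missing value")
    tibble(ce = tb$ce_mg_dm3, qe = tb$qe_mg_g)
  }
}

#' Write equilibrium adsorption data to CSV
#'
#' @param data Tibble from [simulate_batch()] or [read_isotherm_data()].
#' @param path Output CSV path.
#' @param dialect `"equilibrium"` writes `(ce_mg_dm3, qe_mg_g)`;
#'   `"raw_batch"` writes `(sample_id, c0_mg_dm3, ce_mg_dm3, v_dm3, m_g)`
#'   and requires `c0`, `v`, `m` columns.
#' @return `path`, invisibly.
#' @export
write_isotherm_data <- function(data, path,
                                dialect = c("equilibrium", "raw_batch")) {
  dialect <- match.arg(dialect)
  if (dialect == "raw_batch") {
    need <- c("c0", "ce", "v", "m")
    if (!all(need %in% names(data))) {
      abort("raw_batch output needs columns c0, ce, v, m.",
            class = "sorbkit_error_io")
    }
    out <- tibble(
      sample_id = if ("sample_id" %in% names(data)) data$sample_id
                  else seq_len(nrow(data)),
      c0_mg_dm3 = data$c0, ce_mg_dm3 = data$ce,
      v_dm3 = data$v, m_g = data$m
    )
  } else {
    out <- tibble(ce_mg_dm3 = data$ce, qe_mg_g = data$qe)
  }
  readr::write_csv(out, path)
  invisible(path)
}

config_defaults <- function() {
  list(
    temperature_c = 25,
    cs_mg_dm3 = NA_real_,
    molar_mass_g_mol = 470.68,
    families = "all",
    methods = "both",
    tie_threshold = 1.5,
    n_starts = 8L,
    grid_points = 64L,
    seed = 1L,
    round_params_signif = 4L,
    round_energy_decimals = 2L,
    round_percent_decimals = 1L
  )
}

coerce_config_value <- function(key, value, defaults) {
  proto <- defaults[[key]]
  if (is.numeric(proto)) {
    num <- suppressWarnings(as.numeric(value))
    if (is.na(num) && !(is.na(proto) && value %in% c("NA", "na", ""))) {
      abort(paste0("Config key `", key, "` must be numeric; got '", value,
                   "'."), class = "sorbkit_error_config")
    }
    if (is.integer(proto)) as.integer(num) else num
  } else {
    as.character(value)
  }
}

#' Run configuration
#'
#' Builds the validated configuration used by the command-line interface
#' and the report writer. Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults, by key (see Details).
#' @details Keys: `temperature_c`, `cs_mg_dm3` (required for the
#'   Polanyi-based families; no default value), `molar_mass_g_mol`,
#'   `families` (comma-separated ids or `"all"`), `methods`
#'   (`"linear"`, `"nonlinear"`, `"both"`), `tie_threshold`, `n_starts`,
#'   `grid_points`, `seed`, `round_params_signif`,
#'   `round_energy_decimals`, `round_percent_decimals`.
#' @return A list of class `run_config`.
#' @examples
#' run_config(cs_mg_dm3 = 69000, seed = 7)
#' @export
run_config <- function(...) {
  defaults <- config_defaults()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", "),
                 ". Valid keys: ", paste(names(defaults), collapse = ", "),
                 "."), class = "sorbkit_error_config")
  }
  cfg <- utils::modifyList(defaults, overrides)
  if (!cfg$methods %in% c("linear", "nonlinear", "both")) {
    abort("`methods` must be 'linear', 'nonlinear' or 'both'.",
          class = "sorbkit_error_config")
  }
  if (!is.na(cfg$cs_mg_dm3) && cfg$cs_mg_dm3 <= 0) {
    abort("`cs_mg_dm3` must be > 0 when given.",
          class = "sorbkit_error_config")
  }
  if (cfg$temperature_c <= -273.15) {
    abort("`temperature_c` must exceed absolute zero.",
          class = "sorbkit_error_config")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a flat key-value text file
#'
#' One `key = value` pair per line; `#` starts a comment. Keys are the
#' [run_config()] fields; unknown keys are rejected with the valid list.
#'
#' @param path Path to the config file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "sorbkit_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    abort(paste0("Malformed config line(s): ",
                 paste(lines[bad], collapse = "; "),
                 ". Expected `key = value`."),
          class = "sorbkit_error_config")
  }
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, `[[`, character(1), 2))
  defaults <- config_defaults()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s) in ", path, ": ",
                 paste(unknown, collapse = ", "), "."),
          class = "sorbkit_error_config")
  }
  overrides <- stats::setNames(
    lapply(seq_along(keys),
           function(i) coerce_config_value(keys[i], vals[i], defaults)),
    keys
  )
  do.call(run_config, overrides)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat("  ", k, " = ", format(x[[k]]), "\n", sep = "")
  invisible(x)
}

round_signif <- function(x, digits) signif(x, digits)

#' Write a fit report (machine CSV + human-readable table)
#'
#' Emits two files: `<stem>.csv`, one row per sorbent x method x family x
#' term at full precision, and `<stem>.txt`, a display table using the
#' configured rounding profile (parameters to 4 significant figures,
#' energies to 2 decimals). Byte-stable across runs given identical input.
#'
#' @param fits A tibble of fits as returned by [fit_isotherms()] (a
#'   `sorbent` column is added as `label` if absent), or any tibble with
#'   `family`, `method` and a `fit` list-column.
#' @param stem Output path stem (without extension).
#' @param label Sorbent/dataset label recorded in the report.
#' @param config A [run_config()] controlling the rounding profile.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_fit_report <- function(fits, stem, label = "dataset",
                             config = run_config()) {
  if (!is.data.frame(fits) || !nrow(fits) || !"fit" %in% names(fits)) {
    abort("`fits` must be a nonempty tibble with a `fit` list-column.",
          class = "sorbkit_error_input")
  }
  rows <- purrr::map_dfr(fits$fit, function(f) {
    par_rows <- tibble(sorbent = label, method = f$method, family = f$family,
                       term = names(f$params), value = unname(f$params))
    gof <- if (f$method == "linear") {
      tibble(sorbent = label, method = f$method, family = f$family,
             term = "r2", value = f$r2)
    } else {
      tibble(sorbent = label, method = f$method, family = f$family,
             term = "mpsd", value = f$mpsd)
    }
    en <- NULL
    if (f$family == "dubinin_radushkevich") {
      en <- tibble(sorbent = label, method = f$method, family = f$family,
                   term = "e_dr", value = energy_dr(f$params[["k_dr"]]))
    }
    if (f$family == "dubinin_astakhov") {
      en <- tibble(sorbent = label, method = f$method, family = f$family,
                   term = "e_da",
                   value = energy_da(f$params[["k_da"]], f$params[["n_da"]]))
    }
    dplyr::bind_rows(par_rows, gof, en)
  })
  csv_path <- paste0(stem, ".csv")
  txt_path <- paste0(stem, ".txt")
  readr::write_csv(rows, csv_path)

  fmt_value <- function(term, value) {
    if (term %in% c("e_dr", "e_da")) {
      sprintf(paste0("%.", config$round_energy_decimals, "f"), value)
    } else if (term %in% c("r2", "mpsd")) {
      format(signif(value, 4))
    } else {
      format(round_signif(value, config$round_params_signif))
    }
  }
  lines <- c(
    paste0("Isotherm fit report: ", label),
    paste0(format("model", width = 22), format("method", width = 10),
           format("term", width = 8), "value"),
    strrep("-", 52)
  )
  for (i in seq_len(nrow(rows))) {
    lines <- c(lines, paste0(
      format(family_registry()[[rows$family[i]]]$pretty, width = 22),
      format(rows$method[i], width = 10),
      format(rows$term[i], width = 8),
      fmt_value(rows$term[i], rows$value[i])
    ))
  }
  writeLines(lines, txt_path)
  invisible(c(csv_path, txt_path))
}
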