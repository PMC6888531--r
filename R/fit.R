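# User-facing fitting interface and the `isotherm_fit` result class.

#' Control settings for isotherm fitting
#'
#' @param seed Integer seed driving the deterministic multistart schedule.
#' @param n_starts Number of seeded log-perturbed starts added to the
#'   linear-method seed in nonlinear fitting.
#' @param grid_points Size of the log-spaced pre-scan grid bracketing the
#'   profiled parameter (Redlich-Peterson `k_rp`, Dubinin-Astakhov `n_da`).
#' @param profile_tol Absolute tolerance of the 1-D refinement on the log
#'   scale (so approximately a relative tolerance on the parameter).
#' @param tol_mpsd Relative convergence tolerance on the MPSD objective.
#' @param tol_param Convergence tolerance on the (log) parameters.
#' @return A list of class `sorbkit_control`.
#' @examples
#' fit_control(seed = 7)
#' @export
fit_control <- function(seed = 1L, n_starts = 8L, grid_points = 64L,
                        profile_tol = 1e-10, tol_mpsd = 1e-12,
                        tol_param = 1e-10) {
  out <- list(seed = as.integer(seed), n_starts = as.integer(n_starts),
              grid_points = as.integer(grid_points),
              profile_tol = profile_tol, tol_mpsd = tol_mpsd,
              tol_param = tol_param)
  structure(out, class = "sorbkit_control")
}

new_isotherm_fit <- function(family, method, params, data, temp_k, cs,
                             r2 = NA_real_, mpsd = NA_real_, details = list()) {
  predicted <- suppressWarnings(
    predict_qe(family, params, data$ce, temp_k = temp_k, cs = cs)
  )
  structure(
    list(
      family = family, method = method, params = params,
      r2 = r2, mpsd = mpsd,
      n = nrow(data), p = length(params),
      predicted = predicted, data = tibble::as_tibble(data[c("ce", "qe")]),
      temp_k = temp_k, cs = cs, details = details
    ),
    class = "isotherm_fit"
  )
}

resolve_context <- function(temp_c, temp_k) {
  if (is.null(temp_k)) temp_k <- celsius_to_kelvin(temp_c)
  temp_k
}

check_dataset <- function(data, family, p, cs) {
  if (!is.data.frame(data) || !all(c("ce", "qe") %in% names(data))) {
    abort("`data` must be a data frame with columns `ce` and `qe`.",
          class = "sorbkit_error_input")
  }
  if (any(!is.finite(data$ce)) || any(!is.finite(data$qe)) ||
      any(data$ce < 0) || any(data$qe < 0)) {
    abort("`ce` and `qe` must be finite and >= 0.",
          class = "sorbkit_error_input")
  }
  if (nrow(data) <= p) {
    abort(paste0("Fitting a ", p, "-parameter family needs more than ", p,
                 " points (got ", nrow(data), ")."),
          class = "sorbkit_error_input")
  }
  if (family %in% polanyi_families() && !is.null(cs) &&
      cs <= max(data$ce) * (1 + 1e-9)) {
    abort("`cs` must exceed max(ce); the Polanyi potential is undefined otherwise.",
          class = "sorbkit_error_domain")
  }
  invisible(TRUE)
}

#' Fit one isotherm family to equilibrium data
#'
#' The `linear` method fits the family's straight-line form by ordinary
#' least squares and back-transforms slope/intercept to the model
#' parameters; for the three-parameter Redlich-Peterson and
#' Dubinin-Astakhov families the non-linearizable parameter (`k_rp`,
#' `n_da`) is profiled over a bracketed 1-D search that maximizes the inner
#' fit's r-squared. The `nonlinear` method minimizes the MPSD error
#' function directly over all parameters, with a deterministic multistart
#' (seeded from the linear estimate when available).
#'
#' @param data Data frame with numeric columns `ce` (mg/dm^3) and `qe`
#'   (mg/g), one row per equilibrium point.
#' @param family Isotherm family id (see [isotherm_families()]).
#' @param method `"linear"` or `"nonlinear"`.
#' @param temp_c Experiment temperature in Celsius (converted internally);
#'   ignored when `temp_k` is given.
#' @param temp_k Absolute temperature in kelvin (optional override).
#' @param cs Adsorbate solubility (mg/dm^3); required by the
#'   Dubinin-Radushkevich and Dubinin-Astakhov families, and must exceed
#'   `max(ce)`.
#' @param bounds Optional search bounds (length-2 numeric) for the profiled
#'   parameter of the three-parameter families (linear method).
#' @param drop_invalid Drop points outside the linearization domain instead
#'   of erroring (dropped indices are messaged, never silent).
#' @param control A [fit_control()] list.
#' @return An object of class `isotherm_fit`; see [tidy.isotherm_fit()],
#'   [glance.isotherm_fit()], [autoplot.isotherm_fit()].
#' @examples
#' d <- simulate_batch("langmuir", c(q_max = 169.5, k_l = 2.745e-3),
#'                     batch_design(noise_cv = 0))
#' fit_isotherm(d, "langmuir", method = "linear")
#' @export
fit_isotherm <- function(data, family, method = c("linear", "nonlinear"),
                         temp_c = 25, temp_k = NULL, cs = NULL, bounds = NULL,
                         drop_invalid = FALSE, control = fit_control()) {
  family <- match_family(family)
  method <- match.arg(method)
  temp_k <- resolve_context(temp_c, temp_k)
  info <- family_registry()[[family]]
  p <- length(info$pars)
  check_dataset(data, family, p, cs)
  if (family %in% polanyi_families()) {
    check_polanyi_context(family, temp_k, cs, data$ce)
  }
  data <- tibble::as_tibble(data)

  if (method == "linear") {
    use <- require_in_domain(family, data, aux = NULL, cs = cs,
                             drop_invalid = drop_invalid)
    if (nrow(use) <= p) {
      abort("Too few in-domain points left for a linear fit.",
            class = "sorbkit_error_input")
    }
    inner <- if (family %in% c("redlich_peterson", "dubinin_astakhov")) {
      profile_fit_linear(family, use, temp_k, cs, bounds = bounds,
                         control = control)
    } else {
      linear_fit_once(family, use, temp_k, cs)
    }
    params <- check_params(family, inner$params)
    fit <- new_isotherm_fit(family, "linear", params, use, temp_k, cs,
                            r2 = inner$r2,
                            details = inner[setdiff(names(inner),
                                                    c("params", "r2"))])
    fit$mpsd <- tryCatch(mpsd(use$qe, fit$predicted, p),
                         error = function(e) NA_real_)
    return(fit)
  }

  # nonlinear: MPSD needs strictly positive observations
  if (any(data$qe <= 0)) {
    abort("Nonlinear (MPSD) fitting needs all Qe > 0.",
          class = "sorbkit_error_domain")
  }
  start <- tryCatch(
    check_params(family, fit_isotherm(data, family, method = "linear",
                                      temp_k = temp_k, cs = cs,
                                      drop_invalid = drop_invalid,
                                      control = control)$params),
    error = function(e) heuristic_start(family, data, temp_k, cs)
  )
  opt <- nonlinear_optimize(family, data, temp_k, cs, start, control)
  params <- check_params(family, opt$params)
  fit <- new_isotherm_fit(family, "nonlinear", params, data, temp_k, cs,
                          mpsd = opt$mpsd,
                          details = list(convergence = opt$convergence,
                                         start = start))
  fit$r2 <- stats::cor(fit$data$qe, fit$predicted)^2
  fit
}

#' Fit several isotherm families and methods at once
#'
#' @inheritParams fit_isotherm
#' @param families Character vector of family ids, or `"all"`.
#' @param methods Character vector of `"linear"`, `"nonlinear"` (or both).
#' @param ... Passed to [fit_isotherm()].
#' @return A tibble with one row per family x method: `family`, `method`,
#'   `r2`, `mpsd`, and the fit object in the list-column `fit`. Families
#'   that fail to fit are dropped with a message.
#' @examples
#' d <- simulate_batch("langmuir", c(q_max = 169.5, k_l = 2.745e-3),
#'                     batch_design(noise_cv = 0))
#' fit_isotherms(d, families = c("langmuir", "freundlich"),
#'               methods = "linear")
#' @export
fit_isotherms <- function(data, families = "all",
                          methods = c("linear", "nonlinear"), ...) {
  if (identical(families, "all")) families <- isotherm_families()$family
  families <- vapply(families, match_family, character(1), USE.NAMES = FALSE)
  methods <- match.arg(methods, c("linear", "nonlinear"), several.ok = TRUE)
  grid <- tidyr::expand_grid(family = families, method = methods)
  rows <- purrr::pmap(grid, function(family, method) {
    fit <- tryCatch(
      fit_isotherm(data, family, method = method, ...),
      error = function(e) {
        rlang::inform(paste0("Skipping ", family, " (", method, "): ",
                             conditionMessage(e)))
        NULL
      }
    )
    if (is.null(fit)) return(NULL)
    tibble(family = family, method = method, r2 = fit$r2, mpsd = fit$mpsd,
           fit = list(fit))
  })
  dplyr::bind_rows(rows)
}

#' Re-evaluate a fit's goodness on a dataset
#'
#' Recomputes the MPSD error function and the squared correlation between
#' observed and predicted Qe for any `isotherm_fit` (either method), so
#' linear- and nonlinear-method fits can be ranked on a common footing.
#'
#' @param fit An `isotherm_fit`.
#' @param data Optional data frame with `ce`, `qe`; defaults to the fit's
#'   own data.
#' @return A list with `mpsd`, `r2_nonlinear`, and `residuals`
#'   (observed - predicted).
#' @examples
#' d <- simulate_batch("langmuir", c(q_max = 169.5, k_l = 2.745e-3),
#'                     batch_design(noise_cv = 0))
#' evaluate_fit(fit_isotherm(d, "langmuir", method = "linear"))
#' @export
evaluate_fit <- function(fit, data = NULL) {
  if (!inherits(fit, "isotherm_fit")) {
    abort("`fit` must be an isotherm_fit.", class = "sorbkit_error_input")
  }
  if (is.null(data)) data <- fit$data
  if (!all(c("ce", "qe") %in% names(data))) {
    abort("`data` must have columns `ce` and `qe`.",
          class = "sorbkit_error_input")
  }
  pred <- suppressWarnings(
    predict_qe(fit$family, fit$params, data$ce, temp_k = fit$temp_k,
               cs = fit$cs)
  )
  list(
    mpsd = mpsd(data$qe, pred, fit$p),
    r2_nonlinear = stats::cor(data$qe, pred)^2,
    residuals = data$qe - pred
  )
}

#' @export
print.isotherm_fit <- function(x, ...) {
  info <- family_registry()[[x$family]]
  cat("<isotherm_fit> ", info$pretty, " (", x$method, " method)\n", sep = "")
  cat("  parameters:\n")
  for (pn in names(x$params)) {
    cat("    ", format(pn, width = 6), " = ", signif(x$params[[pn]], 4),
        "\n", sep = "")
  }
  if (is.finite(x$r2)) cat("  r2   =", format(x$r2, digits = 6), "\n")
  if (is.finite(x$mpsd)) cat("  MPSD =", format(x$mpsd, digits = 4), "\n")
  cat("  n =", x$n, " p =", x$p, "\n")
  invisible(x)
}

#' Tidy an isotherm fit into a parameter table
#'
#' @param x An `isotherm_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.isotherm_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row goodness-of-fit summary of an isotherm fit
#'
#' @param x An `isotherm_fit`.
#' @param ... Unused.
#' @return A tibble with `family`, `method`, `r2`, `mpsd`, `n`, `p`.
#' @export
glance.isotherm_fit <- function(x, ...) {
  tibble(family = x$family, method = x$method, r2 = x$r2, mpsd = x$mpsd,
         n = x$n, p = x$p)
}

#' Predict from an isotherm fit
#'
#' @param object An `isotherm_fit`.
#' @param newdata Data frame with a `ce` column (defaults to the fitted
#'   data).
#' @param ... Unused.
#' @return Numeric vector of predicted Qe (mg/g).
#' @export
predict.isotherm_fit <- function(object, newdata = NULL, ...) {
  ce <- if (is.null(newdata)) object$data$ce else newdata$ce
  suppressWarnings(
    predict_qe(object$family, object$params, ce, temp_k = object$temp_k,
               cs = object$cs)
  )
}

#' Plot an isotherm fit over its data
#'
#' Observed equilibrium points with the fitted isotherm curve evaluated on
#' a fine Ce grid.
#'
#' @param object An `isotherm_fit`.
#' @param n_grid Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isotherm_fit <- function(object, n_grid = 200, ...) {
  info <- family_registry()[[object$family]]
  grid <- tibble(
    ce = seq(min(object$data$ce), max(object$data$ce), length.out = n_grid)
  )
  grid$qe <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ce, y = .data$qe)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(
      x = expression(C[e] ~ (mg / dm^3)), y = expression(Q[e] ~ (mg / g)),
      title = paste0(info$pretty, " fit (", object$method, " method)")
    ) +
    ggplot2::theme_minimal()
}

#' Compare several fits in one plot
#'
#' @param fits Result of [fit_isotherms()] (tibble with a `fit` list-column)
#'   or a list of `isotherm_fit` objects.
#' @param n_grid Number of curve evaluation points per fit.
#' @return A ggplot object overlaying the fitted curves on the shared data.
#' @export
plot_isotherms <- function(fits, n_grid = 200) {
  fl <- if (is.data.frame(fits)) fits$fit else fits
  if (!length(fl)) abort("No fits to plot.", class = "sorbkit_error_input")
  data <- fl[[1]]$data
  curves <- purrr::map_dfr(fl, function(f) {
    g <- tibble(ce = seq(min(f$data$ce), max(f$data$ce), length.out = n_grid))
    g$qe <- predict(f, g)
    g$model <- paste0(family_registry()[[f$family]]$label, " (", f$method, ")")
    g
  })
  ggplot2::ggplot(data, ggplot2::aes(x = .data$ce, y = .data$qe)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves, ggplot2::aes(colour = .data$model)) +
    ggplot2::labs(x = expression(C[e] ~ (mg / dm^3)),
                  y = expression(Q[e] ~ (mg / g)), colour = "Model") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
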