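# Linearized least-squares estimation, including the embedded 1-D search
# over k_rp (Redlich-Peterson) and n_da (Dubinin-Astakhov) that maximizes
# the r-squared of the inner straight-line fit.

#' Simple unweighted least-squares line
#'
#' Closed-form ordinary least squares for a straight line, the engine behind
#' every linearized isotherm fit. `r2` is the squared Pearson correlation of
#' `(x, y)`.
#'
#' @param x,y Numeric vectors of equal length (>= 3 points; `x` must vary).
#' @return A list with `slope`, `intercept`, and `r2`.
#' @examples
#' ols_line(c(0, 1, 2), c(1, 3, 5))
#' @export
ols_line <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "sorbkit_error_input")
  }
  if (length(x) < 3) {
    abort("Need at least 3 points for a least-squares line.",
          class = "sorbkit_error_input")
  }
  sx <- stats::var(x)
  if (!is.finite(sx) || sx == 0) {
    abort("`x` values are all identical; the slope is undefined.",
          class = "sorbkit_error_input")
  }
  slope <- stats::cov(x, y) / sx
  intercept <- mean(y) - slope * mean(x)
  sy <- stats::var(y)
  r2 <- if (sy == 0) 1 else stats::cor(x, y)^2
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Vectorized per-point domain indicator for a family's linear transform.
transform_domain_ok <- function(family, ce, qe, aux = NULL, cs = NULL) {
  ok <- switch(family,
    langmuir = ,
    freundlich = ce > 0 & qe > 0,
    redlich_peterson = ce > 0 & qe > 0,
    temkin = ce > 0,
    dubinin_radushkevich = ,
    dubinin_astakhov = {
      base <- ce > 0 & qe > 0
      if (!is.null(cs)) base & ce <= cs else base
    }
  )
  ok
}

require_in_domain <- function(family, data, aux, cs, drop_invalid) {
  ok <- transform_domain_ok(family, data$ce, data$qe, aux = aux, cs = cs)
  if (all(ok)) return(data)
  if (!drop_invalid) {
    abort(
      paste0("Point(s) ", paste(which(!ok), collapse = ", "),
             " are outside the ", family, " linearization domain. ",
             "Set `drop_invalid = TRUE` to exclude them explicitly."),
      class = "sorbkit_error_domain"
    )
  }
  rlang::inform(paste0("Dropping ", sum(!ok), " out-of-domain point(s) for ",
                       family, " linear fit: ",
                       paste(which(!ok), collapse = ", ")))
  data[ok, , drop = FALSE]
}

# Back-transform slope/intercept of the family's linear form to parameters.
linear_back_transform <- function(family, sl, temp_k, aux = NULL) {
  s <- sl$slope
  b <- sl$intercept
  bad <- function(msg) abort(
    paste0(family, " linear fit gave a non-physical line (", msg, ")."),
    class = "sorbkit_error_fit"
  )
  switch(family,
    langmuir = {
      if (b <= 0 || s <= 0) bad("need slope > 0 and intercept > 0")
      c(q_max = 1 / b, k_l = b / s)
    },
    freundlich = {
      if (s <= 0) bad("need slope > 0")
      c(k_f = exp(b), n_f = 1 / s)
    },
    redlich_peterson = {
      if (s <= 0) bad("need slope > 0")
      c(k_rp = aux, a_rp = exp(b), beta = s)
    },
    temkin = {
      if (s <= 0) bad("need slope > 0")
      b_t <- GAS_CONSTANT * temp_k / s
      c(k_t = exp(b / s), b_t = b_t)
    },
    dubinin_radushkevich = {
      if (s >= 0) bad("need slope < 0")
      c(q_max = exp(b), k_dr = -s)
    },
    dubinin_astakhov = {
      if (s >= 0) bad("need slope < 0")
      c(q_max = exp(b), k_da = -s, n_da = aux)
    }
  )
}

# One inner linearized fit at a fixed auxiliary value (or none).
linear_fit_once <- function(family, data, temp_k, cs, aux = NULL) {
  xy <- transform_linear(family, data, aux = aux, temp_k = temp_k, cs = cs)
  sl <- ols_line(xy$x, xy$y)
  params <- linear_back_transform(family, sl, temp_k, aux = aux)
  list(params = params, r2 = sl$r2, slope = sl$slope, intercept = sl$intercept)
}

# r2 of the inner OLS as a function of the profiled auxiliary parameter;
# -Inf where the transform or line is infeasible.
profile_objective <- function(family, data, temp_k, cs) {
  function(aux) {
    tryCatch({
      xy <- transform_linear(family, data, aux = aux, temp_k = temp_k, cs = cs)
      ols_line(xy$x, xy$y)$r2
    }, error = function(e) -Inf)
  }
}

default_profile_bounds <- function(family, data) {
  if (family == "redlich_peterson") {
    lo <- (1 + 1e-6) * max(data$qe / data$ce)
    c(lo, lo * 1e6)
  } else {
    c(1, 6)
  }
}

# Profiled linear fit for the three-parameter families: a log-grid scan
# brackets the r2 maximum, golden-section/parabolic refinement polishes it.
profile_fit_linear <- function(family, data, temp_k, cs, bounds = NULL,
                               control = fit_control()) {
  stopifnot(family %in% c("redlich_peterson", "dubinin_astakhov"))
  if (is.null(bounds)) bounds <- default_profile_bounds(family, data)
  if (length(bounds) != 2 || !all(is.finite(bounds)) || bounds[1] <= 0 ||
      bounds[2] <= bounds[1]) {
    abort("`bounds` must be an increasing positive pair.",
          class = "sorbkit_error_input")
  }
  f <- profile_objective(family, data, temp_k, cs)
  lgrid <- seq(log(bounds[1]), log(bounds[2]),
               length.out = control$grid_points)
  r2g <- vapply(lgrid, function(lv) f(exp(lv)), numeric(1))
  if (all(!is.finite(r2g))) {
    abort(
      paste0("No feasible ", family, " profile value inside the search ",
             "bounds [", format(bounds[1]), ", ", format(bounds[2]), "]."),
      class = "sorbkit_error_fit"
    )
  }
  # local maxima of the grid pre-scan (plateau-safe comparison)
  n <- length(r2g)
  is_max <- vapply(seq_len(n), function(i) {
    if (!is.finite(r2g[i])) return(FALSE)
    left <- if (i > 1) r2g[i - 1] else -Inf
    right <- if (i < n) r2g[i + 1] else -Inf
    r2g[i] >= left && r2g[i] >= right
  }, logical(1))
  peaks <- which(is_max)
  refine <- function(i) {
    lo <- if (i > 1) lgrid[i - 1] else lgrid[i]
    hi <- if (i < n) lgrid[i + 1] else lgrid[i]
    if (lo == hi) return(list(maximum = lgrid[i], objective = r2g[i]))
    stats::optimize(function(lv) f(exp(lv)), c(lo, hi), maximum = TRUE,
                    tol = control$profile_tol)
  }
  refined <- lapply(peaks, refine)
  # optimize() returns list(maximum=..., objective=...) when maximum=TRUE
  vals <- vapply(refined, `[[`, numeric(1), "objective")
  locs <- vapply(refined, `[[`, numeric(1), "maximum")
  # distinct interior maxima (beyond grid-resolution duplicates) -> warn
  keep <- order(vals, decreasing = TRUE)
  distinct <- unique(round(locs[keep] / (lgrid[2] - lgrid[1])))
  if (length(distinct) > 1 && diff(range(locs[keep][1:2])) >
      2 * (lgrid[2] - lgrid[1])) {
    warn(
      paste0("Profile r2 for ", family, " is multi-modal; candidates at ",
             paste(signif(exp(locs[keep][1:2]), 6), collapse = " and "),
             " (larger-r2 solution kept)."),
      class = "sorbkit_warning_multimodal"
    )
  }
  best_aux <- exp(locs[keep][1])
  inner <- linear_fit_once(family, data, temp_k, cs, aux = best_aux)
  inner$aux <- best_aux
  inner
}
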