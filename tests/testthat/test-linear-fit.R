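test_that("ols_line reproduces closed-form least squares", {
  exact <- ols_line(c(0, 1, 2), c(1, 3, 5))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r2, 1)

  # hand-computed: x-mean 1, y-mean 1/3, Sxy = 0 -> flat line
  flat <- ols_line(c(0, 1, 2), c(0, 1, 0))
  expect_equal(flat$slope, 0)
  expect_equal(flat$intercept, 1 / 3)
  expect_equal(flat$r2, 0)

  expect_error(ols_line(c(1, 1, 1), c(1, 2, 3)),
               class = "sorbkit_error_input")
  expect_error(ols_line(c(1, 2), c(1, 2)), class = "sorbkit_error_input")
})

test_that("r2 is invariant under affine rescaling of y", {
  withr::with_seed(21, {
    x <- runif(15)
    y <- 2 * x + rnorm(15, sd = 0.1)
    base <- ols_line(x, y)$r2
    for (i in 1:10) {
      a <- runif(1, 0.1, 10)
      b <- rnorm(1, sd = 5)
      expect_equal(ols_line(x, a * y + b)$r2, base, tolerance = 1e-12)
    }
  })
})

test_that("linear fits recover generating parameters on noiseless data", {
  for (family in isotherm_families()$family) {
    truth <- ref_truth(family)
    d <- noiseless_data(family, truth)
    fit <- fit_isotherm(d, family, method = "linear", cs = SIM_CS)
    expect_lt(rel_err(fit$params[names(truth)], truth), 1e-6)
    expect_gte(fit$r2, 1 - 1e-10)
  }
})

test_that("an exact power law is fitted exactly by the Freundlich form", {
  d <- tibble::tibble(ce = c(1, 10, 100), qe = c(2, 20, 200))
  fit <- fit_isotherm(d, "freundlich", method = "linear")
  expect_equal(unname(fit$params["n_f"]), 1, tolerance = 1e-12)
  expect_equal(unname(fit$params["k_f"]), 2, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
})

test_that("fitting refuses datasets without residual degrees of freedom", {
  d <- tibble::tibble(ce = c(10, 100), qe = c(5, 20))
  expect_error(fit_isotherm(d, "langmuir", method = "linear"),
               class = "sorbkit_error_input")
})

test_that("out-of-domain points are refused unless dropping is explicit", {
  d <- tibble::tibble(ce = c(0, 10, 100, 1000), qe = c(0, 5, 30, 90))
  expect_error(fit_isotherm(d, "langmuir", method = "linear"),
               class = "sorbkit_error_domain")
  expect_message(
    fit <- fit_isotherm(d, "langmuir", method = "linear",
                        drop_invalid = TRUE),
    regexp = "Dropping 1"
  )
  expect_equal(fit$n, 3)
})

test_that("profiled linear fits recover the non-linearizable parameter", {
  rp_truth <- c(k_rp = 0.471, a_rp = 5.068e-3, beta = 0.914)
  d <- noiseless_data("redlich_peterson", rp_truth)
  fit <- fit_isotherm(d, "redlich_peterson", method = "linear")
  expect_lt(abs(fit$params[["k_rp"]] - 0.471) / 0.471, 1e-3)
  expect_gte(fit$r2, 1 - 1e-8)

  da_truth <- c(q_max = 210.3, k_da = 5.448e-12, n_da = 2.733)
  d2 <- noiseless_data("dubinin_astakhov", da_truth)
  fit2 <- fit_isotherm(d2, "dubinin_astakhov", method = "linear",
                       cs = SIM_CS)
  expect_lt(abs(fit2$params[["n_da"]] - 2.733) / 2.733, 1e-3)
})

test_that("infeasible profile search bounds raise an error", {
  d <- noiseless_data("redlich_peterson",
                      c(k_rp = 0.471, a_rp = 5.068e-3, beta = 0.914))
  # every k_rp below max(qe/ce) leaves points outside the log's domain
  expect_error(
    fit_isotherm(d, "redlich_peterson", method = "linear",
                 bounds = c(1e-6, 0.5 * max(d$qe / d$ce))),
    class = "sorbkit_error_fit"
  )
})

test_that("profiled fits agree with the dense-grid oracle", {
  withr::with_seed(31, {
    for (i in 1:3) {
      truth <- random_rp_params()
      d <- noiseless_data("redlich_peterson", truth)
      fit <- fit_isotherm(d, "redlich_peterson", method = "linear")
      oracle <- grid_profile_oracle("redlich_peterson", d)
      expect_lt(abs(fit$params[["k_rp"]] - oracle$aux) / oracle$aux, 1e-6)
    }
  })
})
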