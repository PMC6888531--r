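test_that("forward prediction matches hand-evaluated values and limits", {
  # Langmuir at Ce = 1000 with a tabulated parameter set, checked against
  # independent scalar arithmetic q K c / (1 + K c)
  pars <- c(q_max = 169.5, k_l = 2.745e-3)
  expected <- 169.5 * 2.745e-3 * 1000 / (1 + 2.745e-3 * 1000)
  expect_equal(predict_qe("langmuir", pars, 1000), expected)
  expect_equal(round(expected, 1), 124.2)

  # zero concentration, zero uptake
  expect_identical(predict_qe("langmuir", pars, 0), 0)

  # at the solubility limit the Polanyi potential vanishes and the
  # pore-filling models saturate at capacity
  dr <- c(q_max = 282.9, k_dr = 8.107e-9)
  expect_equal(
    predict_qe("dubinin_radushkevich", dr, ce = 500, temp_k = 298.15,
               cs = 500),
    282.9
  )
})

test_that("prediction is vectorized and errors are specific", {
  pars <- c(q_max = 100, k_l = 1e-3)
  expect_length(predict_qe("langmuir", pars, c(0, 10, 100)), 3)
  expect_error(predict_qe("langmuir", c(q_max = -1, k_l = 1e-3), 1),
               class = "sorbkit_error_params")
  expect_error(predict_qe("langmuir", c(q_max = 100, wrong = 1e-3), 1),
               class = "sorbkit_error_params")
  expect_error(
    predict_qe("dubinin_radushkevich", c(q_max = 100, k_dr = 1e-8), 10,
               temp_k = 298.15),
    class = "sorbkit_error_missing_context"
  )
  expect_error(
    predict_qe("dubinin_radushkevich", c(q_max = 100, k_dr = 1e-8), 2000,
               temp_k = 298.15, cs = 1000),
    class = "sorbkit_error_domain"
  )
  expect_error(
    predict_qe("redlich_peterson", c(k_rp = 1, a_rp = 0.1, beta = 1.2), 1),
    class = "sorbkit_error_params"
  )
})

test_that("Temkin prediction may be negative below 1/k_t and is flagged", {
  pars <- c(k_t = 5.728e-2, b_t = 91.96)
  expect_warning(
    qe <- predict_qe("temkin", pars, 1, temp_k = 298.15),
    class = "sorbkit_warning_temkin_negative"
  )
  expect_lt(qe, 0)
  expect_error(predict_qe("temkin", pars, 0, temp_k = 298.15),
               class = "sorbkit_error_domain")
})

test_that("Polanyi potential matches its closed form and domain", {
  expect_identical(polanyi_potential(500, 500, 298.15), 0)
  expect_equal(polanyi_potential(100, 1000, 298.15),
               8.314 * 298.15 * log(10))
  expect_error(polanyi_potential(1001, 1000, 298.15),
               class = "sorbkit_error_domain")
  expect_error(polanyi_potential(0, 1000, 298.15),
               class = "sorbkit_error_domain")
  expect_error(polanyi_potential(10, 1000, -1),
               class = "sorbkit_error_domain")
})

test_that("linearizing transforms map points to the expected coordinates", {
  expect_equal(
    transform_linear("langmuir", tibble::tibble(ce = 500, qe = 100)),
    tibble::tibble(x = 0.002, y = 0.01)
  )
  expect_equal(
    transform_linear("freundlich",
                     tibble::tibble(ce = exp(1), qe = exp(2))),
    tibble::tibble(x = 1, y = 2)
  )
  # Redlich-Peterson needs k_rp Ce / Qe strictly above 1
  expect_error(
    transform_linear("redlich_peterson", tibble::tibble(ce = 10, qe = 10),
                     aux = 1),
    class = "sorbkit_error_domain"
  )
  expect_error(
    transform_linear("langmuir", tibble::tibble(ce = c(1, 0), qe = c(1, 1))),
    regexp = "point\\(s\\) 2"
  )
})

test_that("Redlich-Peterson with beta = 1 collapses to Langmuir", {
  withr::with_seed(11, {
    for (i in 1:20) {
      k_rp <- 10^runif(1, -2, 1)
      a_rp <- 10^runif(1, -4, -1)
      ce <- 10^runif(25, -1, 4)
      rp <- predict_qe("redlich_peterson",
                       c(k_rp = k_rp, a_rp = a_rp, beta = 1), ce)
      lm_equiv <- predict_qe("langmuir",
                             c(q_max = k_rp / a_rp, k_l = a_rp), ce)
      expect_equal(rp, lm_equiv, tolerance = 1e-12)
    }
  })
})

test_that("Dubinin-Astakhov with n = 2 collapses to Dubinin-Radushkevich", {
  withr::with_seed(12, {
    for (i in 1:20) {
      k <- 10^runif(1, -10, -8)
      q <- runif(1, 50, 300)
      ce <- 10^runif(25, 0, log10(SIM_CS))
      expect_equal(
        predict_qe("dubinin_astakhov", c(q_max = q, k_da = k, n_da = 2),
                   ce, temp_k = 298.15, cs = SIM_CS),
        predict_qe("dubinin_radushkevich", c(q_max = q, k_dr = k),
                   ce, temp_k = 298.15, cs = SIM_CS),
        tolerance = 1e-14
      )
    }
  })
})

test_that("monotone families are nondecreasing in Ce up to the solubility", {
  grids <- seq(1, SIM_CS, length.out = 400)
  cases <- list(
    list("langmuir", c(q_max = 169.5, k_l = 2.745e-3)),
    list("freundlich", c(k_f = 2.634, n_f = 1.918)),
    list("dubinin_radushkevich", c(q_max = 282.9, k_dr = 8.107e-9)),
    list("dubinin_astakhov",
         c(q_max = 210.3, k_da = 5.448e-12, n_da = 2.733))
  )
  for (case in cases) {
    qe <- predict_qe(case[[1]], case[[2]], grids, temp_k = 298.15,
                     cs = SIM_CS)
    expect_true(all(diff(qe) >= -1e-10), label = case[[1]])
  }
})

test_that("transforms invert back to Qe within 1e-12 relative", {
  temp_k <- 298.15
  cases <- list(
    langmuir = list(c(q_max = 169.5, k_l = 2.745e-3), NULL),
    freundlich = list(c(k_f = 2.634, n_f = 1.918), NULL),
    redlich_peterson = list(c(k_rp = 0.471, a_rp = 5.068e-3, beta = 0.914),
                            0.471),
    temkin = list(c(k_t = 5.728e-2, b_t = 91.96), NULL),
    dubinin_radushkevich = list(c(q_max = 282.9, k_dr = 8.107e-9), NULL),
    dubinin_astakhov = list(c(q_max = 210.3, k_da = 5.448e-12,
                              n_da = 2.733), 2.733)
  )
  ce <- geometric_schedule(10, 50, 6000)
  for (family in names(cases)) {
    pars <- cases[[family]][[1]]
    aux <- cases[[family]][[2]]
    qe <- suppressWarnings(
      predict_qe(family, pars, ce, temp_k = temp_k, cs = SIM_CS)
    )
    keep <- qe > 0
    d <- tibble::tibble(ce = ce[keep], qe = qe[keep])
    xy <- transform_linear(family, d, aux = aux, temp_k = temp_k,
                           cs = SIM_CS)
    qe_back <- switch(family,
      langmuir = 1 / xy$y,
      freundlich = exp(xy$y),
      redlich_peterson = aux * d$ce / (1 + exp(xy$y)),
      temkin = xy$y,
      dubinin_radushkevich = exp(xy$y),
      dubinin_astakhov = exp(xy$y)
    )
    expect_equal(qe_back, d$qe, tolerance = 1e-12, label = family)
  }
})
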